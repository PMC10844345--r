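#' Window / step / smoothing parameter grid
#'
#' All combinations of the supplied window lengths, sliding steps and
#' smoothing kernels; defaults are the robustness-protocol settings
#' (windows 50, 64, 100 s; steps 2, 4 s; FWHM 6 mm).
#'
#' @param windows_s window lengths in seconds.
#' @param steps_s sliding steps in seconds.
#' @param fwhms_mm smoothing FWHMs in mm.
#' @return data.frame with one row per setting and a `setting` key column.
#' @export
parameter_grid <- function(windows_s = c(50, 64, 100), steps_s = c(2, 4),
                           fwhms_mm = 6) {
  g <- expand.grid(window_s = windows_s, step_s = steps_s,
                   fwhm_mm = fwhms_mm, KEEP.OUT.ATTRS = FALSE)
  g$setting <- sprintf("w%gs%gf%g", g$window_s, g$step_s, g$fwhm_mm)
  g
}

#' Run the group pipeline over a parameter grid
#'
#' Each feasible setting is processed with the identical pipeline and the
#' identical master seed; settings whose window exceeds the (preprocessed)
#' series duration, or whose window/step is not a TR multiple, are skipped
#' with a logged reason rather than crashing.
#'
#' @param cohort a `synthetic_cohort` (or list with the same structure).
#' @param grid data.frame from [parameter_grid()].
#' @param base_config a `run_config`; its window/step/FWHM are overridden
#'   per setting.
#' @param cache_dir optional directory: per-setting results are written as
#'   RDS keyed by setting and re-used on re-runs.
#' @return Named list: per setting, the [end_to_end()] result or a skip
#'   record (`skipped = TRUE`, `reason`).
#' @export
run_grid <- function(cohort, grid, base_config = run_config(),
                     cache_dir = NULL) {
  out <- vector("list", nrow(grid))
  names(out) <- grid$setting
  nt <- ncol(cohort$subjects[[1]]$bold$signal) - base_config$discard
  for (i in seq_len(nrow(grid))) {
    cfg <- base_config
    cfg$window_s <- grid$window_s[i]
    cfg$step_s <- grid$step_s[i]
    cfg$fwhm_mm <- grid$fwhm_mm[i]
    feas <- tryCatch({
      sp <- window_spec(cfg$window_s, cfg$step_s, cohort$tr_s)
      if (sp$window_vols > nt)
        stop("window of ", sp$window_vols,
             " volumes exceeds series length ", nt)
      TRUE
    }, error = function(e) conditionMessage(e))
    if (!isTRUE(feas)) {
      message("skipping setting ", grid$setting[i], ": ", feas)
      out[[i]] <- list(skipped = TRUE, reason = feas)
      next
    }
    cache_file <- NULL
    if (!is.null(cache_dir)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      key <- paste0(grid$setting[i], "_seed", cfg$seed, "_n",
                    nrow(cohort$design))
      cache_file <- file.path(cache_dir, paste0(key, ".rds"))
      if (file.exists(cache_file)) {
        out[[i]] <- readRDS(cache_file)
        next
      }
    }
    res <- end_to_end(cohort, cfg)
    if (!is.null(cache_file)) saveRDS(res, cache_file)
    out[[i]] <- res
  }
  out
}

#' Spatial agreement of two statistical maps
#'
#' Pearson correlation over masked vertices.
#'
#' @param tmap_a,tmap_b per-vertex maps on the same mesh.
#' @param mask a `cortex_mask` or NULL (finite vertices of both maps).
#' @return Correlation in \[-1, 1\].
#' @export
map_agreement <- function(tmap_a, tmap_b, mask = NULL) {
  if (length(tmap_a) != length(tmap_b)) stop("maps differ in length")
  m <- if (is.null(mask)) is.finite(tmap_a) & is.finite(tmap_b)
       else as.logical(unclass(mask))
  a <- tmap_a[m]; b <- tmap_b[m]
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance within the mask")
  stats::cor(a, b)
}

#' Dice overlap of two vertex sets
#'
#' `2 |A ∩ B| / (|A| + |B|)`; two empty sets are defined as overlap 1 with
#' a warning.
#'
#' @param set_a,set_b integer vertex index vectors.
#' @return Dice coefficient in \[0, 1\].
#' @export
dice_overlap <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!length(set_a) && !length(set_b)) {
    warning("both vertex sets are empty; Dice defined as 1")
    return(1)
  }
  2 * length(intersect(set_a, set_b)) / (length(set_a) + length(set_b))
}

surviving_vertices <- function(result) {
  if (isTRUE(result$skipped) || !length(result$clusters)) return(integer(0))
  surv <- Filter(function(cl) isTRUE(cl$survives), result$clusters)
  sort(unique(unlist(lapply(surv, `[[`, "vertices"))))
}

#' Pairwise agreement report for a grid run
#'
#' For every pair of completed settings: the spatial correlation of the
#' group t-maps over the mask and the Dice overlap of the surviving-cluster
#' vertex sets.
#'
#' @param results named list from [run_grid()].
#' @param mask a `cortex_mask` or NULL.
#' @return data.frame with columns `setting_a`, `setting_b`,
#'   `t_correlation`, `dice`.
#' @export
agreement_report <- function(results, mask = NULL) {
  done <- names(results)[!vapply(results, function(r)
    isTRUE(r$skipped), TRUE)]
  if (length(done) < 2L)
    return(data.frame(setting_a = character(0), setting_b = character(0),
                      t_correlation = numeric(0), dice = numeric(0)))
  pairs <- utils::combn(done, 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- results[[pairs[1, j]]]; b <- results[[pairs[2, j]]]
    va <- surviving_vertices(a); vb <- surviving_vertices(b)
    dice <- if (!length(va) && !length(vb)) {
      warning("both settings have no surviving clusters; Dice = 1")
      1
    } else dice_overlap(va, vb)
    data.frame(setting_a = pairs[1, j], setting_b = pairs[2, j],
               t_correlation = map_agreement(a$tmap, b$tmap, mask),
               dice = dice)
  })
  do.call(rbind, rows)
}
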