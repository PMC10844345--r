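#' Pipeline run configuration
#'
#' All tunable pipeline parameters with their default acquisition/analysis
#' values: discard 10 initial volumes, band-pass 0.01-0.1 Hz, 64 s windows
#' advanced by 4 s, 6 mm smoothing, vertex-level p < 0.001, cluster areal
#' extent > 20 mm^2, cluster-level q < 0.05 (halved per hemisphere when the
#' Bonferroni switch is on), 499 permutations.
#'
#' @param discard initial volumes removed.
#' @param low_hz,high_hz band-pass edges in Hz.
#' @param window_s,step_s sliding-window length and step in seconds.
#' @param fwhm_mm smoothing FWHM in mm (0 disables smoothing).
#' @param mode stability target mode.
#' @param vertex_p two-sided vertex-level p threshold.
#' @param min_area_mm2 cluster areal extent threshold (strict).
#' @param q cluster-level FDR level.
#' @param hemi_bonferroni halve `q` per hemisphere.
#' @param n_perm permutations for cluster p-values.
#' @param covariates nuisance covariate column names from the cohort design
#'   used in the group GLM.
#' @param max_trans_mm,max_rot_deg motion exclusion limits.
#' @param seed master seed for permutation inference.
#' @param zscore_before_smooth z-score first, then smooth (default TRUE).
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(discard = 10, low_hz = 0.01, high_hz = 0.1,
                       window_s = 64, step_s = 4, fwhm_mm = 6,
                       mode = "vertex_by_atlas",
                       vertex_p = 0.001, min_area_mm2 = 20, q = 0.05,
                       hemi_bonferroni = FALSE, n_perm = 499,
                       covariates = "mean_fd",
                       max_trans_mm = 2.5, max_rot_deg = 2.5,
                       seed = 1, zscore_before_smooth = TRUE) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Parse a configuration file with flag overrides
#'
#' Reads a YAML file of `run_config` keys; explicit overrides win over file
#' values, file values win over defaults. Unknown keys in either source are
#' rejected by name.
#'
#' @param file path to a YAML config file, or NULL.
#' @param overrides named list of override values (e.g. parsed CLI flags).
#' @return A `run_config`.
#' @export
parse_config <- function(file = NULL, overrides = list()) {
  defaults <- run_config()
  vals <- unclass(defaults)
  apply_layer <- function(vals, layer, src) {
    if (!length(layer)) return(vals)
    unknown <- setdiff(names(layer), names(vals))
    if (length(unknown))
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    vals[names(layer)] <- layer
    vals
  }
  if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    vals <- apply_layer(vals, yaml::read_yaml(file), file)
  }
  vals <- apply_layer(vals, overrides, "overrides")
  structure(vals, class = "run_config")
}

#' Subject-level stability from raw series and motion
#'
#' Applies the subject-level chain: initial-volume discard, Friston-24 +
#' linear-trend confound regression, band-pass filtering, then the
#' sliding-window concordance map.
#'
#' @param bold a raw `bold_series`.
#' @param motion the subject's `motion_trace`.
#' @param mask,atlas surface mask and parcellation.
#' @param config a `run_config`.
#' @return A raw (un-standardised) `stability_map`.
#' @export
subject_stability <- function(bold, motion, mask, atlas, config) {
  b <- discard_initial(bold, config$discard)
  conf <- friston24(motion)[-seq_len(config$discard), , drop = FALSE]
  conf <- cbind(conf, trend = seq_len(ncol(b$signal)))
  b <- regress_confounds(b, conf)
  b <- bandpass(b, config$low_hz, config$high_hz)
  sp <- window_spec(config$window_s, config$step_s, b$tr_s)
  stability_map(b, mask = mask, spec = sp, mode = config$mode,
                atlas = atlas)
}

#' Run the full group pipeline end to end
#'
#' Motion QC, subject-level preprocessing and stability, joint
#' z-standardisation, surface smoothing, the vertex-wise group GLM,
#' cluster formation, permutation cluster p-values with BH-FDR control,
#' cluster labelling, and clinical (visual-field mean deviation)
#' correlations in patients. Identical seeds give identical results.
#'
#' @param cohort a `synthetic_cohort` (or a list with the same fields:
#'   `subjects`, `design`, `mesh`, `atlas`, `tr_s`).
#' @param config a `run_config`.
#' @param out_dir optional output directory for tables and the manifest.
#' @return List with `maps` (smoothed z-scored subject maps), `tmap`,
#'   `df`, `clusters` (with p, q, `survives`), `design_used`, `qc`,
#'   `md_correlations`, `cluster_table`, `manifest`.
#' @export
end_to_end <- function(cohort, config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  mesh <- cohort$mesh
  mask <- if (!is.null(cohort$mask)) cohort$mask
          else cortex_mask(rep(TRUE, n_vertices(mesh)))
  atlas <- cohort$atlas
  design <- cohort$design
  warnings_log <- character(0)

  qc <- lapply(cohort$subjects, function(s)
    qc_motion(s$motion, config$max_trans_mm, config$max_rot_deg))
  keep <- vapply(qc, `[[`, TRUE, "pass")
  if (sum(!keep))
    warnings_log <- c(warnings_log,
                      sprintf("%d subject(s) excluded by motion QC",
                              sum(!keep)))
  design <- design[keep, , drop = FALSE]
  subjects <- cohort$subjects[keep]

  calib <- if (config$fwhm_mm > 0)
    smoothing_calibration(mesh, mask, config$fwhm_mm) else NULL
  maps <- lapply(subjects, function(s)
    subject_stability(s$bold, s$motion, mask, atlas, config))
  maps <- zscore_map(maps, rep(list(mask), length(maps)))
  if (config$fwhm_mm > 0)
    maps <- lapply(maps, smooth_map, mesh = mesh, mask = mask,
                   fwhm_mm = config$fwhm_mm, calibration = calib)

  cov_df <- design[, intersect(config$covariates, names(design)),
                   drop = FALSE]
  gd <- group_design(design$group, cov_df)
  fit <- fit_group_glm(maps, gd, mask)
  clusters <- form_clusters(fit$t, fit$df, mesh, mask,
                            vertex_p = config$vertex_p,
                            min_area_mm2 = config$min_area_mm2)
  clusters <- cluster_pvalues_permutation(
    maps, gd, clusters, mesh, mask, df = fit$df,
    vertex_p = config$vertex_p, min_area_mm2 = config$min_area_mm2,
    n_perm = config$n_perm, seed = config$seed)
  q_eff <- if (config$hemi_bonferroni)
    hemisphere_bonferroni(config$q, 2L) else config$q
  if (length(clusters)) {
    fdr <- bh_fdr(vapply(clusters, `[[`, 0, "p"), q = q_eff)
    for (i in seq_along(clusters)) {
      clusters[[i]]$q <- fdr$adjusted[i]
      clusters[[i]]$survives <- fdr$rejected[i]
    }
  }
  clusters <- label_clusters(clusters, atlas)

  md_cor <- NULL
  surv <- Filter(function(cl) isTRUE(cl$survives), clusters)
  pat <- design$group == "patient"
  if (length(surv) && any(is.finite(design$md_vf[pat]))) {
    md_cor <- lapply(surv, function(cl) {
      vals <- vapply(maps[pat], cluster_mean_stability, 0, cluster = cl)
      sc <- spearman_cor(vals, design$md_vf[pat])
      c(rho = sc$rho, p = sc$p, n = sc$n)
    })
    md_p <- vapply(md_cor, `[`, 0, "p")
    md_adj <- bh_fdr(md_p, q = config$q)$adjusted
    md_cor <- do.call(rbind, md_cor)
    md_cor <- data.frame(cluster = seq_along(surv), md_cor,
                         q = md_adj, row.names = NULL)
  }

  manifest <- list(config = unclass(config),
                   n_subjects_in = length(cohort$subjects),
                   n_subjects_used = sum(keep),
                   n_patients = sum(design$group == "patient"),
                   n_controls = sum(design$group == "control"),
                   n_clusters_formed = length(clusters),
                   n_clusters_surviving = length(surv),
                   q_effective = q_eff,
                   warnings = warnings_log,
                   package_version = as.character(
                     utils::packageVersion("surfstab")))
  result <- list(maps = maps, tmap = fit$t, df = fit$df,
                 clusters = clusters, design_used = design, qc = qc,
                 md_correlations = md_cor,
                 cluster_table = render_cluster_report(clusters),
                 manifest = manifest)
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

#' Render the cluster table
#'
#' One row per cluster with location labels, hemisphere, size (mm^2 and
#' vertices), peak coordinates, peak t, networks, p and q; ordered by
#' hemisphere then descending area.
#'
#' @param clusters list of scored `cluster_result`s.
#' @param digits rounding for coordinates and statistics.
#' @return data.frame (header-only when no clusters).
#' @export
render_cluster_report <- function(clusters, digits = 4) {
  cols <- c("cluster", "location", "hemisphere", "area_mm2", "n_vertices",
            "peak_x", "peak_y", "peak_z", "peak_t", "networks", "p", "q")
  if (!length(clusters)) {
    tb <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    tb$location <- character(0); tb$hemisphere <- character(0)
    tb$networks <- character(0)
    return(tb)
  }
  rows <- lapply(clusters, function(cl) data.frame(
    cluster = NA_integer_,
    location = paste(cl$region_labels, collapse = ";"),
    hemisphere = cl$hemisphere,
    area_mm2 = round(cl$area_mm2, digits),
    n_vertices = cl$n_vertices,
    peak_x = round(cl$peak_coord[1], digits),
    peak_y = round(cl$peak_coord[2], digits),
    peak_z = round(cl$peak_coord[3], digits),
    peak_t = round(cl$peak_t, digits),
    networks = paste(cl$network_labels, collapse = ";"),
    p = cl$p, q = cl$q, row.names = NULL))
  tb <- do.call(rbind, rows)
  tb <- tb[order(tb$hemisphere, -tb$area_mm2), , drop = FALSE]
  tb$cluster <- seq_len(nrow(tb))
  rownames(tb) <- NULL
  tb
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(result$cluster_table,
                     file.path(out_dir, "clusters.tsv"), sep = "\t")
  tmap_df <- data.frame(vertex = seq_along(result$tmap), t = result$tmap)
  data.table::fwrite(tmap_df, file.path(out_dir, "tmap.tsv"), sep = "\t")
  data.table::fwrite(result$design_used,
                     file.path(out_dir, "design_used.tsv"), sep = "\t")
  if (!is.null(result$md_correlations))
    data.table::fwrite(result$md_correlations,
                       file.path(out_dir, "md_correlations.tsv"),
                       sep = "\t")
  jsonlite::write_json(result$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(out_dir)
}
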