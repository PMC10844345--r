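#' Surface BOLD time series
#'
#' @param signal numeric matrix, vertices x timepoints.
#' @param tr_s repetition time in seconds.
#' @param subject subject identifier.
#' @param hemisphere hemisphere tag.
#' @return Object of class `bold_series`.
#' @export
bold_series <- function(signal, tr_s, subject = "sub-01",
                        hemisphere = "single") {
  signal <- as.matrix(signal)
  if (ncol(signal) < 2L) stop("a BOLD series needs at least 2 timepoints")
  if (tr_s <= 0) stop("'tr_s' must be positive")
  structure(list(signal = signal, tr_s = tr_s, subject = subject,
                 hemisphere = hemisphere),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("bold_series %s: %d vertices x %d volumes, TR %gs (%s)\n",
              x$subject, nrow(x$signal), ncol(x$signal), x$tr_s,
              x$hemisphere))
  invisible(x)
}

#' Motion quality control
#'
#' A subject fails when any translation parameter exceeds `max_trans_mm` in
#' magnitude or any rotation exceeds `max_rot_deg`; the comparison is
#' strict, so motion exactly at the limit passes.
#'
#' @param trace a `motion_trace`.
#' @param max_trans_mm translation limit (default 2.5 mm).
#' @param max_rot_deg rotation limit (default 2.5 degrees).
#' @return List with `pass` (logical) and `reason` (character or NA).
#' @export
qc_motion <- function(trace, max_trans_mm = 2.5, max_rot_deg = 2.5) {
  stopifnot(inherits(trace, "motion_trace"))
  mt <- max(abs(trace$params[, 1:3]))
  mr <- max(abs(trace$params[, 4:6]))
  if (mt > max_trans_mm)
    return(list(pass = FALSE,
                reason = sprintf("max translation %.3f mm > %g mm",
                                 mt, max_trans_mm)))
  if (mr > max_rot_deg)
    return(list(pass = FALSE,
                reason = sprintf("max rotation %.3f deg > %g deg",
                                 mr, max_rot_deg)))
  list(pass = TRUE, reason = NA_character_)
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` timepoints to allow for signal equilibration.
#'
#' @param bold a `bold_series`.
#' @param n_discard number of initial volumes to remove (default 10).
#' @return The shortened `bold_series`.
#' @export
discard_initial <- function(bold, n_discard = 10L) {
  stopifnot(inherits(bold, "bold_series"))
  nt <- ncol(bold$signal)
  if (n_discard < 0) stop("'n_discard' must be non-negative")
  if (n_discard >= nt)
    stop("cannot discard ", n_discard, " of ", nt, " timepoints")
  if (n_discard == 0L) return(bold)
  bold$signal <- bold$signal[, -seq_len(n_discard), drop = FALSE]
  bold
}

#' Friston 24-parameter motion regressors
#'
#' The 6 rigid-body parameters, their one-volume-lagged copies (first row
#' zero-padded), and the squares of both sets: 24 columns.
#'
#' @param trace a `motion_trace` (or volumes x 6 parameter matrix).
#' @return Numeric matrix, volumes x 24.
#' @export
friston24 <- function(trace) {
  p <- if (inherits(trace, "motion_trace")) trace$params else as.matrix(trace)
  stopifnot(ncol(p) == 6L, nrow(p) >= 2L)
  lag <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lag, p^2, lag^2)
  base <- colnames(p)
  if (is.null(base)) base <- paste0("rp", 1:6)
  colnames(out) <- c(base, paste0(base, "_lag"), paste0(base, "_sq"),
                     paste0(base, "_lag_sq"))
  out
}

#' Regress confounds from a BOLD series
#'
#' Per-vertex ordinary least-squares residualisation against the supplied
#' per-volume regressors; an intercept is always included, so with an empty
#' confound set the signal is mean-centered. Residuals are orthogonal to
#' every regressor.
#'
#' @param bold a `bold_series`.
#' @param confounds numeric matrix/data.frame with one row per volume, or
#'   NULL for intercept-only.
#' @return The residual `bold_series`.
#' @export
regress_confounds <- function(bold, confounds = NULL) {
  stopifnot(inherits(bold, "bold_series"))
  nt <- ncol(bold$signal)
  X <- cbind(intercept = rep(1, nt))
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    if (nrow(confounds) != nt)
      stop("confound rows (", nrow(confounds),
           ") must equal timepoints (", nt, ")")
    X <- cbind(X, confounds)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("confound design is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- t(bold$signal)
  bold$signal <- t(Y - X %*% qr.coef(qrX, Y))
  bold
}

#' Band-pass filter a BOLD series
#'
#' Frequency-domain mask filter: Fourier components with frequency inside
#' `[low_hz, high_hz]` are retained, all others (including the DC component
#' whenever `low_hz > 0`) are zeroed.
#'
#' @param bold a `bold_series`.
#' @param low_hz lower edge (default 0.01 Hz).
#' @param high_hz upper edge (default 0.1 Hz).
#' @return The filtered `bold_series`.
#' @export
bandpass <- function(bold, low_hz = 0.01, high_hz = 0.1) {
  stopifnot(inherits(bold, "bold_series"))
  nyq <- 1 / (2 * bold$tr_s)
  if (low_hz < 0 || low_hz >= high_hz)
    stop("need 0 <= low_hz < high_hz")
  if (high_hz > nyq + 1e-12)
    stop(sprintf("high_hz %.4g exceeds the Nyquist frequency %.4g", high_hz,
                 nyq))
  nt <- ncol(bold$signal)
  freq <- (seq_len(nt) - 1) / (nt * bold$tr_s)
  freq <- pmin(freq, 1 / bold$tr_s - freq)  # folded (two-sided) frequency
  keep <- freq >= low_hz - 1e-12 & freq <= high_hz + 1e-12
  if (low_hz > 0) keep[1L] <- FALSE
  F <- t(stats::mvfft(t(bold$signal)))
  F[, !keep] <- 0
  bold$signal <- Re(t(stats::mvfft(t(F), inverse = TRUE))) / nt
  bold
}

#' Sliding-window specification
#'
#' @param window_s window length in seconds.
#' @param step_s step between window starts in seconds.
#' @param tr_s repetition time; both `window_s` and `step_s` must be integer
#'   multiples of it.
#' @return Object of class `window_spec` with derived `window_vols` and
#'   `step_vols`.
#' @export
window_spec <- function(window_s, step_s, tr_s) {
  wv <- window_s / tr_s
  sv <- step_s / tr_s
  if (abs(wv - round(wv)) > 1e-9 || abs(sv - round(sv)) > 1e-9)
    stop("window_s and step_s must be integer multiples of tr_s")
  wv <- as.integer(round(wv)); sv <- as.integer(round(sv))
  if (wv < 3L) stop("window must span at least 3 volumes")
  if (sv < 1L) stop("step must span at least 1 volume")
  structure(list(window_s = window_s, step_s = step_s, tr_s = tr_s,
                 window_vols = wv, step_vols = sv),
            class = "window_spec")
}

#' Enumerate sliding windows
#'
#' Full windows only: the count is `floor((n - w) / s) + 1` where w and s
#' are the window and step in volumes; a trailing partial window is dropped.
#'
#' @param n_timepoints series length in volumes.
#' @param tr_s repetition time in seconds.
#' @param spec a `window_spec` (its `tr_s` must match).
#' @return data.frame with 1-based inclusive `start` and `end` volume
#'   indices, one row per window.
#' @export
make_windows <- function(n_timepoints, tr_s, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (abs(spec$tr_s - tr_s) > 1e-9)
    stop("window_spec was built for a different TR")
  w <- spec$window_vols; s <- spec$step_vols
  if (w > n_timepoints)
    stop("window of ", w, " volumes exceeds series length ", n_timepoints)
  starts <- seq.int(1L, n_timepoints - w + 1L, by = s)
  data.frame(start = starts, end = starts + w - 1L)
}

# Pearson correlations between one seed column and target columns for each
# window; zero-variance series within a window yield NA.
window_cor <- function(seed_ts, target_ts, windows) {
  k <- nrow(windows)
  out <- matrix(NA_real_, k, ncol(target_ts))
  for (w in seq_len(k)) {
    rows <- windows$start[w]:windows$end[w]
    x <- seed_ts[rows]
    if (stats::sd(x) == 0) next
    Ty <- target_ts[rows, , drop = FALSE]
    sdy <- apply(Ty, 2, stats::sd)
    r <- suppressWarnings(as.numeric(stats::cor(x, Ty)))
    r[sdy == 0] <- NA_real_
    out[w, ] <- r
  }
  out
}

#' Sliding-window functional connectivity for one seed vertex
#'
#' For every window, the Pearson correlation of the seed vertex's series
#' with each target series: either all other masked vertices
#' (`targets = "mask"`) or per-window parcel-mean series
#' (`targets = "atlas"`, the seed's own parcel mean recomputed without the
#' seed). Zero-variance series within a window give an undefined (NA)
#' correlation, later excluded from ranking.
#'
#' @param bold a `bold_series`.
#' @param seed_vertex 1-based seed vertex index (must be inside the mask).
#' @param targets `"mask"` or `"atlas"`.
#' @param windows data.frame from [make_windows()].
#' @param mask a `cortex_mask` or NULL.
#' @param atlas a `parcellation_atlas` (required for `targets = "atlas"`).
#' @return Object of class `dfc_stack`: matrix windows x targets with
#'   attributes `seed_vertex` and `target_ids`.
#' @export
windowed_fc <- function(bold, seed_vertex, targets = c("mask", "atlas"),
                        windows, mask = NULL, atlas = NULL) {
  targets <- match.arg(targets)
  stopifnot(inherits(bold, "bold_series"))
  if (min(windows$end - windows$start) + 1L < 3L)
    stop("each window needs at least 3 volumes")
  V <- nrow(bold$signal)
  m <- if (is.null(mask)) rep(TRUE, V) else as.logical(unclass(mask))
  if (!m[seed_vertex]) stop("seed vertex lies outside the mask")
  ts <- t(bold$signal)  # time x vertices
  if (targets == "mask") {
    tgt <- setdiff(which(m), seed_vertex)
    stack <- window_cor(ts[, seed_vertex], ts[, tgt, drop = FALSE], windows)
    ids <- tgt
  } else {
    if (is.null(atlas)) stop("'atlas' required for vertex-by-atlas targets")
    lab <- atlas$labels
    parcels <- sort(unique(lab[lab > 0 & m]))
    if (length(parcels) < 2L)
      stop("vertex-by-atlas mode needs at least 2 parcels")
    S <- vapply(parcels, function(p)
      rowMeans(ts[, lab == p & m, drop = FALSE]), numeric(nrow(ts)))
    own <- lab[seed_vertex]
    oi <- match(own, parcels)
    if (!is.na(oi)) {
      np <- sum(lab == own & m)
      if (np > 1L) S[, oi] <- (S[, oi] * np - ts[, seed_vertex]) / (np - 1L)
      else S[, oi] <- NA_real_
    }
    stack <- window_cor(ts[, seed_vertex], S, windows)
    ids <- parcels
  }
  structure(stack, class = c("dfc_stack", "matrix"),
            seed_vertex = seed_vertex, target_ids = ids)
}

#' Kendall's coefficient of concordance of a DFC stack
#'
#' Windows act as judges ranking the connectivity targets; ties receive
#' average ranks and the tie-corrected W is returned, clamped to \[0, 1\].
#' Targets with an undefined correlation in any window are dropped from all
#' windows' rankings (keeping the judge/item grid rectangular); the number
#' dropped is reported as an attribute.
#'
#' @param stack numeric matrix, windows x targets (a `dfc_stack`).
#' @return W in \[0, 1\] with attribute `n_dropped`; NA with a warning when
#'   all targets are tied in every window.
#' @export
kendalls_w <- function(stack) {
  m <- unclass(stack)
  if (!is.matrix(m)) stop("'stack' must be a windows x targets matrix")
  if (nrow(m) < 2L) stop("need at least 2 windows (judges)")
  keep <- colSums(!is.finite(m)) == 0L
  nd <- sum(!keep)
  if (sum(keep) < 2L)
    stop("need at least 2 targets (items) with defined correlations")
  w <- cpp_kendall_w(m[, keep, drop = FALSE])
  if (is.nan(w)) {
    warning("Kendall's W undefined: all targets tied within every window")
    w <- NA_real_
  }
  structure(w, n_dropped = nd)
}

#' Per-vertex functional stability map
#'
#' For every masked vertex, the Kendall concordance of its sliding-window
#' functional-connectivity maps: windows are judges, connectivity targets
#' are items. `vertex_by_vertex` uses every other masked vertex as a
#' target; `vertex_by_atlas` uses per-window parcel-mean series, with the
#' seed's own parcel mean recomputed without the seed.
#'
#' @param bold a preprocessed `bold_series`.
#' @param mask a `cortex_mask` or NULL.
#' @param spec a `window_spec`.
#' @param mode `"vertex_by_atlas"` (default) or `"vertex_by_vertex"`.
#' @param atlas a `parcellation_atlas` (required in atlas mode).
#' @param own_parcel in atlas mode, how the seed's parcel enters its target
#'   set: `"exclude_self"` (leave-one-out mean, default), `"include_self"`,
#'   or `"drop"` (own parcel not a target).
#' @return Object of class `stability_map`: `values` (per-vertex W, NA
#'   outside the mask), `provenance` list.
#' @export
stability_map <- function(bold, mask = NULL, spec,
                          mode = c("vertex_by_atlas", "vertex_by_vertex"),
                          atlas = NULL, own_parcel = "exclude_self") {
  mode <- match.arg(mode)
  stopifnot(inherits(bold, "bold_series"), inherits(spec, "window_spec"))
  V <- nrow(bold$signal)
  m <- if (is.null(mask)) rep(TRUE, V) else as.logical(unclass(mask))
  windows <- make_windows(ncol(bold$signal), bold$tr_s, spec)
  k <- nrow(windows)
  ts <- t(bold$signal)
  vals <- rep(NA_real_, V)

  if (mode == "vertex_by_vertex") {
    midx <- which(m)
    # per-window correlation matrices over all vertices (BLAS crossprod)
    C <- array(NA_real_, c(V, V, k))
    for (w in seq_len(k)) {
      rows <- windows$start[w]:windows$end[w]
      X <- ts[rows, , drop = FALSE]
      X <- sweep(X, 2, colMeans(X))
      s <- sqrt(colSums(X^2))
      X <- sweep(X, 2, ifelse(s > 0, s, Inf), "/")
      Cw <- crossprod(X)
      Cw[s == 0, ] <- NA_real_
      Cw[, s == 0] <- NA_real_
      C[, , w] <- Cw
    }
    res <- cpp_stability_vv(C, V, k, midx - 1L)
    vals <- res$w
  } else {
    if (is.null(atlas)) stop("vertex_by_atlas mode requires an atlas")
    lab <- atlas$labels
    parcels <- sort(unique(lab[lab > 0 & m]))
    if (length(parcels) < 2L)
      stop("vertex_by_atlas mode needs at least 2 parcels")
    P <- length(parcels)
    midx <- which(m)
    nm <- length(midx)
    lab_i <- match(lab, parcels)           # parcel index per vertex (or NA)
    np <- tabulate(lab_i[m], nbins = P)    # masked parcel sizes
    stacks <- array(NA_real_, c(k, P, nm))
    for (w in seq_len(k)) {
      rows <- windows$start[w]:windows$end[w]
      X <- ts[rows, midx, drop = FALSE]          # time x masked vertices
      S <- vapply(seq_len(P), function(p)
        rowMeans(X[, lab_i[midx] == p, drop = FALSE]),
        numeric(length(rows)))                   # time x parcels
      nT <- length(rows)
      Xc <- sweep(X, 2, colMeans(X))
      Sc <- sweep(S, 2, colMeans(S))
      vX <- colSums(Xc^2); vS <- colSums(Sc^2)
      CxS <- crossprod(Xc, Sc)                   # vertices x parcels
      R <- CxS / sqrt(outer(vX, vS))
      R[!is.finite(R)] <- NA_real_
      # leave-one-out own-parcel correlation: cor(x, (np*S - x)/(np-1))
      own <- lab_i[midx]
      has_own <- !is.na(own) & np[ifelse(is.na(own), 1L, own)] > 1L
      if (own_parcel == "exclude_self") {
        oi <- own[has_own]
        covxo <- CxS[cbind(which(has_own), oi)]
        n_p <- np[oi]
        cov_loo <- (n_p * covxo - vX[has_own]) / (n_p - 1)
        var_loo <- (n_p^2 * vS[oi] - 2 * n_p * covxo + vX[has_own]) /
          (n_p - 1)^2
        r_loo <- cov_loo / sqrt(vX[has_own] * var_loo)
        r_loo[!is.finite(r_loo)] <- NA_real_
        R[cbind(which(has_own), oi)] <- r_loo
        if (any(!has_own & !is.na(own)))
          R[cbind(which(!has_own & !is.na(own)), own[!has_own & !is.na(own)])] <-
            NA_real_
      } else if (own_parcel == "drop") {
        R[cbind(seq_len(nm), own)[!is.na(own), , drop = FALSE]] <- NA_real_
      }
      stacks[w, , ] <- t(R)
    }
    vals[midx] <- cpp_kendall_w_stacks(stacks, k, P, nm)
  }
  vals[is.nan(vals)] <- NA_real_
  structure(list(values = vals,
                 provenance = list(window_spec = spec, mode = mode,
                                   own_parcel = own_parcel,
                                   n_windows = k, zscored = FALSE,
                                   fwhm_mm = NA_real_,
                                   subject = bold$subject)),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf(paste0("stability_map (%s%s): %d masked vertices, ",
                     "median %.3f [%.3f, %.3f]\n"),
              x$provenance$mode,
              if (isTRUE(x$provenance$zscored)) ", z-scored" else "",
              length(v), stats::median(v), min(v), max(v)))
  invisible(x)
}

#' Z-standardise a stability map within the cortex mask
#'
#' Subtracts the masked mean and divides by the masked sample standard
#' deviation, so the result has mask mean 0 and SD 1. When a list of maps
#' and masks for two hemispheres is supplied, the mean and SD are pooled
#' over both masks jointly.
#'
#' @param map a `stability_map` (or list of two for both hemispheres).
#' @param mask matching `cortex_mask` (or list of two).
#' @return The standardised map(s) with the `zscored` provenance flag set.
#' @export
zscore_map <- function(map, mask = NULL) {
  maps <- if (inherits(map, "stability_map")) list(map) else map
  masks <- if (is.null(mask) || inherits(mask, "cortex_mask"))
    rep(list(mask), length(maps)) else mask
  vals <- unlist(lapply(seq_along(maps), function(i) {
    v <- maps[[i]]$values
    m <- if (is.null(masks[[i]])) is.finite(v)
         else as.logical(unclass(masks[[i]]))
    v[m]
  }))
  vals <- vals[is.finite(vals)]
  if (length(vals) < 2L) stop("need at least 2 masked finite values")
  mu <- mean(vals); sdv <- stats::sd(vals)
  if (sdv == 0) stop("cannot z-score a constant map (zero SD)")
  out <- lapply(maps, function(mp) {
    mp$values <- (mp$values - mu) / sdv
    mp$provenance$zscored <- TRUE
    mp
  })
  if (inherits(map, "stability_map")) out[[1L]] else out
}

#' Smooth a stability map on the surface
#'
#' @param map a `stability_map`.
#' @param mesh,mask surface and cortex mask.
#' @param fwhm_mm smoothing FWHM in mm.
#' @param calibration optional precomputed `smoothing_calibration`.
#' @return The smoothed map with `fwhm_mm` recorded in provenance.
#' @export
smooth_map <- function(map, mesh, mask = NULL, fwhm_mm,
                       calibration = NULL) {
  stopifnot(inherits(map, "stability_map"))
  map$values <- smooth_field(mesh, map$values, mask, fwhm_mm, calibration)
  map$provenance$fwhm_mm <- fwhm_mm
  map
}
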