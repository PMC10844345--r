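#' Regime configuration for the synthetic BOLD generator
#'
#' Parcel-level generative model of time-varying functional connectivity:
#' parcels carry unit-variance latent signals whose pairwise correlation is
#' modulated over time, and vertices observe their parcel's latent plus
#' spatially independent noise. Modulation amplitude 0 makes a parcel's
#' couplings stationary; amplitude a > 0 makes the parcel reconfigure its
#' connectivity profile between states: as the modulation state s(t) rises,
#' the parcel's latent blends from its own factor toward a state-switch
#' partner's factor (`sqrt(1 - a s) z_p + sqrt(a s) z_partner`), so its
#' windowed connectivity profile reorders between regimes — the signature
#' the concordance statistic detects.
#'
#' @param partner optional integer vector assigning each parcel its
#'   state-switch partner; defaults to the parcel half the label circle
#'   away.
#'
#' @param coupling data.frame with columns `p1`, `p2`, `rho`: coupled parcel
#'   pairs and their baseline correlation.
#' @param amplitude numeric vector of modulation amplitudes in \[0, 1\],
#'   one per parcel label (named or positional by sorted label).
#' @param form `"regimes"` (piecewise-constant coupling states) or
#'   `"sinusoid"` (continuous modulation).
#' @param dwell_s regime dwell time in seconds (form = "regimes").
#' @param period_s modulation period in seconds (form = "sinusoid").
#' @param noise_sd observation noise SD relative to unit-variance latents.
#' @param ar1 AR(1) coefficient of latent and noise innovations.
#' @return Object of class `regime_config`.
#' @export
regime_config <- function(coupling, amplitude, form = c("regimes", "sinusoid"),
                          dwell_s = 96, period_s = 128,
                          noise_sd = 0.5, ar1 = 0.3, partner = NULL) {
  form <- match.arg(form)
  stopifnot(is.data.frame(coupling),
            all(c("p1", "p2", "rho") %in% names(coupling)))
  if (any(amplitude < 0 | amplitude > 1))
    stop("modulation amplitudes must lie in [0, 1]")
  if (abs(ar1) >= 1) stop("'ar1' must lie in (-1, 1)")
  if (noise_sd < 0) stop("'noise_sd' must be non-negative")
  structure(list(coupling = coupling, amplitude = amplitude, form = form,
                 dwell_s = dwell_s, period_s = period_s,
                 noise_sd = noise_sd, ar1 = ar1, partner = partner),
            class = "regime_config")
}

# Baseline parcel correlation matrix implied by the coupling graph.
parcel_corr_base <- function(config, parcels) {
  P <- length(parcels)
  C <- diag(P)
  for (r in seq_len(nrow(config$coupling))) {
    i <- match(config$coupling$p1[r], parcels)
    j <- match(config$coupling$p2[r], parcels)
    if (is.na(i) || is.na(j)) stop("coupling names parcel absent from atlas")
    C[i, j] <- C[j, i] <- config$coupling$rho[r]
  }
  C
}

# Parcel correlation matrix at modulation state s in [0, 1]. A parcel with
# amplitude a reconfigures its connectivity profile as the modulation state
# rises: its latent blends from its own factor toward its state-switch
# partner's factor, x_p = sqrt(1 - a*s) z_p + sqrt(a*s) z_partner(p), so at
# full modulation the parcel carries the partner's coupling profile. The
# result is the correlation matrix of well-defined mixtures of the jointly
# Gaussian baseline factors, hence positive semi-definite by construction
# whenever the baseline matrix is.
parcel_corr_at <- function(config, parcels, s) {
  C <- parcel_corr_base(config, parcels)
  P <- length(parcels)
  b <- rep_len(config$amplitude, P) * rep_len(s, P)
  partner <- config$partner
  if (is.null(partner)) partner <- ((seq_len(P) - 1L + P %/% 2L) %% P) + 1L
  M <- diag(sqrt(1 - b), P)
  M[cbind(seq_len(P), partner)] <- M[cbind(seq_len(P), partner)] + sqrt(b)
  S <- M %*% C %*% t(M)
  d <- sqrt(diag(S))
  S / outer(d, d)
}

#' Simulate one subject's surface BOLD series
#'
#' Draws latent parcel signals from the time-varying coupling model and adds
#' per-vertex observation noise; both carry AR(1) temporal autocorrelation.
#' Deterministic given the seed.
#'
#' @param mesh a `surface_mesh`.
#' @param atlas a `parcellation_atlas` aligned to the mesh.
#' @param config a `regime_config`.
#' @param n_volumes number of timepoints.
#' @param tr_s repetition time in seconds.
#' @param seed integer RNG seed.
#' @param subject subject identifier stored in the result.
#' @return A `bold_series`: list with `signal` (vertices x timepoints),
#'   `tr_s`, `subject`, `hemisphere`.
#' @export
simulate_subject_bold <- function(mesh, atlas, config, n_volumes, tr_s,
                                  seed, subject = "sub-01") {
  stopifnot(inherits(config, "regime_config"))
  labels <- atlas$labels
  parcels <- sort(unique(labels[labels > 0L]))
  P <- length(parcels)
  amp <- rep_len(config$amplitude, P)
  config$amplitude <- amp
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)

  t_s <- (seq_len(n_volumes) - 1) * tr_s
  # each modulated parcel carries its own independent regime phase:
  # cortical regions reconfigure asynchronously, and a parcel's stability
  # must track its own modulation amplitude, not a global state clock
  S <- matrix(0, n_volumes, P)
  for (p in which(amp > 0)) {
    if (config$form == "regimes") {
      dwell_vols <- max(1L, round(config$dwell_s / tr_s))
      phase <- sample.int(2L * dwell_vols, 1L) - 1L
      S[, p] <- ((seq_len(n_volumes) - 1L + phase) %/% dwell_vols) %% 2L
    } else {
      phase <- stats::runif(1, 0, 2 * pi)
      S[, p] <- (1 + sin(2 * pi * t_s / config$period_s + phase)) / 2
    }
  }
  # PSD check on the extreme modulation states
  for (s in c(0, 1)) {
    C <- parcel_corr_at(config, parcels, s)
    ev <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-8)
      stop(sprintf(paste0("requested coupling is not positive semi-definite",
                          " at modulation state s = %g (min eigenvalue %.3g)"),
                   s, ev))
  }
  # innovations with per-timepoint correlation via Cholesky per unique
  # joint state (only modulated parcels contribute distinct states)
  E <- matrix(stats::rnorm(n_volumes * P), n_volumes, P)
  key <- apply(S, 1, paste, collapse = ",")
  for (kk in unique(key)) {
    rows <- which(key == kk)
    R <- chol(parcel_corr_at(config, parcels, S[rows[1L], ]) +
                diag(1e-10, P))
    E[rows, ] <- E[rows, , drop = FALSE] %*% R
  }
  phi <- config$ar1
  X <- E
  if (phi != 0 && n_volumes > 1) {
    w <- sqrt(1 - phi^2)
    for (t in 2:n_volumes) X[t, ] <- phi * X[t - 1, ] + w * E[t, ]
  }
  V <- n_vertices(mesh)
  noise <- matrix(stats::rnorm(V * n_volumes), V, n_volumes)
  if (phi != 0) {
    noise <- noise * sqrt(1 - phi^2)
    for (t in 2:n_volumes) noise[, t] <- phi * noise[, t - 1] + noise[, t]
  }
  sig <- config$noise_sd * noise
  lab_idx <- match(labels, parcels)
  has <- !is.na(lab_idx)
  sig[has, ] <- sig[has, , drop = FALSE] + t(X)[lab_idx[has], , drop = FALSE]
  bold_series(sig, tr_s = tr_s, subject = subject,
              hemisphere = mesh$hemisphere)
}

# seed scoping helper: set the seed, return a restorer for the previous state
.Random.seed_guard <- function(seed) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  function() {
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  }
}

#' Simulate a rigid-body head-motion trace
#'
#' Random-walk translations (mm) and rotations (degrees) with scale set by
#' `severity`; framewise displacement is the Power-style sum of absolute
#' backward differences with rotations converted to arc length on a 50 mm
#' sphere.
#'
#' @param n_volumes number of volumes.
#' @param severity non-negative scale; increments have SD `0.02 * severity`
#'   (mm or degrees) per volume, so severity near 1 emulates a typical
#'   compliant adult and severity above ~8 regularly violates a 2.5 mm
#'   excursion limit.
#' @param seed integer RNG seed.
#' @return Object of class `motion_trace`: `params` (volumes x 6, columns
#'   trans_x/y/z mm then rot_x/y/z deg), `fd` (mm, first volume 0) and
#'   `mean_fd`.
#' @export
simulate_motion <- function(n_volumes, severity = 1, seed = 1) {
  stopifnot(n_volumes >= 1)
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  inc <- matrix(stats::rnorm(n_volumes * 6, sd = 0.02 * severity),
                n_volumes, 6)
  inc[1, ] <- 0
  params <- apply(inc, 2, cumsum)
  if (n_volumes == 1L) params <- matrix(params, 1L, 6L)
  colnames(params) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  motion_trace(params)
}

#' Construct a motion trace from parameters
#'
#' @param params volumes x 6 matrix: 3 translations (mm), 3 rotations (deg).
#' @param radius_mm rotation-to-displacement conversion radius.
#' @return A `motion_trace` with derived framewise displacement.
#' @export
motion_trace <- function(params, radius_mm = 50) {
  params <- as.matrix(params)
  stopifnot(ncol(params) == 6L)
  d <- abs(diff(params))
  if (nrow(params) == 1L) d <- matrix(0, 0, 6)
  fd_body <- rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * pi / 180 * rowSums(d[, 4:6, drop = FALSE])
  fd <- c(0, fd_body)
  structure(list(params = params, fd = fd, mean_fd = mean(fd),
                 radius_mm = radius_mm),
            class = "motion_trace")
}

#' Ground truth for the synthetic cohort
#'
#' @param effect_parcels atlas labels where patients receive extra
#'   modulation (lower expected stability).
#' @param effect_delta added modulation amplitude in patients.
#' @param compensatory_parcels labels where patients receive reduced
#'   modulation (higher expected stability).
#' @param compensatory_delta amplitude reduction in patients.
#' @param covariate_parcel label whose per-patient modulation is linked to
#'   the visual-field mean deviation covariate.
#' @param md_rho target Spearman correlation between `md_vf` and the
#'   covariate parcel's modulation amplitude (must lie in (-1, 1)).
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(effect_parcels = integer(0), effect_delta = 0.6,
                         compensatory_parcels = integer(0),
                         compensatory_delta = 0.4,
                         covariate_parcel = NA_integer_, md_rho = -0.5) {
  if (!is.na(md_rho) && (md_rho <= -1 || md_rho >= 1))
    stop("target correlation must lie strictly inside (-1, 1)")
  structure(list(effect_parcels = as.integer(effect_parcels),
                 effect_delta = effect_delta,
                 compensatory_parcels = as.integer(compensatory_parcels),
                 compensatory_delta = compensatory_delta,
                 covariate_parcel = covariate_parcel, md_rho = md_rho),
            class = "ground_truth")
}

#' Default desk-scale study conditions
#'
#' An icosphere mesh whose per-vertex area matches fsaverage5 areal density,
#' a 12-parcel icosahedral Voronoi parcellation, six coupled parcel pairs of
#' which half are temporally modulated, and a ground truth placing a group
#' effect in parcel 1 and the clinical covariate in parcel 3.
#'
#' @param subdivision_level icosphere subdivision (default 2: 162 vertices).
#' @param radius_mm sphere radius (default 12 mm, per-vertex area ~11 mm^2).
#' @param n_parcels number of parcels (default 12).
#' @return List with `mesh`, `mask`, `atlas`, `config`, `truth`.
#' @export
default_study <- function(subdivision_level = 2, radius_mm = 12,
                          n_parcels = 12) {
  mesh <- build_icosphere(subdivision_level, radius_mm)
  mask <- cortex_mask(rep(TRUE, n_vertices(mesh)))
  # Voronoi parcels around the first n_parcels base icosahedron directions
  base <- build_icosphere(0, radius_mm)$vertices
  if (n_parcels > 12) {
    base <- rbind(base, build_icosphere(1, radius_mm)$vertices[13:42, ])
  }
  centers <- base[seq_len(n_parcels), , drop = FALSE]
  d <- as.matrix(mesh$vertices) %*% t(centers)  # cosine similarity * r^2
  labels <- max.col(d, ties.method = "first")
  atlas <- parcellation_atlas(labels)
  P <- n_parcels
  # heterogeneous circulant coupling: every parcel has the same diverse
  # profile of baseline correlations (0.64 to nearest index-neighbors,
  # decaying to ~0.12 opposite), so parcels are exchangeable and window
  # rankings have stable structure for the concordance statistic to
  # preserve; the matrix is strictly positive definite (min eigenvalue
  # ~0.23)
  pairs <- t(utils::combn(P, 2))
  dcirc <- pmin(abs(pairs[, 1] - pairs[, 2]),
                P - abs(pairs[, 1] - pairs[, 2]))
  coupling <- data.frame(p1 = pairs[, 1], p2 = pairs[, 2],
                         rho = 0.9 * exp(-dcirc / 3))
  amp <- rep(0, P)
  amp[c(3, 5)] <- 0.2  # mildly modulated baseline parcels
  config <- regime_config(coupling, amp)
  truth <- ground_truth(effect_parcels = 1L, effect_delta = 0.6,
                        covariate_parcel = 3L, md_rho = -0.5)
  list(mesh = mesh, mask = mask, atlas = atlas, config = config,
       truth = truth)
}

#' Simulate a two-group synthetic cohort
#'
#' Patients receive extra modulation amplitude in the designated effect
#' parcels (lower expected stability) and reduced modulation in designated
#' compensatory parcels; the visual-field mean-deviation covariate is drawn
#' via a Gaussian copula so its rank correlation with the covariate parcel's
#' modulation hits the target within sampling error. Fully deterministic
#' given the master seed.
#'
#' @param n_per_group subjects per group (>= 3).
#' @param mesh,atlas surface and parcellation shared by all subjects.
#' @param config a `regime_config` of baseline (control) conditions.
#' @param truth a `ground_truth`.
#' @param n_volumes acquired volumes per subject (default 180).
#' @param tr_s repetition time (default 2 s).
#' @param seed master seed; per-subject seeds derive from it.
#' @param motion_severity range of per-subject motion severities.
#' @return Object of class `synthetic_cohort`: `subjects` (list with
#'   `bold`, `motion`), `design` (data.frame: subject, group, age, sex,
#'   mean_fd, md_vf), `truth`, plus the generating objects.
#' @export
simulate_cohort <- function(n_per_group, mesh, atlas, config, truth,
                            n_volumes = 180, tr_s = 2, seed = 1,
                            motion_severity = c(0.3, 1.2)) {
  stopifnot(n_per_group >= 3, inherits(truth, "ground_truth"))
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  n <- 2L * n_per_group
  group <- rep(c("patient", "control"), each = n_per_group)
  subject <- sprintf("sub-%03d", seq_len(n))
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 3L * n)
  sex <- ifelse(stats::runif(n) < 0.58, "male", "female")
  age <- round(stats::runif(n, 21, 72))
  sev <- stats::runif(n, motion_severity[1], motion_severity[2])

  labels <- atlas$labels
  parcels <- sort(unique(labels[labels > 0L]))
  P <- length(parcels)
  base_amp <- rep_len(config$amplitude, P)

  # covariate parcel modulation and md_vf via Gaussian copula (patients)
  is_pat <- group == "patient"
  md_vf <- rep(NA_real_, n)
  cov_amp <- rep(NA_real_, n)
  ci <- match(truth$covariate_parcel, parcels)
  if (!is.na(ci)) {
    rho_z <- 2 * sin(pi * truth$md_rho / 6)
    z1 <- stats::rnorm(n_per_group)
    z2 <- rho_z * z1 + sqrt(1 - rho_z^2) * stats::rnorm(n_per_group)
    cov_amp[is_pat] <- stats::pnorm(z1) * 0.8
    md_vf[is_pat] <- pmax(-32, pmin(1.7, -8 + 7 * z2))
  }

  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    amp <- base_amp
    if (is_pat[i]) {
      ei <- match(truth$effect_parcels, parcels)
      amp[ei] <- pmin(1, amp[ei] + truth$effect_delta)
      ki <- match(truth$compensatory_parcels, parcels)
      if (length(ki)) amp[ki] <- pmax(0, amp[ki] - truth$compensatory_delta)
      if (!is.na(ci)) amp[ci] <- pmin(1, pmax(0, cov_amp[i]))
    }
    cfg_i <- config
    cfg_i$amplitude <- amp
    bold <- simulate_subject_bold(mesh, atlas, cfg_i, n_volumes, tr_s,
                                  seed = sub_seeds[i], subject = subject[i])
    motion <- simulate_motion(n_volumes, severity = sev[i],
                              seed = sub_seeds[n + i])
    subjects[[i]] <- list(bold = bold, motion = motion)
  }
  design <- data.frame(subject = subject, group = group, age = age,
                       sex = sex,
                       mean_fd = vapply(subjects,
                                        function(s) s$motion$mean_fd, 0),
                       md_vf = md_vf, stringsAsFactors = FALSE)
  generative <- data.frame(subject = subject,
                           covariate_amplitude = cov_amp)
  structure(list(subjects = subjects, design = design, truth = truth,
                 generative = generative,
                 mesh = mesh, atlas = atlas, config = config,
                 tr_s = tr_s, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects (%d patients / %d controls)\n",
              nrow(x$design), sum(x$design$group == "patient"),
              sum(x$design$group == "control")))
  cat(sprintf("  mesh %d vertices, %d parcels, %d volumes, TR %gs\n",
              n_vertices(x$mesh),
              length(unique(x$atlas$labels[x$atlas$labels > 0])),
              ncol(x$subjects[[1]]$bold$signal), x$tr_s))
  invisible(x)
}
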