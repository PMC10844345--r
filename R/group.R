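#' Group design for vertex-wise inference
#'
#' @param group character/factor of `"patient"` / `"control"` per subject
#'   (the contrast is patient minus control).
#' @param covariates optional data.frame of numeric nuisance covariates
#'   (e.g. mean framewise displacement, age).
#' @return Object of class `group_design` with the assembled design matrix.
#' @export
group_design <- function(group, covariates = NULL) {
  group <- as.character(group)
  lv <- c("control", "patient")
  if (!all(group %in% lv)) stop("group must be 'patient' or 'control'")
  if (min(table(factor(group, lv))) < 2L)
    stop("both groups need at least 2 subjects")
  X <- cbind(intercept = 1, group = as.numeric(group == "patient"))
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    cv <- as.matrix(as.data.frame(covariates))
    if (anyNA(cv)) stop("covariates must be finite")
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  structure(list(group = group, X = X), class = "group_design")
}

#' Vertex-wise group GLM
#'
#' Per-vertex least-squares fit of stability on intercept, group indicator
#' and nuisance covariates; the returned map is the t-statistic of the
#' group coefficient (patient minus control). With no covariates this is
#' exactly the classical pooled-variance two-sample t-test.
#'
#' @param maps list of `stability_map`s (or a subjects x vertices matrix),
#'   vertex-aligned across subjects.
#' @param design a `group_design`.
#' @param mask a `cortex_mask` or NULL.
#' @return List with `t` (per-vertex t, NA outside mask) and `df`.
#' @export
fit_group_glm <- function(maps, design, mask = NULL) {
  stopifnot(inherits(design, "group_design"))
  Y <- maps_to_matrix(maps)
  X <- design$X
  if (nrow(Y) != nrow(X)) stop("map count must match design rows")
  df <- nrow(X) - ncol(X)
  if (df < 3L) stop("fewer than 3 residual degrees of freedom")
  m <- if (is.null(mask)) colSums(!is.finite(Y)) == 0L
       else as.logical(unclass(mask))
  tmap <- glm_group_t(Y[, m, drop = FALSE], X)
  out <- rep(NA_real_, ncol(Y))
  out[m] <- tmap
  list(t = out, df = df)
}

maps_to_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps)
  do.call(rbind, lapply(maps, function(mp) {
    if (inherits(mp, "stability_map")) mp$values else as.numeric(mp)
  }))
}

# t-statistic of the 'group' column (2nd) of X for each response column
glm_group_t <- function(Y, X) {
  qrX <- qr(X)
  beta <- qr.coef(qrX, Y)
  res <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxinv_gg <- chol2inv(qr.R(qrX))[2L, 2L]
  as.numeric(beta[2L, ] / sqrt(sigma2 * xtxinv_gg))
}

#' Form suprathreshold clusters on the surface
#'
#' Thresholds |t| at the two-sided critical value for `vertex_p`, clusters
#' positive and negative excursions separately as connected components of
#' the mesh adjacency restricted to the mask, and discards components whose
#' summed vertex area is not strictly greater than `min_area_mm2`.
#'
#' @param tmap per-vertex t-statistics.
#' @param df degrees of freedom of the t-map.
#' @param mesh a `surface_mesh`.
#' @param mask a `cortex_mask` or NULL.
#' @param vertex_p two-sided vertex-level p threshold (default 0.001).
#' @param min_area_mm2 cluster areal extent threshold (default 20; strict
#'   "greater than").
#' @return List of `cluster_result` objects (possibly empty), each with
#'   vertices, sign, vertex count, area, peak t / vertex / coordinate.
#' @export
form_clusters <- function(tmap, df, mesh, mask = NULL, vertex_p = 0.001,
                          min_area_mm2 = 20) {
  m <- if (is.null(mask)) rep(TRUE, n_vertices(mesh))
       else as.logical(unclass(mask))
  tcrit <- stats::qt(1 - vertex_p / 2, df)
  va <- vertex_areas(mesh)
  nb <- adjacency(mesh)$neighbors
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- which(m & is.finite(tmap) & sgn * tmap > tcrit)
    for (comp in connected_components(supra, nb)) {
      area <- sum(va[comp])
      if (area <= min_area_mm2) next
      pk <- comp[which.max(abs(tmap[comp]))]
      out[[length(out) + 1L]] <- structure(
        list(vertices = comp, sign = sgn, n_vertices = length(comp),
             area_mm2 = area, peak_t = tmap[pk], peak_vertex = pk,
             peak_coord = mesh$vertices[pk, ],
             hemisphere = mesh$hemisphere,
             p = NA_real_, q = NA_real_,
             region_labels = NULL, network_labels = NULL),
        class = "cluster_result")
    }
  }
  out
}

# connected components of the vertex subset 'supra' under adjacency 'nb'
connected_components <- function(supra, nb) {
  if (!length(supra)) return(list())
  in_set <- logical(length(nb))
  in_set[supra] <- TRUE
  seen <- logical(length(nb))
  comps <- list()
  for (v in supra) {
    if (seen[v]) next
    queue <- v
    seen[v] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      u <- queue[[1L]]
      queue <- queue[-1L]
      members <- c(members, u)
      for (w in nb[[u]]) {
        if (in_set[w] && !seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

#' Permutation cluster p-values
#'
#' Group labels are permuted (covariates stay with their subjects and the
#' model is re-fit each permutation); for each permutation the maximal
#' same-sign suprathreshold cluster area is recorded, and each observed
#' cluster's p-value is
#' `(1 + #permuted maxima >= observed area) / (1 + n_perm)`.
#'
#' @param maps subject stability maps (list or matrix).
#' @param design a `group_design`.
#' @param clusters list from [form_clusters()].
#' @param mesh,mask surface and mask (must match the cluster run).
#' @param df degrees of freedom of the observed fit.
#' @param vertex_p,min_area_mm2 thresholds, identical to the observed run.
#' @param n_perm number of permutations (>= 100 recommended).
#' @param seed RNG seed; results are deterministic given it.
#' @return The clusters with `p` filled in.
#' @export
cluster_pvalues_permutation <- function(maps, design, clusters, mesh,
                                        mask = NULL, df,
                                        vertex_p = 0.001,
                                        min_area_mm2 = 20,
                                        n_perm = 499, seed = 1) {
  if (!length(clusters)) return(clusters)
  if (n_perm < 100)
    warning("n_perm < 100 gives poor p-value resolution")
  Y <- maps_to_matrix(maps)
  m <- if (is.null(mask)) colSums(!is.finite(Y)) == 0L
       else as.logical(unclass(mask))
  va <- vertex_areas(mesh)
  nb <- adjacency(mesh)$neighbors
  tcrit <- stats::qt(1 - vertex_p / 2, df)
  Ym <- Y[, m, drop = FALSE]
  midx <- which(m)
  max_area <- function(tm, sgn) {
    supra <- midx[sgn * tm > tcrit]
    comps <- connected_components(supra, nb)
    if (!length(comps)) return(0)
    max(vapply(comps, function(cc) sum(va[cc]), 0))
  }
  old <- .Random.seed_guard(seed)
  on.exit(old(), add = TRUE)
  n <- nrow(Y)
  perm_max <- matrix(0, n_perm, 2)  # columns: positive, negative
  X <- design$X
  for (b in seq_len(n_perm)) {
    pr <- sample.int(n)
    Xp <- X
    Xp[, 2L] <- X[pr, 2L]
    tm <- glm_group_t(Ym, Xp)
    perm_max[b, 1L] <- max_area(tm, 1)
    perm_max[b, 2L] <- max_area(tm, -1)
  }
  lapply(clusters, function(cl) {
    col <- if (cl$sign > 0) 1L else 2L
    cl$p <- (1 + sum(perm_max[, col] >= cl$area_mm2)) / (1 + n_perm)
    cl
  })
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Standard step-up procedure: adjusted value `min over j >= i` of
#' `m * p_(j) / j` clipped at 1; rejection iff the adjusted value is at
#' most `q`.
#'
#' @param pvals numeric p-values in \[0, 1\].
#' @param q FDR level (default 0.05).
#' @return List with `adjusted` and logical `rejected`.
#' @export
bh_fdr <- function(pvals, q = 0.05) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = !is.na(adj) & adj <= q)
}

#' Per-hemisphere Bonferroni threshold
#'
#' @param alpha family-wise level (default 0.05).
#' @param n_hemis number of hemispheres tested separately (default 2).
#' @return `alpha / n_hemis`.
#' @export
hemisphere_bonferroni <- function(alpha = 0.05, n_hemis = 2) {
  stopifnot(n_hemis >= 1)
  alpha / n_hemis
}

#' Mean stability of a cluster for one subject
#'
#' @param map a `stability_map` (typically z-scored and smoothed).
#' @param cluster a `cluster_result`.
#' @param areas optional vertex areas for an area-weighted mean.
#' @return The (optionally area-weighted) mean over cluster vertices.
#' @export
cluster_mean_stability <- function(map, cluster, areas = NULL) {
  v <- if (inherits(map, "stability_map")) map$values else as.numeric(map)
  idx <- cluster$vertices
  if (!length(idx)) stop("cluster is empty")
  if (is.null(areas)) mean(v[idx])
  else stats::weighted.mean(v[idx], areas[idx])
}

#' Spearman rank correlation with p-value
#'
#' Pearson correlation of average ranks over pairwise-complete
#' observations. The p-value uses the t approximation with n - 2 degrees of
#' freedom; for n <= 9 with no ties an exact permutation p is computed by
#' full enumeration.
#'
#' @param x,y numeric vectors of equal length (NAs dropped pairwise).
#' @return List with `rho`, `p`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance")
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9L && !ties) {
    p <- cpp_spearman_exact_p(rx, ry)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

#' Demographic and clinical group tests
#'
#' Age compared with the two-sided Mann-Whitney U test, sex with the
#' Pearson chi-square test (no continuity correction by default; when any
#' expected cell count is very small, Fisher's exact test is substituted
#' with a warning), and paired inter-eye visual-field mean deviation with
#' the Wilcoxon signed-rank test when both eye columns are present.
#'
#' @param design data.frame with columns `group`, `age`, `sex` and
#'   optionally `md_od` / `md_os` (per-eye mean deviation in patients).
#' @param correct logical; apply the Yates continuity correction to the
#'   chi-square test (default FALSE).
#' @return Named list of test results (`statistic`, `p`, `test`, `n`).
#' @export
demographics_tests <- function(design, correct = FALSE) {
  stopifnot(all(c("group", "age", "sex") %in% names(design)))
  g <- factor(design$group, c("control", "patient"))
  out <- list()
  wt <- stats::wilcox.test(age ~ g, data = design, exact = NULL)
  out$age <- list(statistic = unname(wt$statistic), p = wt$p.value,
                  test = "Mann-Whitney U", n = table(g))
  tab <- table(design$sex, g)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 1)) {
    warning("very small expected cell counts; using Fisher's exact test")
    ft <- stats::fisher.test(tab)
    out$sex <- list(statistic = NA_real_, p = ft$p.value,
                    test = "Fisher exact", n = table(g))
  } else {
    ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
    out$sex <- list(statistic = unname(ct$statistic), p = ct$p.value,
                    test = "Pearson chi-square", n = table(g))
  }
  if (all(c("md_od", "md_os") %in% names(design))) {
    pat <- design[design$group == "patient", ]
    d <- pat$md_od - pat$md_os
    d <- d[is.finite(d)]
    if (all(d == 0)) {
      warning("all paired differences are zero; signed-rank p undefined")
      out$md_intereye <- list(statistic = NA_real_, p = NA_real_,
                              test = "Wilcoxon signed-rank",
                              n = length(d))
    } else {
      st <- stats::wilcox.test(pat$md_od, pat$md_os, paired = TRUE)
      out$md_intereye <- list(statistic = unname(st$statistic),
                              p = st$p.value,
                              test = "Wilcoxon signed-rank",
                              n = sum(is.finite(d)))
    }
  }
  out
}

#' Attach region and network labels to clusters
#'
#' Region labels are the parcels covering at least 10 percent of a
#' cluster's vertices, ordered by coverage; network labels come from the
#' atlas network map. Purely a lookup: with no name tables, numeric label
#' ids are reported.
#'
#' @param clusters list of `cluster_result`.
#' @param atlas a `parcellation_atlas` aligned to the mesh.
#' @param min_coverage coverage fraction for reporting a parcel (default
#'   0.10, boundary inclusive).
#' @return The clusters with `region_labels` and `network_labels` filled.
#' @export
label_clusters <- function(clusters, atlas, min_coverage = 0.10) {
  lapply(clusters, function(cl) {
    lab <- atlas$labels[cl$vertices]
    lab <- lab[lab > 0]
    if (!length(lab)) {
      cl$region_labels <- character(0)
      cl$network_labels <- character(0)
      return(cl)
    }
    cov <- sort(table(lab) / cl$n_vertices, decreasing = TRUE)
    keep <- cov[cov >= min_coverage - 1e-12]
    ids <- names(keep)
    nm <- atlas$label_names
    cl$region_labels <- if (!is.null(nm) && all(ids %in% names(nm)))
      unname(nm[ids]) else ids
    nw <- atlas$network_map
    cl$network_labels <- if (!is.null(nw))
      unique(unname(nw[ids[ids %in% names(nw)]])) else character(0)
    cl
  })
}
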