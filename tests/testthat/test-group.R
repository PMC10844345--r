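test_that("covariate-free group GLM equals the classical two-sample t", {
  set.seed(8)
  n1 <- 7; n2 <- 6; V <- 40
  Y <- rbind(matrix(rnorm(n1 * V, mean = 0.3), n1, V),
             matrix(rnorm(n2 * V), n2, V))
  gd <- group_design(rep(c("patient", "control"), c(n1, n2)))
  fit <- fit_group_glm(Y, gd)
  expect_equal(fit$df, n1 + n2 - 2L)
  tref <- vapply(seq_len(V), function(v)
    oracle_two_sample_t(Y[1:n1, v], Y[(n1 + 1):(n1 + n2), v]), 0)
  expect_equal(fit$t, tref, tolerance = 1e-10)
})

test_that("identical groups give t = 0 and orthogonal covariates change nothing", {
  set.seed(9)
  M <- matrix(rnorm(5 * 30), 5, 30)
  Y <- rbind(M, M)
  gd <- group_design(rep(c("patient", "control"), each = 5))
  fit <- fit_group_glm(Y, gd)
  expect_equal(max(abs(fit$t)), 0, tolerance = 1e-8)

  Y2 <- matrix(rnorm(12 * 30), 12, 30)
  g <- rep(c("patient", "control"), each = 6)
  cv <- rnorm(12)
  cv <- residuals(lm(cv ~ I(g == "patient")))  # orthogonal to group
  Y2 <- Y2 - cv %*% (crossprod(cv, Y2) / sum(cv^2))  # and to the data
  f0 <- fit_group_glm(Y2, group_design(g))
  f1 <- fit_group_glm(Y2, group_design(g, data.frame(cv = cv)))
  # the group coefficient is untouched; t rescales only through the df
  expect_equal(f1$t * sqrt(f0$df / f1$df), f0$t, tolerance = 1e-10)

  expect_error(group_design(rep("patient", 4)), "patient|control|groups")
  expect_error(group_design(g, data.frame(a = g == "patient")),
               "rank-deficient")
})

test_that("cluster formation matches a flood-fill oracle with areal threshold", {
  st <- fx_study()
  df <- 28
  tcrit <- qt(1 - 0.001 / 2, df)

  tmap <- rep(0, 162)
  expect_length(form_clusters(tmap, df, st$mesh, st$mask), 0L)

  # a single suprathreshold vertex (~11 mm^2) is discarded at > 20 mm^2
  tmap[5] <- 6
  expect_length(form_clusters(tmap, df, st$mesh, st$mask), 0L)

  # hand-built patches: two disjoint suprathreshold neighborhoods
  nb <- adjacency(st$mesh)$neighbors
  patch1 <- c(1L, nb[[1]])
  far <- which(st$mesh$vertices[, 3] < -0.9 * 12)[1]
  patch2 <- c(far, nb[[far]])
  stopifnot(length(intersect(patch1, patch2)) == 0)
  tmap <- rep(0, 162)
  tmap[patch1] <- 5
  tmap[patch2] <- -5
  cl <- form_clusters(tmap, df, st$mesh, st$mask)
  expect_length(cl, 2L)
  signs <- vapply(cl, `[[`, 0, "sign")
  expect_setequal(signs, c(1, -1))
  expect_equal(sort(cl[[which(signs == 1)]]$vertices), sort(patch1))
  expect_equal(sort(cl[[which(signs == -1)]]$vertices), sort(patch2))
  va <- vertex_areas(st$mesh)
  expect_equal(cl[[1]]$area_mm2, sum(va[cl[[1]]$vertices]), tolerance = 1e-12)
  expect_equal(abs(cl[[1]]$peak_t), max(abs(tmap[cl[[1]]$vertices])))

  # random maps against the igraph components oracle
  edges <- adjacency(st$mesh)$edges
  set.seed(31)
  for (i in 1:10) {
    tm <- rnorm(162, sd = 2)
    got <- form_clusters(tm, df, st$mesh, st$mask, min_area_mm2 = 0)
    for (sgn in c(1, -1)) {
      supra <- which(sgn * tm > tcrit)
      want <- oracle_components(supra, edges)
      got_s <- Filter(function(x) x$sign == sgn, got)
      canon <- function(sets) sort(vapply(sets, function(v)
        paste(sort(v), collapse = ","), ""))
      expect_identical(canon(lapply(got_s, `[[`, "vertices")), canon(want))
    }
  }
})

test_that("permutation p-values hit the formula floor and are reproducible", {
  set.seed(12)
  st <- fx_study()
  # build a strong synthetic effect directly in map space
  nb <- adjacency(st$mesh)$neighbors
  patch <- unique(c(1L, nb[[1]], unlist(nb[nb[[1]]])))
  Y <- matrix(rnorm(16 * 162, sd = 0.3), 16, 162)
  Y[1:8, patch] <- Y[1:8, patch] + 3
  gd <- group_design(rep(c("patient", "control"), each = 8))
  fit <- fit_group_glm(Y, gd)
  cl <- form_clusters(fit$t, fit$df, st$mesh, st$mask)
  expect_gte(length(cl), 1L)
  p1 <- cluster_pvalues_permutation(Y, gd, cl, st$mesh, st$mask,
                                    df = fit$df, n_perm = 199, seed = 4)
  big <- which.max(vapply(p1, `[[`, 0, "area_mm2"))
  expect_equal(p1[[big]]$p, 1 / 200)
  p2 <- cluster_pvalues_permutation(Y, gd, cl, st$mesh, st$mask,
                                    df = fit$df, n_perm = 199, seed = 4)
  expect_identical(vapply(p1, `[[`, 0, "p"), vapply(p2, `[[`, 0, "p"))
  expect_warning(
    cluster_pvalues_permutation(Y, gd, cl, st$mesh, st$mask,
                                df = fit$df, n_perm = 50, seed = 4),
    "resolution")
})

test_that("BH-FDR reproduces the step-up rule", {
  r <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q = 0.05)
  expect_equal(sum(r$rejected), 3L)

  expect_equal(sum(bh_fdr(rep(1, 6))$rejected), 0L)

  r1 <- bh_fdr(0.04, q = 0.05)
  expect_true(r1$rejected)
  expect_equal(r1$adjusted, 0.04)

  set.seed(41)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    got <- bh_fdr(p, q = 0.05)
    want <- oracle_bh(p, q = 0.05)
    expect_equal(got$adjusted, want$adjusted, tolerance = 1e-12)
    expect_identical(got$rejected, want$rejected)
  }
})

test_that("hemisphere Bonferroni divides the level", {
  expect_equal(hemisphere_bonferroni(0.05, 2), 0.025)
  expect_equal(hemisphere_bonferroni(0.05, 1), 0.05)
  expect_equal(hemisphere_bonferroni(0.06, 3), 0.02)
})

test_that("cluster mean stability averages member vertices", {
  cl <- structure(list(vertices = c(2L, 3L, 5L)), class = "cluster_result")
  expect_equal(cluster_mean_stability(c(0, 1, 2, 9, 6), cl), 3)
  one <- structure(list(vertices = 4L), class = "cluster_result")
  expect_equal(cluster_mean_stability(c(0, 1, 2, 7), one), 7)
  expect_equal(cluster_mean_stability(rep(2.5, 10), cl), 2.5)
  empty <- structure(list(vertices = integer(0)), class = "cluster_result")
  expect_error(cluster_mean_stability(1:5, empty), "empty")
})

test_that("Spearman correlation matches rank-then-Pearson and cor.test", {
  expect_equal(spearman_cor(1:8, (1:8)^3)$rho, 1)
  expect_equal(spearman_cor(1:8, -(1:8))$rho, -1)

  set.seed(51)
  x <- rnorm(20); y <- rnorm(20)
  sc <- spearman_cor(x, y)
  expect_equal(sc$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(sc$rho, unname(ct$estimate), tolerance = 1e-12)

  x8 <- rnorm(8); y8 <- rnorm(8)
  sc8 <- spearman_cor(x8, y8)
  expect_equal(sc8$method, "exact permutation")
  expect_equal(sc8$p, cor.test(x8, y8, method = "spearman")$p.value,
               tolerance = 1e-12)

  # pairwise-complete handling
  xm <- c(x, NA); ym <- c(y, 1)
  expect_equal(spearman_cor(xm, ym)$n, 20L)
  expect_error(spearman_cor(rep(1, 5), 1:5), "rank variance")
})

test_that("demographics tests reproduce the printed sex-table p-value", {
  # printed male/female counts 41/29 (patients) vs 26/19 (controls)
  design <- data.frame(
    group = rep(c("patient", "control"), c(70, 45)),
    sex = c(rep(c("male", "female"), c(41, 29)),
            rep(c("male", "female"), c(26, 19))),
    age = c(round(runif(70, 21, 72)), round(runif(45, 23, 62))))
  res <- demographics_tests(design)
  expect_equal(res$sex$test, "Pearson chi-square")
  expect_equal(round(res$sex$p, 3), 0.933)
  # the Pearson statistic on these counts is far below 0.674
  expect_lt(res$sex$statistic, 0.01)
  expect_true(res$age$p >= 0 && res$age$p <= 1)

  # Mann-Whitney exact boundary case
  wt <- wilcox.test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(wt$statistic), 0)
  expect_equal(wt$p.value, 0.1)

  # degenerate paired case warns
  d2 <- data.frame(group = rep(c("patient", "control"), each = 5),
                   sex = rep(c("male", "female"), 5),
                   age = rnorm(10, 40),
                   md_od = c(rep(-5, 5), rep(NA, 5)),
                   md_os = c(rep(-5, 5), rep(NA, 5)))
  expect_warning(r2 <- demographics_tests(d2), "zero")
  expect_true(is.na(r2$md_intereye$p))
})

test_that("cluster labelling is a coverage-ordered lookup", {
  atlas <- parcellation_atlas(
    rep(c(7L, 2L, 9L), c(6, 3, 1)),
    label_names = c(`7` = "visual", `2` = "parietal", `9` = "frontal"),
    network_map = c(`7` = "VN", `2` = "VAN"))
  inside <- structure(list(vertices = 1:6, n_vertices = 6L),
                      class = "cluster_result")
  lc <- label_clusters(list(inside), atlas)[[1]]
  expect_equal(lc$region_labels, "visual")
  expect_equal(lc$network_labels, "VN")

  # 60% / 30% / 10% coverage: all three reported (10% inclusive)
  span <- structure(list(vertices = 1:10, n_vertices = 10L),
                    class = "cluster_result")
  atlas2 <- parcellation_atlas(rep(c(7L, 2L, 9L), c(6, 3, 1)),
                               label_names = NULL)
  lc2 <- label_clusters(list(span), atlas2)[[1]]
  expect_equal(lc2$region_labels, c("7", "2", "9"))
})
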