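test_that("subject simulation is deterministic and respects the coupling", {
  st <- fx_study()
  b1 <- simulate_subject_bold(st$mesh, st$atlas, st$config, 120, 2, seed = 9)
  b2 <- simulate_subject_bold(st$mesh, st$atlas, st$config, 120, 2, seed = 9)
  expect_identical(b1$signal, b2$signal)
  b3 <- simulate_subject_bold(st$mesh, st$atlas, st$config, 120, 2, seed = 10)
  expect_false(identical(b1$signal, b3$signal))
})

test_that("with zero modulation the full-length parcel FC matches baseline", {
  st <- fx_study()
  cfg <- st$config
  cfg$amplitude <- rep(0, 12)
  cfg$noise_sd <- 0  # observe the latents directly
  b <- simulate_subject_bold(st$mesh, st$atlas, cfg, 2000, 2, seed = 31)
  lab <- st$atlas$labels
  pm <- vapply(1:12, function(p) colMeans(b$signal[lab == p, , drop = FALSE]),
               numeric(2000))
  # neighbors on the label circle couple at 0.9 * exp(-1/3)
  rho_expected <- 0.9 * exp(-1 / 3)
  got <- mean(c(cor(pm[, 1], pm[, 2]), cor(pm[, 5], pm[, 6]),
                cor(pm[, 9], pm[, 10])))
  expect_equal(got, rho_expected, tolerance = 0.06)
})

test_that("modulation inflates windowed-FC variance across 64 s windows", {
  st <- fx_study()
  lab <- st$atlas$labels
  w <- make_windows(170, 2, window_spec(64, 4, 2))
  var_win <- function(amp1, seed) {
    cfg <- st$config
    cfg$amplitude <- rep(0, 12)
    cfg$amplitude[1] <- amp1
    b <- simulate_subject_bold(st$mesh, st$atlas, cfg, 170, 2, seed = seed)
    # parcel 1 reconfigures toward its state-switch partner (parcel 7),
    # so that pair's windowed correlation carries the modulation
    pm1 <- colMeans(b$signal[lab == 1, ])
    pm7 <- colMeans(b$signal[lab == 7, ])
    r <- vapply(seq_len(nrow(w)), function(i) {
      rows <- w$start[i]:w$end[i]
      cor(pm1[rows], pm7[rows])
    }, 0)
    var(r)
  }
  wins <- vapply(1:50, function(s)
    var_win(0.8, 4000 + s) > var_win(0, 8000 + s), TRUE)
  expect_gte(mean(wins), 0.9)
})

test_that("non-PSD coupling requests are rejected with a clear error", {
  st <- fx_study()
  bad <- data.frame(p1 = c(1, 1, 2), p2 = c(2, 3, 3),
                    rho = c(0.9, 0.9, -0.9))
  cfg <- regime_config(bad, rep(0, 12))
  expect_error(
    simulate_subject_bold(st$mesh, st$atlas, cfg, 50, 2, seed = 1),
    "positive semi-definite")
})

test_that("motion traces behave as random walks with Power-style FD", {
  m0 <- simulate_motion(50, severity = 0, seed = 3)
  expect_true(all(m0$fd == 0))

  const <- motion_trace(matrix(1.3, 40, 6))
  expect_true(all(const$fd == 0))

  tr <- motion_trace(rbind(rep(0, 6), c(1, 0, 0, 0, 0, 0),
                           c(1, 0, 0, 1, 0, 0)))
  expect_equal(tr$fd, c(0, 1, 50 * pi / 180))

  # severe motion violates the 2.5 mm excursion limit in most seeds
  viol <- vapply(1:10, function(s) {
    t <- simulate_motion(180, severity = 15, seed = s)
    !qc_motion(t)$pass
  }, TRUE)
  expect_gte(mean(viol), 0.8)
})

test_that("cohorts are reproducible and carry the designed group effect", {
  st <- fx_study()
  c1 <- fx_small_cohort()
  c2 <- simulate_cohort(4, st$mesh, st$atlas, st$config, st$truth,
                        seed = 77)
  expect_identical(c1$subjects[[1]]$bold$signal,
                   c2$subjects[[1]]$bold$signal)
  expect_identical(c1$design, c2$design)
  expect_equal(nrow(c1$design), 8L)
  expect_setequal(unique(c1$design$group), c("patient", "control"))
  expect_true(all(is.finite(c1$design$mean_fd)))
  expect_true(all(is.na(c1$design$md_vf[c1$design$group == "control"])))
  expect_true(all(is.finite(c1$design$md_vf[c1$design$group == "patient"])))

  expect_error(ground_truth(covariate_parcel = 3, md_rho = 1.2),
               "inside")
})

test_that("effect-parcel stability drops in patients across master seeds", {
  st <- fx_study()
  cfg <- run_config()
  lab <- st$atlas$labels
  lower <- vapply(1:8, function(s) {
    coh <- simulate_cohort(3, st$mesh, st$atlas, st$config, st$truth,
                           seed = 900 + s)
    w1 <- vapply(coh$subjects, function(sub) {
      sm <- subject_stability(sub$bold, sub$motion, st$mask, st$atlas, cfg)
      mean(sm$values[lab == 1])
    }, 0)
    pat <- coh$design$group == "patient"
    mean(w1[pat]) < mean(w1[!pat])
  }, TRUE)
  expect_gte(mean(lower), 7 / 8)
})

test_that("md_vf rank correlation with covariate modulation hits the target", {
  st <- fx_study()
  # generative check: the drawn covariate-parcel amplitudes must rank-
  # correlate with md_vf near the -0.5 target, within sampling error
  gen_rhos <- vapply(1:10, function(s) {
    coh <- simulate_cohort(15, st$mesh, st$atlas, st$config, st$truth,
                           seed = 1500 + s)
    pat <- coh$design$group == "patient"
    spearman_cor(coh$generative$covariate_amplitude[pat],
                 coh$design$md_vf[pat])$rho
  }, 0)
  expect_true(all(gen_rhos > -0.9 & gen_rhos < 0))
  expect_lt(mean(gen_rhos), -0.3)

  # downstream observable: patients' parcel-3 stability correlates
  # positively with md_vf (lower stability with worse visual fields)
  cfg <- run_config()
  rhos <- vapply(1:8, function(s) {
    coh <- simulate_cohort(15, st$mesh, st$atlas, st$config, st$truth,
                           seed = 1200 + s)
    pat <- which(coh$design$group == "patient")
    w3 <- vapply(coh$subjects[pat], function(sub) {
      sm <- subject_stability(sub$bold, sub$motion, st$mask, st$atlas, cfg)
      mean(sm$values[st$atlas$labels == 3])
    }, 0)
    spearman_cor(w3, coh$design$md_vf[pat])$rho
  }, 0)
  expect_gt(mean(rhos), 0.1)
})
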