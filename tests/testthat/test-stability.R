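test_that("motion QC applies strict 2.5 mm / 2.5 degree limits", {
  zero <- motion_trace(matrix(0, 20, 6))
  expect_true(qc_motion(zero)$pass)

  p <- matrix(0, 20, 6); p[10, 1] <- 2.6
  expect_false(qc_motion(motion_trace(p))$pass)

  p <- matrix(0, 20, 6); p[10, 5] <- 2.5  # exactly at the limit passes
  expect_true(qc_motion(motion_trace(p))$pass)
  p[10, 5] <- 2.5001
  expect_false(qc_motion(motion_trace(p))$pass)
})

test_that("initial-volume discard shortens the series in order", {
  b <- bold_series(matrix(seq_len(5 * 180), 5, 180), tr_s = 2)
  b10 <- discard_initial(b, 10)
  expect_equal(ncol(b10$signal), 170L)
  expect_equal(b10$signal[, 1], b$signal[, 11])
  expect_identical(discard_initial(b, 0), b)
  b5 <- bold_series(matrix(rnorm(25), 5, 5), tr_s = 2)
  expect_error(discard_initial(b5, 10), "discard")
})

test_that("Friston-24 expansion has the documented structure", {
  tr <- simulate_motion(30, severity = 1, seed = 2)
  X <- friston24(tr)
  expect_equal(ncol(X), 24L)
  expect_equal(nrow(X), 30L)
  expect_equal(X[, 7:12], rbind(0, tr$params[-30, ]),
               ignore_attr = TRUE)
  expect_equal(X[, 13:18], tr$params^2, ignore_attr = TRUE)
  zero <- friston24(motion_trace(matrix(0, 10, 6)))
  expect_true(all(zero == 0))
})

test_that("confound regression leaves orthogonal residuals", {
  nt <- 60
  ramp <- matrix(rep(seq_len(nt), each = 4), 4, nt, byrow = FALSE)
  b <- bold_series(ramp * c(1, -2, 0.5, 3), tr_s = 2)
  r <- regress_confounds(b, cbind(trend = seq_len(nt)))
  expect_equal(max(abs(r$signal)), 0, tolerance = 1e-8)

  set.seed(5)
  sig <- matrix(rnorm(4 * nt), 4, nt)
  b <- bold_series(sig, tr_s = 2)
  mc <- regress_confounds(b, NULL)
  expect_equal(mc$signal, sig - rowMeans(sig), tolerance = 1e-12)

  conf <- matrix(rnorm(nt * 3), nt, 3)
  mixed <- bold_series(sig + t(conf %*% matrix(rnorm(12), 3, 4)), tr_s = 2)
  res <- regress_confounds(mixed, conf)
  for (j in 1:3)
    expect_lt(max(abs(cor(t(res$signal), conf[, j]))), 1e-10)

  dup <- cbind(a = conf[, 1], b = conf[, 1] * 2)
  expect_error(regress_confounds(b, dup), "collinear")
})

test_that("band-pass keeps in-band sinusoids and rejects out-of-band", {
  nt <- 170; tr <- 2
  t_s <- (seq_len(nt) - 1) * tr
  inband <- sin(2 * pi * 0.05 * t_s)          # 0.05 Hz = bin 17
  outband <- sin(2 * pi * 0.2 * t_s)          # 0.2 Hz > 0.1 Hz
  b <- bold_series(rbind(inband, outband, rep(1, nt)), tr_s = tr)
  f <- bandpass(b, 0.01, 0.1)
  expect_equal(max(abs(f$signal[1, ])), max(abs(inband)), tolerance = 0.01)
  expect_equal(f$signal[1, ], inband, tolerance = 0.02)
  expect_lt(max(abs(f$signal[2, ])), 0.01)
  expect_equal(max(abs(f$signal[3, ])), 0, tolerance = 1e-10)

  expect_error(bandpass(b, 0.05, 0.3), "Nyquist")
  expect_error(bandpass(b, 0.1, 0.05), "low_hz")
})

test_that("window enumeration matches brute-force start enumeration", {
  sp <- window_spec(64, 4, 2)
  w <- make_windows(170, 2, sp)
  expect_equal(nrow(w), 70L)
  expect_true(all(w$end - w$start + 1L == 32L))
  expect_equal(w$start, oracle_window_starts(170, 32L, 2L))

  sp1 <- window_spec(100, 2, 2)
  expect_equal(nrow(make_windows(170, 2, sp1)), 121L)

  expect_equal(nrow(make_windows(32, 2, sp)), 1L)  # n == window
  expect_error(make_windows(20, 2, sp), "exceeds")
  expect_error(window_spec(63, 4, 2), "integer multiples")
  expect_error(window_spec(4, 4, 2), "at least 3")
})

test_that("windowed FC returns the exact Pearson values", {
  sig <- rbind(c(1, 2, 3, 4), c(1, 3, 2, 4), c(1, 2, 3, 4) * -1 + 10,
               c(5, 5, 5, 5))
  b <- bold_series(sig, tr_s = 1)
  w <- data.frame(start = 1L, end = 4L)
  st <- windowed_fc(b, 1, "mask", w)
  # targets are vertices 2,3,4: r = 0.8, -1, undefined
  expect_equal(st[1, 1], 0.8, tolerance = 1e-12)
  expect_equal(st[1, 2], -1, tolerance = 1e-12)
  expect_true(is.na(st[1, 3]))

  ident <- bold_series(rbind(sig[1, ], sig[1, ], sig[2, ]), tr_s = 1)
  st2 <- windowed_fc(ident, 1, "mask", w)
  expect_equal(st2[1, 1], 1, tolerance = 1e-12)
})

test_that("Kendall's W honors its boundary cases and the brute-force oracle", {
  perfect <- matrix(rep(1:6, 4), 4, 6, byrow = TRUE)
  expect_equal(as.numeric(kendalls_w(perfect)), 1)

  reversed <- rbind(1:5, 5:1)
  expect_equal(as.numeric(kendalls_w(reversed)), 0)

  set.seed(99)
  for (i in 1:25) {
    k <- sample(2:8, 1); n <- sample(3:10, 1)
    m <- matrix(rnorm(k * n), k, n)
    if (i %% 3 == 0) m <- round(m, 1)  # force ties
    expect_equal(as.numeric(kendalls_w(m)), oracle_kendall_w(m),
                 tolerance = 1e-13)
  }

  allt <- matrix(1, 3, 4)
  expect_warning(w <- kendalls_w(allt), "tied")
  expect_true(is.na(w))
  expect_error(kendalls_w(matrix(1:4, 1)), "2 windows")
})

test_that("W is invariant to monotone transforms and permutations", {
  set.seed(123)
  m <- matrix(runif(6 * 8, -0.9, 0.9), 6, 8)
  w0 <- as.numeric(kendalls_w(m))
  expect_identical(as.numeric(kendalls_w(atanh(m))), w0)  # Fisher z
  expect_identical(as.numeric(kendalls_w(m[, sample(8)])), w0)
  expect_identical(as.numeric(kendalls_w(m[sample(6), ])), w0)
})

test_that("stability maps carry NA outside the mask and behave at the null", {
  set.seed(17)
  sig <- matrix(rnorm(162 * 170), 162, 170)
  b <- bold_series(sig, tr_s = 2)
  mask <- cortex_mask(c(rep(TRUE, 150), rep(FALSE, 12)))
  # non-overlapping windows: judges independent, E[W] = 1/k
  sp <- window_spec(40, 40, 2)   # 8 windows of 20 volumes
  sm <- stability_map(b, mask, sp, mode = "vertex_by_vertex")
  expect_true(all(is.na(sm$values[151:162])))
  v <- sm$values[1:150]
  expect_equal(mean(v), 1 / 8, tolerance = 0.02)
  # overlapping windows are dependent judges and inflate the null
  sp_ov <- window_spec(64, 4, 2)
  sm_ov <- stability_map(b, mask, sp_ov, mode = "vertex_by_vertex")
  expect_gt(mean(sm_ov$values[1:150]), 1 / 70 + 0.1)
})

test_that("coupled stationary parcels rank above the map median", {
  st <- fx_study()
  sub <- fx_subject()
  cfg <- run_config()
  sm <- subject_stability(sub$bold, sub$motion, st$mask, st$atlas, cfg)
  lab <- st$atlas$labels
  stationary <- which(!(lab %in% c(3, 5)))  # parcels without modulation
  expect_gt(mean(sm$values[stationary]), median(sm$values))
  expect_error(stability_map(sub$bold, st$mask,
                             window_spec(64, 4, 2),
                             mode = "vertex_by_atlas",
                             atlas = parcellation_atlas(rep(1L, 162))),
               "2 parcels")
})

test_that("z-scoring standardises within the mask and is idempotent", {
  mk <- function(v) structure(list(values = v, provenance = list()),
                              class = "stability_map")
  z <- zscore_map(mk(c(1, 2, 3)))
  expect_equal(z$values, c(-1, 0, 1))

  set.seed(3)
  v <- rnorm(162); v[1:5] <- NA
  m <- cortex_mask(c(rep(FALSE, 5), rep(TRUE, 157)))
  z1 <- zscore_map(mk(v), m)
  expect_equal(mean(z1$values[6:162]), 0, tolerance = 1e-10)
  expect_equal(sd(z1$values[6:162]), 1, tolerance = 1e-10)
  z2 <- zscore_map(z1, m)
  expect_equal(z2$values, z1$values, tolerance = 1e-10)

  expect_error(zscore_map(mk(rep(2, 10))), "constant|zero SD")
})
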