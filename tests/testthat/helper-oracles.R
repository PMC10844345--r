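# Independent reference implementations, coded from first principles and
# kept free of the package's internal code paths.

# Kendall's W from rank definitions: average ranks per judge, squared
# deviation of rank sums, standard per-judge tie correction.
oracle_kendall_w <- function(m) {
  k <- nrow(m); n <- ncol(m)
  R <- t(apply(m, 1, rank, ties.method = "average"))
  if (n == 1L) R <- t(R)
  Ri <- colSums(R)
  S <- sum((Ri - mean(Ri))^2)
  Tj <- apply(m, 1, function(x) {
    tt <- table(x)
    sum(tt^3 - tt)
  })
  den <- k^2 * (n^3 - n) - k * sum(Tj)
  if (den <= 0) return(NaN)
  12 * S / den
}

# Benjamini-Hochberg step-up from the definition: find the largest i with
# p_(i) <= i*q/m; adjusted values via the running minimum from the top.
oracle_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  run <- 1
  for (i in m:1) {
    run <- min(run, m * ps[i] / i)
    adj[i] <- run
  }
  rejected_sorted <- logical(m)
  thresh <- which(ps <= (seq_len(m) * q) / m)
  if (length(thresh)) rejected_sorted[seq_len(max(thresh))] <- TRUE
  out_adj <- numeric(m); out_rej <- logical(m)
  out_adj[o] <- adj; out_rej[o] <- rejected_sorted
  list(adjusted = out_adj, rejected = out_rej)
}

# Classical pooled-variance two-sample t (patient minus control).
oracle_two_sample_t <- function(x_pat, x_con) {
  n1 <- length(x_pat); n2 <- length(x_con)
  sp2 <- ((n1 - 1) * stats::var(x_pat) + (n2 - 1) * stats::var(x_con)) /
    (n1 + n2 - 2)
  (mean(x_pat) - mean(x_con)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Naive vertex-by-vertex stability: explicit loops over seeds and windows,
# cor() and rank() from base R, W from the oracle above.
naive_stability_vv <- function(signal, mask_logical, windows) {
  V <- nrow(signal)
  k <- nrow(windows)
  midx <- which(mask_logical)
  out <- rep(NA_real_, V)
  for (s in midx) {
    tgt <- setdiff(midx, s)
    stack <- matrix(NA_real_, k, length(tgt))
    for (w in seq_len(k)) {
      rows <- windows$start[w]:windows$end[w]
      stack[w, ] <- suppressWarnings(
        as.numeric(stats::cor(signal[s, rows], t(signal[tgt, rows]))))
    }
    keep <- colSums(!is.finite(stack)) == 0
    if (sum(keep) >= 2)
      out[s] <- oracle_kendall_w(stack[, keep, drop = FALSE])
  }
  out
}

# Connected suprathreshold components via igraph, independent of the
# package's BFS.
oracle_components <- function(supra, edges) {
  if (!length(supra)) return(list())
  keep <- edges[edges[, 1] %in% supra & edges[, 2] %in% supra, ,
                drop = FALSE]
  g <- igraph::graph_from_data_frame(
    as.data.frame(keep), directed = FALSE,
    vertices = data.frame(name = supra))
  comp <- igraph::components(g)
  lapply(seq_len(comp$no), function(i)
    sort(as.integer(names(comp$membership)[comp$membership == i])))
}

# Brute-force enumeration of valid full-window start indices.
oracle_window_starts <- function(n, window_vols, step_vols) {
  starts <- integer(0)
  s <- 1L
  while (s + window_vols - 1L <= n) {
    starts <- c(starts, s)
    s <- s + step_vols
  }
  starts
}
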