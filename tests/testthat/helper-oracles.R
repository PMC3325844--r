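# Independent brute-force oracles used to cross-check the implementation.
# These are written against the definitions, not against the package code.

# Step-up FDR adjustment, literal formulation: q_(i) = min_{j >= i} p_(j) m / j.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q[i] <- min(1, min(p[ord[js]] * m / js))
  }
  out <- numeric(m)
  out[ord] <- q
  out
}

# Exhaustive steady-window scan: for every sampled start, test every channel
# point against the window mean directly.
oracle_steady_scan <- function(trace, D, tol = 0.05, win = 4) {
  len <- win / D
  t <- trace$time_h
  channels <- list(trace$od600, trace$dissolved_o2, trace$co2_frac)
  ok <- function(i, j) {
    all(vapply(channels, function(x) {
      w <- x[i:j]
      m <- mean(w)
      m > 0 && all(abs(w / m - 1) <= tol)
    }, logical(1)))
  }
  steady_from <- NA_real_
  for (i in seq_along(t)) {
    if (t[i] + len > t[length(t)] + 1e-9) break
    j <- max(which(t <= t[i] + len))
    if (ok(i, j)) { steady_from <- t[i]; break }
  }
  # trailing window
  i0 <- min(which(t >= t[length(t)] - len - 1e-9))
  list(is_steady = ok(i0, length(t)), steady_from = steady_from)
}

# Cosine match factor written out directly over a dense m/z grid.
oracle_cosine <- function(a, b, lo = 1, hi = 1000) {
  va <- vb <- numeric(hi - lo + 1)
  va[as.integer(names(a)) - lo + 1] <- sqrt(a)
  vb[as.integer(names(b)) - lo + 1] <- sqrt(b)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# Piecewise-linear retention-index interpolation written independently.
oracle_ri <- function(rt, ladder) {
  vapply(rt, function(x) {
    k <- max(which(ladder$rt_min <= x))
    if (k == nrow(ladder)) return(100 * ladder$n[k])
    n0 <- ladder$n[k]; n1 <- ladder$n[k + 1]
    t0 <- ladder$rt_min[k]; t1 <- ladder$rt_min[k + 1]
    100 * (n0 + (n1 - n0) * (x - t0) / (t1 - t0))
  }, numeric(1))
}

# Direct filter pass over a DE result table (transcript rule).
oracle_transcript_filter <- function(results, fc = 2, alpha = 0.05) {
  up <- results$fold_change_signed > fc & results$adj_p_value < alpha
  down <- results$fold_change_signed < -fc & results$adj_p_value < alpha
  list(up = results$locus_tag[up], down = results$locus_tag[down])
}

# Table 1-anchored reference values used across physiology tests.
table1_reference <- function() {
  list(
    conditions = c("carbon", "dual", "nitrogen"),
    c0_n0 = c(5.83, 16.56, 26.97),
    y_xc = c(1.11, 1.16, 1.01),
    y_xn = c(9.80, 16.67, 17.74),
    borders = c(10.40, 20.50),
    cdw = c(1.46, 4.35, 4.63),
    pha_pct = c(25.78, 61.94, 80.58),
    q_pha_nitrogen = 0.43
  )
}

# Paths to the packaged study input tables.
extdata <- function(f) system.file("extdata", f, package = "phaomics")
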