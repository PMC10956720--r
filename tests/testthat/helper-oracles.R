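# Independent brute-force reference implementations used as oracles.
# Deliberately written as literal loops, sharing no code with the package.

# connected correlation: literal (i, j, t) triple loop over Eq-style sums
oracle_corr <- function(u, positions, breaks) {
  n <- nrow(u); Tn <- ncol(u)
  d <- as.matrix(dist(positions))
  nb <- length(breaks) - 1
  pair_sum <- numeric(nb); n_pairs <- integer(nb)
  C0 <- 0
  for (i in seq_len(n)) for (t in seq_len(Tn)) C0 <- C0 + u[i, t]^2
  C0 <- C0 / (n * Tn)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- 0
      for (b in seq_len(nb))
        if (d[i, j] > breaks[b] && d[i, j] <= breaks[b + 1]) k <- b
      if (k == 0) next
      s <- 0
      for (t in seq_len(Tn)) s <- s + u[i, t] * u[j, t]
      pair_sum[k] <- pair_sum[k] + s
      n_pairs[k] <- n_pairs[k] + 1L
    }
  }
  keep <- n_pairs > 0
  list(r = ((head(breaks, -1) + tail(breaks, -1)) / 2)[keep],
       C = (pair_sum[keep] / (n_pairs[keep] * Tn)) / C0,
       n_pairs = n_pairs[keep], C0 = C0)
}

# plain Pearson correlation per distance bin, pair loop with stats::cor
oracle_pearson <- function(sig, positions, breaks) {
  n <- nrow(sig)
  d <- as.matrix(dist(positions))
  nb <- length(breaks) - 1
  s <- numeric(nb); np <- integer(nb)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      k <- findInterval(d[i, j], breaks, left.open = TRUE)
      if (k < 1 || k > nb) next
      s[k] <- s[k] + cor(sig[i, ], sig[j, ])
      np[k] <- np[k] + 1L
    }
  }
  keep <- np > 0
  list(C = s[keep] / np[keep], n_pairs = np[keep])
}

# sliding low-percentile baseline, plain double loop
oracle_baseline <- function(x, w, p) {
  out <- numeric(length(x))
  for (t in seq_along(x)) {
    win <- if (t == 1) x[1] else x[max(1, t - w):(t - 1)]
    thr <- quantile(win, p, names = FALSE)
    r0 <- mean(win[win <= thr])
    out[t] <- (x[t] - r0) / r0
  }
  out
}

# centered running median with shrinking edges, plain loop
oracle_runmed <- function(x, w) {
  n <- length(x)
  lo <- (w - 1) %/% 2; hi <- w %/% 2
  sapply(seq_len(n), function(t) median(x[max(1, t - lo):min(n, t + hi)]))
}

# zero crossing by dense linear resampling of the tabulated curve
oracle_root <- function(r, C, res = 1e5) {
  g <- seq(min(r), max(r), length.out = res)
  y <- approx(r, C, xout = g)$y
  i <- which(y[-length(y)] * y[-1] < 0)[1]
  g[i] - y[i] * (g[i + 1] - g[i]) / (y[i + 1] - y[i])
}

# dense trapezoid quadrature of the xi ratio and chi on a resampled grid
oracle_xi_chi <- function(r, C, r0, res = 2e5) {
  g <- seq(0, r0, length.out = res)
  y <- approx(c(0, r, r0), c(0, C, 0), xout = g)$y
  tz <- function(f) sum(diff(g) * (head(f, -1) + tail(f, -1)) / 2)
  list(xi = sqrt(tz(g^2 * y) / tz(y)), chi = tz(y))
}

# rejection sampler for the truncated exponential-distance offset law
oracle_offset_sample <- function(n, R0, Ic, seed) {
  set.seed(seed)
  out <- numeric(0)
  while (length(out) < n) {
    dx <- sample(-Ic:Ic, n, replace = TRUE)
    dy <- sample(-Ic:Ic, n, replace = TRUE)
    r <- sqrt(dx^2 + dy^2)
    ok <- r > 0 & r <= Ic & runif(n) < exp(-r / R0)
    out <- c(out, r[ok])
  }
  out[seq_len(n)]
}
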