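test_that("running-median smoothing matches a literal sliding-median loop", {
  set.seed(51)
  x <- matrix(rnorm(3 * 80), 3, 80)
  expect_identical(smooth_time(x, 1), x)
  cst <- matrix(2, 2, 30)
  expect_equal(smooth_time(cst, 8), cst)
  for (w in c(3, 8, 20)) {
    got <- smooth_time(x, w)
    for (i in 1:3)
      expect_equal(got[i, ], oracle_runmed(x[i, ], w), tolerance = 1e-12)
  }
  expect_error(smooth_time(x, 81), "longer than")
})

test_that("window enumeration honours the half-open square and the 5-unit rule", {
  pos <- cbind(c(0, 1, 2, 3, 4, 10), c(0, 1, 2, 3, 4, 10))
  # one big window holding everything
  wins <- enumerate_windows(pos, L = 11, stride = 1)
  expect_length(wins, 1)
  expect_equal(wins[[1]]$members, 1:6)
  # [0,5)^2 holds 5 units (kept); [0.5,4.5)^2 holds 4 (dropped)
  wins5 <- enumerate_windows(pos, L = 5, stride = 0.5)
  counts <- vapply(wins5, function(w) length(w$members), integer(1))
  expect_true(all(counts >= 5))
  expect_true(any(vapply(wins5, function(w) setequal(w$members, 1:5),
                         logical(1))))
  for (w in wins5) {
    p <- pos[w$members, , drop = FALSE]
    expect_true(all(p[, 1] >= w$origin[1] & p[, 1] < w$origin[1] + w$side))
    expect_true(all(p[, 2] >= w$origin[2] & p[, 2] < w$origin[2] + w$side))
  }
})

test_that("population-mean subtraction removes the common mode exactly", {
  set.seed(52)
  sig <- matrix(rnorm(40), 4, 10)
  u <- subtract_population_mean(sig)
  expect_true(all(abs(colSums(u)) < 1e-12))
  u2 <- subtract_population_mean(sig[1:2, ])
  expect_equal(u2[1, ], -u2[2, ])
  same <- matrix(rep(rnorm(10), each = 3), 3, 10)
  expect_true(all(abs(subtract_population_mean(same)) < 1e-12))
  expect_error(subtract_population_mean(sig[1, , drop = FALSE]), "2 units")
})

test_that("connected correlation equals the literal triple-loop oracle", {
  set.seed(53)
  for (k in 1:10) {
    n <- sample(5:20, 1); Tn <- sample(10:40, 1)
    pos <- cbind(runif(n, 0, 50), runif(n, 0, 50))
    u <- subtract_population_mean(matrix(rnorm(n * Tn), n, Tn))
    br <- seq(0, 80, by = 8)
    got <- correlation_vs_distance(u, pos, br)
    ref <- oracle_corr(u, pos, br)
    expect_equal(got$C, ref$C, tolerance = 1e-10)
    expect_equal(got$n_pairs, as.numeric(ref$n_pairs))
    expect_equal(got$C0, ref$C0, tolerance = 1e-12)
  }
})

test_that("independent units sit on the -1/(N-1) mean-subtraction floor", {
  set.seed(54)
  n <- 10; Tn <- 20000
  pos <- cbind(runif(n, 0, 10), runif(n, 0, 10))
  u <- subtract_population_mean(matrix(rnorm(n * Tn), n, Tn))
  cf <- correlation_vs_distance(u, pos, breaks = c(0, 20))
  se <- 1 / sqrt(cf$n_pairs * Tn)
  expect_lt(abs(cf$C[1] - (-1 / (n - 1))), 3 * se)
})

test_that("zero crossing: exact on linear data, dense-grid oracle on noisy data", {
  r <- seq(0.25, 10, by = 0.25)
  zc <- zero_crossing(make_cf(r, 1 - r / 5))
  expect_equal(zc$r0, 5, tolerance = 1e-9)
  expect_equal(zc$slope, -1 / 5, tolerance = 1e-9)
  set.seed(55)
  C <- exp(-r / 2) - 0.25 + rnorm(length(r), 0, 0.01)
  cf <- make_cf(r, C)
  zc2 <- zero_crossing(cf)
  expect_lt(abs(zc2$r0 - oracle_root(r, C)), 0.25)  # within one bin width
  # monotone positive curve: crossing undefined, flagged not thrown
  none <- zero_crossing(make_cf(r, 1 + r))
  expect_false(none$defined)
  expect_true(is.na(none$r0))
})

test_that("binning refinement moves the crossing by less than one coarse bin", {
  f <- function(r) exp(-r / 3) - 0.3
  r1 <- seq(0.5, 12, by = 1); r2 <- seq(0.25, 12, by = 0.5)
  z1 <- zero_crossing(make_cf(r1, f(r1)))$r0
  z2 <- zero_crossing(make_cf(r2, f(r2)))$r0
  expect_lt(abs(z1 - z2), 1)
})

test_that("trial shuffling conserves per-unit trial multisets; degenerate case is identity", {
  rec <- small_recording(seed = 56, n_stim = 2, rep_per_stim = 3)
  sh <- trial_shuffle(rec, seed = 1)
  tt <- rec$trial_table
  for (i in seq_len(nrow(rec$signals))) {
    for (s in unique(tt$stimulus)) {
      rows <- which(tt$stimulus == s)
      segs <- function(sig) lapply(rows, function(k)
        round(sig[i, (tt$onset[k] + 1):tt$offset[k]], 10))
      expect_setequal(segs(rec$signals), segs(sh$signals))
    }
  }
  # one repetition per stimulus: nothing to permute
  rec1 <- small_recording(seed = 57, n_stim = 3, rep_per_stim = 1)
  expect_identical(trial_shuffle(rec1, seed = 2)$signals, rec1$signals)
  expect_false(identical(sh$signals, rec$signals))
})

test_that("position shuffling permutes positions and conserves the distance multiset", {
  rec <- small_recording(seed = 58)
  sh <- position_shuffle(rec, seed = 3)
  expect_identical(sh$signals, rec$signals)
  expect_setequal(unname(split(unname(sh$positions), row(sh$positions))),
                  unname(split(unname(rec$positions), row(rec$positions))))
  expect_equal(sort(as.vector(dist(sh$positions))),
               sort(as.vector(dist(rec$positions))))
})

test_that("plain Pearson variant matches a pairwise cor() loop and flags flat units", {
  set.seed(59)
  n <- 12; Tn <- 30
  pos <- cbind(runif(n, 0, 40), runif(n, 0, 40))
  sig <- matrix(rnorm(n * Tn), n, Tn)
  br <- seq(0, 60, 10)
  got <- pearson_vs_distance(sig, pos, br)
  ref <- oracle_pearson(sig, pos, br)
  expect_equal(got$C, ref$C, tolerance = 1e-10)
  sig[3, ] <- 1
  expect_warning(pearson_vs_distance(sig, pos, br), "zero-variance")
})

test_that("windowed fast path equals the composed window-by-window computation", {
  set.seed(60)
  n <- 40; Tn <- 50
  pos <- cbind(runif(n, 0, 100), runif(n, 0, 100))
  sig <- matrix(rnorm(n * Tn), n, Tn)
  br <- seq(0, 150, 10)
  L <- 60; stride <- 20
  fast <- windowed_correlation(sig, pos, L, stride, br)
  wins <- enumerate_windows(pos, L, stride)
  slow <- average_over_windows(lapply(wins, function(w) {
    u <- subtract_population_mean(sig[w$members, , drop = FALSE])
    correlation_vs_distance(u, pos[w$members, , drop = FALSE], br, L = L)
  }))
  expect_equal(fast$C, slow$C, tolerance = 1e-10)
  expect_equal(fast$n_pairs, slow$n_pairs)
  # sparse input takes the sparse code path and agrees with dense
  sp <- Matrix::Matrix(round(abs(sig)) * (abs(sig) > 1.2), sparse = TRUE)
  f_sp <- windowed_correlation(sp, pos, L, stride, br)
  f_de <- windowed_correlation(as.matrix(sp), pos, L, stride, br)
  expect_equal(f_sp$C, f_de$C, tolerance = 1e-10)
})

test_that("C++ pair-binning kernels agree with plain R binning", {
  set.seed(61)
  n <- 150
  pos <- cbind(runif(n, 0, 30), runif(n, 0, 30))
  a <- rnorm(n)
  br <- seq(0, 45, 1.5)
  st <- corrscale:::pair_bin_stats_cpp(pos[, 1], pos[, 2], a, br)
  d <- as.matrix(dist(pos)); iu <- which(upper.tri(d))
  b <- findInterval(d[iu], br, left.open = TRUE)
  expect_equal(st$count, as.numeric(tabulate(b, length(br) - 1)))
  asum_ref <- sapply(seq_len(length(br) - 1), function(k)
    sum(outer(a, a, `+`)[iu][b == k]))
  expect_equal(st$asum, asum_ref, tolerance = 1e-10)
  V <- tcrossprod(matrix(rnorm(n * 10), n))
  vs <- corrscale:::matrix_bin_sums_cpp(V, pos[, 1], pos[, 2], br)
  vs_ref <- sapply(seq_len(length(br) - 1), function(k) sum(V[iu][b == k]))
  expect_equal(vs, vs_ref, tolerance = 1e-8)
  Vs <- methods::as(Matrix::Matrix(V * (abs(V) > 1), sparse = TRUE),
                    "generalMatrix")
  tr <- Matrix::summary(Vs)
  ts <- corrscale:::triplet_bin_sums_cpp(tr$i, tr$j, tr$x,
                                         pos[, 1], pos[, 2], br)
  Vd <- as.matrix(Vs)
  ts_ref <- sapply(seq_len(length(br) - 1), function(k) sum(Vd[iu][b == k]))
  expect_equal(ts, ts_ref, tolerance = 1e-8)
})

test_that("window averaging is an identity for one window and pools by pair count", {
  set.seed(62)
  cf <- make_cf(seq(0.5, 9.5, 1), rnorm(10))
  expect_identical(average_over_windows(list(cf)), cf)
  avg2 <- average_over_windows(list(cf, cf))
  expect_equal(avg2$C, cf$C)
  # unequal pair counts: pooled mean, not plain mean
  cf2 <- make_cf(seq(0.5, 9.5, 1), rnorm(10), n_pairs = rep(30L, 10))
  avg <- average_over_windows(list(cf, cf2))
  expect_equal(avg$C, (cf$C * 10 + cf2$C * 30) / 40, tolerance = 1e-12)
  cf3 <- make_cf(seq(1, 19, 2), rnorm(10))
  expect_error(average_over_windows(list(cf, cf3)), "inconsistent")
})
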