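test_that("correlation length reproduces closed forms and the dense quadrature", {
  nb <- 100
  R <- 5
  r <- seq(R / (2 * nb), R * 1.2, length.out = round(1.2 * nb))
  # constant C on (0, R]: xi = R / sqrt(3)
  cf_const <- make_cf(r, ifelse(r <= R, 1, -0.2))
  expect_equal(correlation_length(cf_const, r0 = R), R / sqrt(3),
               tolerance = 0.01)
  # linear C = 1 - r/R: xi = R / sqrt(6), chi = R / 2
  cf_lin <- make_cf(r, 1 - r / R)
  expect_equal(correlation_length(cf_lin, r0 = R), R / sqrt(6),
               tolerance = 0.01)
  expect_equal(susceptibility(cf_lin, r0 = R), R / 2, tolerance = 0.01)
  # noisy tabulated curve against a fine-grid quadrature oracle
  set.seed(71)
  C <- exp(-r / 2) - 0.2 + rnorm(length(r), 0, 0.005)
  cf <- make_cf(r, C)
  r0 <- zero_crossing(cf)$r0
  ref <- oracle_xi_chi(r[r < r0], C[r < r0], r0)
  expect_equal(correlation_length(cf, r0), ref$xi, tolerance = 0.01)
  expect_equal(susceptibility(cf, r0), ref$chi, tolerance = 0.01)
})

test_that("xi stays below r0 and both scale linearly under distance rescaling", {
  set.seed(72)
  for (k in 1:20) {
    r <- seq(0.1, 12, length.out = 80)
    C <- exp(-r / runif(1, 1, 4)) - runif(1, 0.1, 0.4)
    cf <- make_cf(r, C)
    zc <- zero_crossing(cf)
    if (!zc$defined) next
    xi <- correlation_length(cf, zc$r0)
    expect_lt(xi, zc$r0)
    # unit covariance: rescale all distances by 3
    cf3 <- make_cf(r * 3, C)
    zc3 <- zero_crossing(cf3)
    expect_equal(zc3$r0, 3 * zc$r0, tolerance = 1e-6)
    expect_equal(correlation_length(cf3, zc3$r0), 3 * xi, tolerance = 1e-3)
  }
})

test_that("gamma and Delta are invariant under global distance rescaling", {
  fam <- make_scaling_family(0.4)
  fam3 <- lapply(fam, function(cf) make_cf(cf$r * 3, cf$C, L = cf$L * 3))
  g1 <- gamma_estimate(fam); g3 <- gamma_estimate(fam3)
  expect_equal(g1$gamma, g3$gamma, tolerance = 1e-6)
  d1 <- collapse_curves(fam, g1$gamma_signed)
  d3 <- collapse_curves(fam3, g3$gamma_signed)
  expect_equal(d1$Delta_shape, d3$Delta_shape, tolerance = 1e-6)
})

test_that("collapse exponent recovery on constructed scaling families", {
  # L-independent rescaled curves with L-independent derivative: gamma = 0
  fam0 <- make_scaling_family(0)
  g0 <- gamma_estimate(fam0)
  expect_lt(abs(g0$gamma), 0.02)
  # amplitude decaying as r0^-0.5: gamma recovered near 0.5
  fam <- make_scaling_family(0.5)
  g <- gamma_estimate(fam)
  expect_equal(g$gamma, 0.5, tolerance = 0.05)
  expect_equal(g$gamma_signed, 0.5, tolerance = 0.05)
  # growing amplitudes give the mirrored signed exponent
  famg <- make_scaling_family(-0.5)
  gg <- gamma_estimate(famg)
  expect_equal(gg$gamma_signed, -0.5, tolerance = 0.05)
  expect_equal(gg$gamma, 0.5, tolerance = 0.05)
})

test_that("collapse error vanishes for a perfect family and flags misfits", {
  fam <- make_scaling_family(0)
  clp <- collapse_curves(fam, 0)
  expect_lt(clp$Delta, 1e-10)
  fam5 <- make_scaling_family(0.5)
  g <- gamma_estimate(fam5)
  clp5 <- collapse_curves(fam5, g$gamma_signed)
  expect_lt(clp5$Delta_shape, 1e-3)
  # wrong exponent degrades the collapse
  bad <- collapse_curves(fam5, g$gamma_signed - 1.5)
  expect_gt(bad$Delta, 10 * clp5$Delta)
  expect_error(collapse_curves(fam5, 0.5, L_min = 1e6), "at least 2 curves")
})

test_that("linearity statistic is exact on a line and calibrated under its null", {
  L <- seq(20, 120, by = 20)
  lin <- suppressWarnings(linear_scaling_test(L, 0.4 * L))
  expect_lt(lin$chi2, 1e-20)
  expect_equal(lin$p_upper, 1)
  # calibration: homoskedastic Gaussian scatter with variance equal to the
  # regression level R ~= 100 makes chi_c^2 follow chisq(n - 2)
  set.seed(73)
  n <- 10
  Lc <- seq(1, 10, length.out = n)
  R_true <- 100 + 0.2 * Lc
  stats <- replicate(1000, {
    xi <- R_true + rnorm(n, 0, sqrt(100))
    linear_scaling_test(Lc, xi)$chi2
  })
  ks <- suppressWarnings(ks.test(stats, pchisq, df = n - 2))
  expect_gt(ks$p.value, 0.01)
  expect_error(linear_scaling_test(c(1, 2), c(1, 2)), "at least 3")
})

test_that("xi/r0 proportionality diagnostic: closed form and violation flag", {
  # linear family C = 1 - r/(0.5 L): xi/r0 = 1/sqrt(6) at every L
  Ls <- c(10, 20, 40)
  r0s <- xis <- numeric(3)
  for (i in seq_along(Ls)) {
    R <- 0.5 * Ls[i]
    r <- seq(R / 200, 1.2 * R, length.out = 240)
    cf <- make_cf(r, 1 - r / R, L = Ls[i])
    r0s[i] <- zero_crossing(cf)$r0
    xis[i] <- correlation_length(cf, r0s[i])
  }
  rat <- xi_r0_ratio(Ls, xis, r0s)
  expect_equal(mean(rat$ratio), 1 / sqrt(6), tolerance = 0.01)
  expect_lt(rat$cv, 0.01)
  expect_false(rat$violated)
  bad <- xi_r0_ratio(Ls, c(1, 3, 10), c(5, 10, 20), tol = 0.1)
  expect_true(bad$violated)
})

test_that("saturating xi(L) is separated from linear growth by the slope ratio", {
  L <- c(10, 20, 40, 60, 80, 100)
  expect_equal(xi_saturation_ratio(L, 0.3 * L), 1, tolerance = 1e-9)
  xi_sat <- 8 * (1 - exp(-L / 15))   # saturates around L ~ 45
  expect_lt(xi_saturation_ratio(L, xi_sat), 0.5)
})
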