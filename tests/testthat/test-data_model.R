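test_that("recording container round-trips bit-exactly and deterministically", {
  rec <- small_recording(seed = 3)
  p1 <- file.path(tempdir(), "rt1")
  write_recording(rec, p1)
  back <- read_recording(p1)
  expect_identical(back$signals, rec$signals)
  expect_identical(back$positions[, 1], unname(rec$positions[, 1]))
  expect_equal(back$trial_table, rec$trial_table)
  expect_equal(back$sample_rate, rec$sample_rate)
  expect_equal(back$modality, rec$modality)
  # write/read/write: second container byte-identical to the first
  p2 <- file.path(tempdir(), "rt2")
  write_recording(back, p2)
  for (f in c("positions.csv", "signals.csv", "trials.csv", "meta.json"))
    expect_identical(readLines(file.path(p1, f)), readLines(file.path(p2, f)))
})

test_that("integer rasters and empty trial tables survive the container", {
  sig <- matrix(rpois(12, 2), 3, 4)
  storage.mode(sig) <- "integer"
  rec <- population_recording(1:3, cbind(0:2, 0:2), sig, 1)
  p <- file.path(tempdir(), "int_rec")
  write_recording(rec, p)
  back <- read_recording(p)
  expect_identical(back$signals, sig)
  expect_equal(nrow(back$trial_table), 0L)
})

test_that("malformed containers and inconsistent shapes are rejected", {
  expect_error(population_recording(1:4, cbind(0:2, 0:2),
                                    matrix(0, 4, 5), 30),
               "position rows")
  expect_error(population_recording(1:3, cbind(0:2, 0:2),
                                    matrix(0, 4, 5), 30),
               "signal rows")
  tt <- data.frame(onset = 0L, offset = 99L, stimulus = "a", epoch = "stim_on")
  expect_error(population_recording(1:3, cbind(0:2, 0:2),
                                    matrix(0, 3, 5), 30, tt),
               "onset < offset")
  p <- file.path(tempdir(), "broken")
  rec <- small_recording()
  write_recording(rec, p)
  unlink(file.path(p, "positions.csv"))
  expect_error(read_recording(p), "missing member")
})

test_that("dR/R0 baseline normalisation matches its sliding-window oracle", {
  # constant trace: baseline equals the signal everywhere
  const <- matrix(5, 1, 60)
  expect_equal(baseline_normalize(const, 10), matrix(0, 1, 60))
  # ratio invariance under multiplicative rescaling
  set.seed(11)
  x <- matrix(abs(rnorm(100, 10, 1)), 1, 100)
  expect_equal(baseline_normalize(x, 40), baseline_normalize(7.3 * x, 40),
               tolerance = 1e-12)
  # transient trace against the independent double-loop oracle
  tr <- 10 + c(rep(0, 40), 8 * exp(-(1:20) / 5), rep(0, 40)) +
    rnorm(100, 0, 0.05)
  got <- baseline_normalize(matrix(tr, 1), 40)
  expect_equal(as.numeric(got), oracle_baseline(tr, 40, 0.10),
               tolerance = 1e-12)
  expect_error(baseline_normalize(matrix(0:9, 1), 5), "R0 = 0")
})

test_that("variance/mean ratio: zero-variance, hand-checked, and Poisson cases", {
  tbl <- array(2, dim = c(2, 1, 5))
  expect_equal(unname(variance_mean_ratio(tbl)), c(0, 0))
  # one unit, responses {2, 4, 6}: var 4, mean 4, ratio 1
  tbl <- array(c(2, 4, 6), dim = c(1, 1, 3))
  expect_equal(unname(variance_mean_ratio(tbl)), var(c(2, 4, 6)) / 4)
  # Poisson counts converge to the ratio-1 reference line
  set.seed(5)
  n_rep <- 4000
  counts <- array(rpois(3 * n_rep, lambda = 6), dim = c(3, 1, n_rep))
  r <- variance_mean_ratio(counts)
  se <- sqrt(2 / n_rep)  # var of ratio estimate ~ 2/n for Poisson
  expect_true(all(abs(r - 1) < 3 * se))
  expect_error(variance_mean_ratio(array(1, c(2, 2, 1))), "2 repetitions")
})

test_that("direction selectivity index and its bounds", {
  dirs <- seq(0, 315, by = 45)
  resp <- array(0, dim = c(2, 8, 3))
  resp[1, 1, ] <- 2            # unit 1: responds only at 0 deg
  resp[2, , ] <- 1             # unit 2: flat tuning
  d <- direction_selectivity(resp, dirs)
  expect_equal(d$dsi, c(1, 0))
  expect_equal(d$pref_direction[1], 0)
  # non-negative responses keep DSI in [0, 1]
  set.seed(8)
  arr <- array(runif(5 * 8 * 4), dim = c(5, 8, 4))
  d2 <- direction_selectivity(arr, dirs)
  expect_true(all(d2$dsi >= 0 & d2$dsi <= 1))
  expect_error(direction_selectivity(arr, dirs + c(0, 1, rep(0, 6))),
               "opposite pairs")
})

test_that("ISI-shuffle significance separates tuned from untuned spiking", {
  set.seed(21)
  dirs <- seq(0, 315, by = 45)
  onset <- seq(0L, by = 40L, length.out = 40L)
  tt <- data.frame(onset = onset, offset = onset + 20L,
                   stimulus = rep(paste0("d", dirs), 5), epoch = "stim_on")
  nf <- max(tt$offset) + 20L
  sig <- matrix(rpois(2 * nf, 0.3), 2, nf)   # ongoing firing everywhere
  for (k in which(tt$stimulus == "d0")) {
    fr <- (tt$onset[k] + 1):tt$offset[k]
    sig[1, fr] <- sig[1, fr] + rpois(length(fr), 1.0)  # unit 1 tuned to 0
  }
  rec <- population_recording(1:2, cbind(c(0, 10), c(0, 10)), sig, 30, tt)
  res <- dsi_significance(rec, setNames(dirs, paste0("d", dirs)),
                          n_shuffle = 200, seed = 4)
  expect_gt(res$dsi[1], 0.5)
  expect_lt(res$p_value[1], 0.05)     # tuning survives the ISI-shuffle null
  expect_gt(res$p_value[2], 0.2)      # untuned unit does not
  expect_true(all(res$p_value >= 0 & res$p_value <= 1, na.rm = TRUE))
})

test_that("trial_responses arranges epoch means by stimulus and repetition", {
  rec <- small_recording(seed = 2)
  tbl <- trial_responses(rec)
  expect_equal(dim(tbl), c(8, 2, 3))
  k <- which(rec$trial_table$stimulus == "s1")[1]
  fr <- (rec$trial_table$onset[k] + 1):rec$trial_table$offset[k]
  expect_equal(tbl[3, "s1", 1], mean(rec$signals[3, fr]))
})
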