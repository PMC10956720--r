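# Small in-code fixtures shared across the suite.

make_cf <- function(r, C, L = max(r), n_pairs = rep(10L, length(r))) {
  w <- diff(r[1:2])
  structure(list(L = L, r = r, C = C, n_pairs = n_pairs, C0 = 1,
                 breaks = c(r - w / 2, max(r) + w / 2), n_frames = 1L,
                 n_windows = 1L),
            class = "correlation_function")
}

# family obeying C(r, L) = F(r / r0) * r0^(-gamma) with r0 proportional to L
make_scaling_family <- function(gamma, Ls = c(10, 20, 40, 80),
                                r0_frac = 0.5, n_bins = 120,
                                F_fun = function(x) cos(pi * x / 2)) {
  fam <- list()
  for (L in Ls) {
    r0 <- r0_frac * L
    r <- seq(1.2 * r0 / n_bins, 1.2 * r0, length.out = n_bins)
    fam[[as.character(L)]] <- make_cf(r, F_fun(r / r0) * r0^(-gamma), L = L)
  }
  fam
}

small_recording <- function(n_units = 8, n_frames = 60, seed = 1,
                            n_stim = 2, rep_per_stim = 3, trial_len = 10) {
  set.seed(seed)
  pos <- cbind(x = runif(n_units, 0, 100), y = runif(n_units, 0, 100))
  sig <- matrix(rnorm(n_units * n_frames), n_units, n_frames)
  n_tr <- n_stim * rep_per_stim
  stopifnot(n_tr * trial_len <= n_frames)
  onset <- (seq_len(n_tr) - 1L) * trial_len
  tt <- data.frame(onset = onset, offset = onset + trial_len,
                   stimulus = rep(paste0("s", seq_len(n_stim)), rep_per_stim),
                   epoch = "stim_on", stringsAsFactors = FALSE)
  population_recording(seq_len(n_units), pos, sig, 30, tt, "test")
}
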