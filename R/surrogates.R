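#' Specification of a surrogate population
#'
#' Describes a spatially positioned population whose residual fluctuations
#' are a stationary Gaussian field with exponential spatial covariance
#' `variance * exp(-d / lambda)`, optionally riding on a stimulus-locked
#' common signal shared by every unit.
#'
#' @param n_units number of units, placed uniformly in the square.
#' @param area_side side of the square arena (micrometres).
#' @param lambda spatial correlation scale of the residual field (um).
#' @param variance residual variance per unit.
#' @param common_amplitude amplitude multiplying the per-stimulus common
#'   waveform (0 disables common input).
#' @param n_stimuli number of distinct stimuli.
#' @param n_repeats repetitions per stimulus.
#' @param frames_per_trial frames in each trial epoch.
#' @param gap_frames silent frames between trials (default 0).
#' @param noise_sd sd of i.i.d. per-unit measurement noise.
#' @param sample_rate sampling rate in Hz.
#' @param seed RNG seed.
#' @return a `surrogate_spec` list.
#' @export
surrogate_spec <- function(n_units = 60L, area_side = 400, lambda = 10,
                           variance = 1, common_amplitude = 0,
                           n_stimuli = 4L, n_repeats = 10L,
                           frames_per_trial = 20L, gap_frames = 0L,
                           noise_sd = 0, sample_rate = 30, seed = 1L) {
  if (lambda <= 0) stop("lambda must be positive")
  if (variance < 0) stop("variance must be non-negative")
  structure(list(n_units = as.integer(n_units), area_side = area_side,
                 lambda = lambda, variance = variance,
                 common_amplitude = common_amplitude,
                 n_stimuli = as.integer(n_stimuli),
                 n_repeats = as.integer(n_repeats),
                 frames_per_trial = as.integer(frames_per_trial),
                 gap_frames = as.integer(gap_frames),
                 noise_sd = noise_sd, sample_rate = sample_rate,
                 seed = as.integer(seed)),
            class = "surrogate_spec")
}

# Cholesky factor of the exponential kernel with a small diagonal jitter
# for numerical positive semi-definiteness.
kernel_chol <- function(positions, lambda, variance, jitter = 1e-10) {
  d <- as.matrix(stats::dist(positions))
  K <- variance * exp(-d / lambda)
  diag(K) <- diag(K) + jitter
  ch <- tryCatch(chol(K), error = function(e)
    stop("kernel factorization failed even with jitter: ", conditionMessage(e)))
  ch
}

#' Gaussian-field population with known correlation scale
#'
#' Places `n_units` uniformly at random in the square arena and draws
#' zero-mean stationary time series whose pairwise covariance follows
#' `variance * exp(-d / lambda)`. Serves as a parameter-recovery oracle
#' for the correlation estimators: the imposed scale `lambda` is the
#' ground truth the downstream correlation length must track.
#'
#' @param spec a `surrogate_spec` (its common-input fields are ignored
#'   here; use [evoked_surrogate()] for trial structure with common
#'   input).
#' @param n_frames total frames to draw (default: trials x frames).
#' @return a `population_recording` with an all-covering single trial.
#' @export
gaussian_field_population <- function(spec,
                                      n_frames = spec$n_stimuli *
                                        spec$n_repeats * spec$frames_per_trial) {
  set.seed(spec$seed)
  pos <- cbind(x = runif(spec$n_units, 0, spec$area_side),
               y = runif(spec$n_units, 0, spec$area_side))
  ch <- kernel_chol(pos, spec$lambda, spec$variance)
  z <- matrix(rnorm(spec$n_units * n_frames), spec$n_units, n_frames)
  sig <- crossprod(ch, z)   # t(ch) %*% z: rows get the kernel covariance
  if (spec$noise_sd > 0)
    sig <- sig + matrix(rnorm(length(sig), sd = spec$noise_sd),
                        nrow = nrow(sig))
  tt <- data.frame(onset = 0L, offset = n_frames, stimulus = "field",
                   epoch = "stim_on", stringsAsFactors = FALSE)
  population_recording(seq_len(spec$n_units), pos, sig, spec$sample_rate,
                       tt, modality = "gaussian_field")
}

# default stimulus waveform: half-sine bump over the trial epoch
default_waveform <- function(frames_per_trial, stimulus_index) {
  stimulus_index * sin(pi * seq_len(frames_per_trial) / (frames_per_trial + 1))
}

#' Trial-structured evoked surrogate with common input
#'
#' Builds a recording of repeated stimulus presentations in randomized
#' order. Each trial's signal is a stimulus-locked waveform identical
#' across units (the common input), plus a spatially correlated
#' Gaussian-field residual, plus i.i.d. unit noise. With
#' `common_amplitude = 0` the output is an exact trial-structured
#' Gaussian-field population; with zero variance and noise it is pure
#' common input, which the population-mean subtraction removes entirely.
#'
#' @param spec a `surrogate_spec`.
#' @param waveforms optional list (one numeric vector of length
#'   `frames_per_trial` per stimulus); defaults to half-sine bumps with
#'   stimulus-dependent amplitude.
#' @return a `population_recording` with trial table in presentation
#'   order (`epoch = "stim_on"` during trials, gaps unlabeled).
#' @export
evoked_surrogate <- function(spec, waveforms = NULL) {
  set.seed(spec$seed)
  pos <- cbind(x = runif(spec$n_units, 0, spec$area_side),
               y = runif(spec$n_units, 0, spec$area_side))
  n_trials <- spec$n_stimuli * spec$n_repeats
  period <- spec$frames_per_trial + spec$gap_frames
  n_frames <- n_trials * period
  if (is.null(waveforms))
    waveforms <- lapply(seq_len(spec$n_stimuli), function(s)
      default_waveform(spec$frames_per_trial, s))
  stopifnot(all(vapply(waveforms, length, 1L) == spec$frames_per_trial))
  order_seq <- sample(rep(seq_len(spec$n_stimuli), spec$n_repeats))
  sig <- matrix(0, spec$n_units, n_frames)
  if (spec$variance > 0) {
    ch <- kernel_chol(pos, spec$lambda, spec$variance)
    z <- matrix(rnorm(spec$n_units * n_frames), spec$n_units, n_frames)
    sig <- crossprod(ch, z)
  }
  if (spec$noise_sd > 0)
    sig <- sig + matrix(rnorm(length(sig), sd = spec$noise_sd),
                        nrow = nrow(sig))
  onset <- (seq_len(n_trials) - 1L) * period
  for (k in seq_len(n_trials)) {
    fr <- onset[k] + seq_len(spec$frames_per_trial)
    sig[, fr] <- sig[, fr] +
      rep(spec$common_amplitude * waveforms[[order_seq[k]]],
          each = spec$n_units)
  }
  tt <- data.frame(onset = onset, offset = onset + spec$frames_per_trial,
                   stimulus = paste0("stim", order_seq), epoch = "stim_on",
                   stringsAsFactors = FALSE)
  population_recording(seq_len(spec$n_units), pos, sig, spec$sample_rate,
                       tt, modality = "evoked_surrogate")
}
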