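#' Baseline-normalise fluorescence traces (dR/R0)
#'
#' For each unit and frame t, the baseline R0(t) is the mean of the samples
#' lying at or below the `percentile` quantile of the raw trace inside the
#' window of `window_frames` frames preceding t (frames t-window_frames ..
#' t-1). During the warm-up, when fewer than `window_frames` frames
#' precede t, all available preceding frames are used; for the very first
#' frame the frame itself serves as its own baseline. The output is
#' (R - R0) / R0.
#'
#' @param raw numeric matrix, units x frames, strictly measured signal.
#' @param window_frames sliding-window length in frames (default 40,
#'   i.e. 1.3 s at 30 Hz).
#' @param percentile quantile defining "low" samples (default 0.10).
#' @return matrix of the same shape holding dR/R0.
#' @export
baseline_normalize <- function(raw, window_frames = 40L, percentile = 0.10) {
  raw <- as.matrix(raw)
  nf <- ncol(raw)
  if (window_frames < 2) stop("window_frames must be >= 2")
  if (nf <= window_frames)
    stop("need more frames (", nf, ") than window_frames (", window_frames, ")")
  out <- matrix(NA_real_, nrow(raw), nf)
  for (i in seq_len(nrow(raw))) {
    x <- raw[i, ]
    for (t in seq_len(nf)) {
      w <- if (t == 1L) x[1L] else x[max(1L, t - window_frames):(t - 1L)]
      thr <- quantile(w, percentile, names = FALSE)
      r0 <- mean(w[w <= thr])
      if (r0 == 0)
        stop("division error: baseline R0 = 0 at unit ", i, ", frame ", t)
      out[i, t] <- (x[t] - r0) / r0
    }
  }
  dimnames(out) <- dimnames(raw)
  out
}

#' Trial-response table from a recording
#'
#' Collapses each trial epoch of a recording to one scalar per unit
#' (by default the mean signal across the epoch's frames, or the sum for
#' count data) and arranges the scalars as a units x stimuli x repetitions
#' array. Only epochs with the requested label enter; repetitions are
#' numbered in order of trial onset within each stimulus.
#'
#' @param rec a `population_recording` with a populated trial table.
#' @param epoch epoch label to keep (default `"stim_on"`).
#' @param stat `"mean"` or `"sum"` over the epoch's frames.
#' @return numeric array `[unit, stimulus, repetition]` with dimnames;
#'   class `trial_response_table`.
#' @export
trial_responses <- function(rec, epoch = "stim_on", stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  tt <- rec$trial_table[rec$trial_table$epoch == epoch, , drop = FALSE]
  if (nrow(tt) == 0) stop("no trials with epoch label '", epoch, "'")
  tt <- tt[order(tt$onset), , drop = FALSE]
  stims <- sort(unique(tt$stimulus))
  reps <- table(tt$stimulus)
  if (length(unique(reps)) != 1)
    stop("unequal repetition counts across stimuli: ",
         paste(names(reps), reps, sep = "=", collapse = ", "))
  n_rep <- unname(reps[1])
  arr <- array(NA_real_, dim = c(length(rec$unit_ids), length(stims), n_rep),
               dimnames = list(unit = as.character(rec$unit_ids),
                               stimulus = stims, repetition = NULL))
  counter <- stats::setNames(integer(length(stims)), stims)
  f <- if (stat == "mean") rowMeans else rowSums
  for (k in seq_len(nrow(tt))) {
    s <- tt$stimulus[k]
    counter[s] <- counter[s] + 1L
    frames <- (tt$onset[k] + 1L):tt$offset[k]  # 0-based half-open -> R index
    arr[, s, counter[s]] <- f(rec$signals[, frames, drop = FALSE])
  }
  structure(arr, class = c("trial_response_table", "array"))
}

#' Variance-to-mean ratio of trial responses
#'
#' Quantifies trial-by-trial variability of each unit by dividing the
#' response variance across repetitions of the same stimulus by the mean
#' response, then averaging the per-stimulus ratios over stimuli with a
#' non-zero mean. A Poisson spike-count process gives a ratio of 1, the
#' usual reference line; cortical responses typically exceed it.
#'
#' @param tbl `trial_response_table` (units x stimuli x repetitions), or a
#'   units x repetitions matrix for a single stimulus.
#' @return numeric vector, one ratio per unit; `NaN` for units whose mean
#'   response is zero for every stimulus.
#' @export
variance_mean_ratio <- function(tbl) {
  if (is.matrix(tbl)) tbl <- array(tbl, dim = c(nrow(tbl), 1L, ncol(tbl)))
  if (dim(tbl)[3] < 2) stop("need at least 2 repetitions per stimulus")
  n_u <- dim(tbl)[1]
  out <- vapply(seq_len(n_u), function(i) {
    m <- apply(tbl[i, , , drop = FALSE], 2, function(z) mean(as.vector(z)))
    v <- apply(tbl[i, , , drop = FALSE], 2, function(z) var(as.vector(z)))
    ok <- m != 0
    if (!any(ok)) return(NaN)
    mean(v[ok] / m[ok])
  }, numeric(1))
  names(out) <- dimnames(tbl)[[1]]
  out
}

#' Direction selectivity index
#'
#' DSI = (R_P - R_O) / (R_P + R_O), where R_P is the largest trial-mean
#' response over directions (ties broken toward the lowest angle) and R_O
#' the trial-mean response to the direction 180 degrees opposite. Units
#' with R_P + R_O = 0 are flagged undefined (NaN). With the conventional
#' threshold, units with DSI > 0.4 are classed direction selective.
#'
#' @param tbl `trial_response_table` whose stimulus dimension corresponds
#'   to `directions`.
#' @param directions numeric vector of direction angles in degrees, one per
#'   stimulus, coming in opposite pairs (e.g. 0,45,...,315).
#' @return data.frame with columns `unit`, `dsi`, `pref_direction`.
#' @export
direction_selectivity <- function(tbl, directions) {
  directions <- as.numeric(directions) %% 360
  if (length(directions) != dim(tbl)[2])
    stop("one direction per stimulus required")
  opp <- match((directions + 180) %% 360, directions)
  if (anyNA(opp)) stop("directions must come in opposite pairs")
  mean_resp <- apply(tbl, c(1, 2), mean)   # units x directions
  ord <- order(directions)
  units <- dimnames(tbl)[[1]]
  if (is.null(units)) units <- as.character(seq_len(nrow(mean_resp)))
  out <- lapply(seq_len(nrow(mean_resp)), function(i) {
    m <- mean_resp[i, ]
    p <- ord[which.max(m[ord])]            # lowest angle wins ties
    rp <- m[p]; ro <- m[opp[p]]
    dsi <- if (rp + ro == 0) NaN else (rp - ro) / (rp + ro)
    data.frame(unit = units[i], dsi = dsi,
               pref_direction = directions[p])
  })
  do.call(rbind, out)
}

#' DSI significance from inter-spike-interval shuffling
#'
#' Builds a null distribution for each unit's DSI by shuffling the unit's
#' inter-spike intervals: all spike frames are pooled across the recording,
#' the intervals between successive spikes are randomly permuted, the train
#' is reassembled from the first spike onward, and the DSI is recomputed
#' from the reassembled train using the original trial windows. The
#' reported significance is the fraction of surrogates with a DSI at least
#' as large as the observed one.
#'
#' @param rec `population_recording` whose signals are spike counts per
#'   frame.
#' @param directions direction angle per stimulus label (named vector, or
#'   in the sorted-label order used by [trial_responses()]).
#' @param n_shuffle number of ISI-shuffled surrogates (default 1000).
#' @param seed RNG seed.
#' @param epoch epoch label of the stimulus-on windows.
#' @return data.frame with columns `unit`, `dsi`, `p_value`.
#' @export
dsi_significance <- function(rec, directions, n_shuffle = 1000L, seed = 1L,
                             epoch = "stim_on") {
  set.seed(seed)
  tbl <- trial_responses(rec, epoch = epoch, stat = "sum")
  stims <- dimnames(tbl)[[2]]
  if (!is.null(names(directions))) directions <- directions[stims]
  obs <- direction_selectivity(tbl, directions)
  nf <- ncol(rec$signals)
  tt <- rec$trial_table[rec$trial_table$epoch == epoch, , drop = FALSE]
  p <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    counts <- rec$signals[i, ]
    spikes <- rep(seq_len(nf), times = round(counts))
    if (length(spikes) < 3 || is.nan(obs$dsi[i])) { p[i] <- NA_real_; next }
    isi <- diff(spikes)
    hits <- 0L
    for (s in seq_len(n_shuffle)) {
      new_spikes <- cumsum(c(spikes[1], sample(isi)))
      cnt <- tabulate(new_spikes, nbins = nf)
      shuf_tbl <- trial_responses_from_counts(cnt, tt, stims)
      dsi_s <- dsi_one(shuf_tbl, directions)
      if (!is.nan(dsi_s) && dsi_s >= obs$dsi[i]) hits <- hits + 1L
    }
    p[i] <- hits / n_shuffle
  }
  data.frame(unit = obs$unit, dsi = obs$dsi, p_value = p)
}

# single-unit helpers for the ISI-shuffle loop
trial_responses_from_counts <- function(counts, tt, stims) {
  resp <- vapply(stims, function(s) {
    rows <- which(tt$stimulus == s)
    mean(vapply(rows, function(k)
      sum(counts[(tt$onset[k] + 1L):tt$offset[k]]), numeric(1)))
  }, numeric(1))
  resp
}

dsi_one <- function(mean_resp, directions) {
  directions <- as.numeric(directions) %% 360
  opp <- match((directions + 180) %% 360, directions)
  ord <- order(directions)
  pidx <- ord[which.max(mean_resp[ord])]
  rp <- mean_resp[pidx]; ro <- mean_resp[opp[pidx]]
  if (rp + ro == 0) NaN else (rp - ro) / (rp + ro)
}
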