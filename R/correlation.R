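#' Running-median temporal smoothing
#'
#' Per-unit running median with a centered window of `window_samples`
#' frames; at the trace edges the window shrinks to the valid range. Used
#' to stabilise the correlation estimates (20 samples is a typical choice
#' for 2PI calcium data, 8 for MEA LFP data); `window_samples = 1` is the
#' identity.
#'
#' @param signals units x frames matrix.
#' @param window_samples window length in frames.
#' @return smoothed matrix of the same shape.
#' @export
smooth_time <- function(signals, window_samples) {
  signals <- as.matrix(signals)
  if (window_samples < 1) stop("window_samples must be >= 1")
  if (window_samples > ncol(signals))
    stop("smoothing window (", window_samples, ") longer than trace (",
         ncol(signals), " frames)")
  if (window_samples == 1) return(signals)
  out <- row_running_median(matrix(as.numeric(signals), nrow(signals)),
                            as.integer(window_samples))
  dimnames(out) <- dimnames(signals)
  out
}

#' Enumerate square observation windows
#'
#' Slides an axis-aligned square of side `L` across the population's
#' bounding box at the given stride and keeps every placement holding at
#' least `min_units` units. Membership uses the half-open square
#' `[origin, origin + L)` in both coordinates. Windows with fewer than
#' `min_units` (default 5) units are discarded because the population-mean
#' subtraction is badly biased for very small populations.
#'
#' @param positions units x 2 matrix.
#' @param L window side, in position units.
#' @param stride origin step; default `L / 8`. Use the grid pitch for
#'   lattice or electrode data to enumerate every subregion.
#' @param min_units minimum units per retained window.
#' @return list of `window_spec` lists (`origin`, `side`, `members`).
#' @export
enumerate_windows <- function(positions, L, stride = L / 8, min_units = 5L) {
  if (L <= 0) stop("L must be positive")
  x <- positions[, 1]; y <- positions[, 2]
  ox <- origin_seq(min(x), max(x), L, stride)
  oy <- origin_seq(min(y), max(y), L, stride)
  out <- list()
  for (oxi in ox) {
    inx <- x >= oxi & x < oxi + L
    if (sum(inx) < min_units) next
    for (oyi in oy) {
      members <- which(inx & y >= oyi & y < oyi + L)
      if (length(members) >= min_units)
        out[[length(out) + 1L]] <-
          structure(list(origin = c(oxi, oyi), side = L, members = members),
                    class = "window_spec")
    }
  }
  out
}

origin_seq <- function(lo, hi, L, stride) {
  if (hi - L <= lo) return(lo)
  seq(lo, hi - L, by = stride)
}

#' Subtract the instantaneous population mean
#'
#' The residual of unit i at frame t is u_i(t) = v_i(t) - vbar(t), with
#' vbar(t) the mean over all units inside the observation window at that
#' frame. By construction the residuals sum to zero over units at every
#' frame: the analysis studies fluctuations *around* the population
#' response, discarding the common signal.
#'
#' @param signals units x frames matrix (the window's members only).
#' @param frames optional integer vector of frame indices (1-based) to
#'   retain, e.g. the concatenated stimulus-on epochs.
#' @return matrix of residuals, units x retained frames.
#' @export
subtract_population_mean <- function(signals, frames = NULL) {
  signals <- as.matrix(signals)
  if (nrow(signals) < 2) stop("need at least 2 units to subtract a mean")
  if (!is.null(frames)) signals <- signals[, frames, drop = FALSE]
  sweep(signals, 2, colMeans(signals))
}

#' Distance bins for a population
#'
#' Default smoothed-delta realisation: fixed-width bins of width equal to
#' the median nearest-neighbour distance (scattered units) or an explicit
#' width (grid or electrode data, where the pitch is the natural width).
#'
#' @param positions units x 2 matrix.
#' @param bin_width bin width; `NULL` uses the median nearest-neighbour
#'   distance.
#' @return numeric vector of bin breaks starting at 0, covering the
#'   maximum pairwise distance.
#' @export
distance_breaks <- function(positions, bin_width = NULL) {
  d <- stats::dist(positions)
  if (is.null(bin_width)) {
    dm <- as.matrix(d)
    diag(dm) <- Inf
    bin_width <- median(apply(dm, 1, min))
  }
  mx <- max(d)
  seq(0, bin_width * ceiling(mx / bin_width + 1e-9), by = bin_width)
}

# sum `vals` within distance-bin indices b (0 or > nb are dropped)
bin_sums <- function(vals, b, nb) {
  keep <- b >= 1L & b <= nb
  out <- numeric(nb)
  if (!any(keep)) return(out)
  agg <- rowsum(vals[keep], b[keep])
  out[as.integer(rownames(agg))] <- agg
  out
}

new_correlation_function <- function(L, breaks, C, n_pairs, C0, n_frames,
                                     n_windows = 1L) {
  keep <- n_pairs > 0
  structure(list(L = L,
                 r = (head(breaks, -1) + tail(breaks, -1))[keep] / 2,
                 C = C[keep], n_pairs = n_pairs[keep], C0 = C0,
                 breaks = breaks, n_frames = n_frames,
                 n_windows = n_windows),
            class = "correlation_function")
}

#' @export
print.correlation_function <- function(x, ...) {
  cat("<correlation_function> L = ", x$L, ", ", length(x$r),
      " distance bins, ", x$n_windows, " window(s), C0 = ",
      signif(x$C0, 4), "\n", sep = "")
  invisible(x)
}

#' Connected correlation versus distance
#'
#' For residual signals u (population mean already subtracted), computes
#' for every distance bin the average over frames and over unit pairs
#' (i != j) of u_i(t) u_j(t), normalised by C0, the r -> 0 self term
#' (mean over units and frames of u_i^2). With this normalisation
#' C(r = 0) = 1 by construction; bins containing no pair are omitted.
#'
#' @param u residuals from [subtract_population_mean()].
#' @param positions matching units x 2 position matrix.
#' @param breaks distance-bin breaks (see [distance_breaks()]).
#' @param L window side stored for provenance (default: position extent).
#' @return a `correlation_function`.
#' @export
correlation_vs_distance <- function(u, positions, breaks = NULL, L = NULL) {
  u <- as.matrix(u)
  if (ncol(u) < 1) stop("need at least one frame")
  if (is.null(breaks)) breaks <- distance_breaks(positions)
  if (is.null(L)) L <- max(diff(apply(positions, 2, range)))
  S <- tcrossprod(u)                 # sum over frames of u_i u_j
  C0 <- mean(diag(S)) / ncol(u)      # mean_i,t u_i(t)^2
  if (C0 == 0)
    stop("undefined correlation: residuals are identically zero (C0 = 0)")
  iu <- which(upper.tri(S))
  su <- S[iu]
  d <- as.matrix(stats::dist(positions))[iu]
  b <- findInterval(d, breaks, left.open = TRUE)
  nb <- length(breaks) - 1L
  pair_sum <- bin_sums(su, b, nb)
  n_pairs <- tabulate(b, nbins = nb)
  C <- ifelse(n_pairs > 0, pair_sum / (pmax(n_pairs, 1L) * ncol(u) * C0), NA_real_)
  new_correlation_function(L, breaks, C, n_pairs, C0, ncol(u))
}

#' Pair-count-weighted average of correlation functions
#'
#' Averages per-window correlation functions for one window size L,
#' weighting each bin by its pair count, which equals pooling all pairs
#' across windows (each window normalised by its own C0).
#'
#' @param cfs list of `correlation_function`s sharing `L` and breaks.
#' @return a single averaged `correlation_function`.
#' @export
average_over_windows <- function(cfs) {
  if (length(cfs) == 0) stop("no correlation functions to average")
  if (length(cfs) == 1) return(cfs[[1]])
  br <- cfs[[1]]$breaks
  if (!all(vapply(cfs, function(f)
        isTRUE(all.equal(f$breaks, br)) && isTRUE(all.equal(f$L, cfs[[1]]$L)),
        logical(1))))
    stop("inconsistent binning or L across windows")
  nb <- length(br) - 1L
  num <- den <- numeric(nb)
  for (f in cfs) {
    idx <- findInterval(f$r, br, left.open = TRUE)
    num[idx] <- num[idx] + f$C * f$n_pairs
    den[idx] <- den[idx] + f$n_pairs
  }
  C <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  new_correlation_function(cfs[[1]]$L, br, C, den,
                           mean(vapply(cfs, `[[`, numeric(1), "C0")),
                           cfs[[1]]$n_frames, n_windows = length(cfs))
}

#' Zero crossing of a correlation function
#'
#' Locates the first sign change of C(r) scanning from the smallest
#' distance, then refines it by a cubic least-squares fit to the bins
#' within `halfwidth` bins of the bracketing pair; the root is taken
#' inside the bracketing interval (falling back to linear interpolation
#' if the cubic has no root there). Also reports the fitted derivative
#' dC/dr at r0, needed by the collapse-exponent fit.
#'
#' @param cf a `correlation_function`.
#' @param halfwidth bins on each side of the bracket entering the fit
#'   (default 3).
#' @return list with `r0`, `slope` (dC/dr at r0), and `defined`; when no
#'   sign change exists, `defined = FALSE` and `r0 = NA` (no error).
#' @export
zero_crossing <- function(cf, halfwidth = 3L) {
  r <- cf$r; C <- cf$C
  s <- sign(C)
  n <- length(s)
  # first sign change; a bin sitting exactly on zero also brackets a root
  i <- which(s[-n] * s[-1] < 0 | (s[-n] != 0 & s[-1] == 0))
  if (length(i) == 0)
    return(list(r0 = NA_real_, slope = NA_real_, defined = FALSE))
  i <- i[1]
  lo <- max(1L, i - halfwidth); hi <- min(length(r), i + 1L + halfwidth)
  rr <- r[lo:hi]; cc <- C[lo:hi]
  deg <- min(3L, length(rr) - 1L)
  fit <- lm(cc ~ poly(rr, deg, raw = TRUE))
  cf_coef <- coef(fit)
  root <- poly_root_in(cf_coef, r[i], r[i + 1])
  if (is.na(root)) {  # linear interpolation inside the bracket
    root <- r[i] + (r[i + 1] - r[i]) * C[i] / (C[i] - C[i + 1])
    slope <- (C[i + 1] - C[i]) / (r[i + 1] - r[i])
  } else {
    dcoef <- cf_coef[-1] * seq_len(deg)
    slope <- sum(dcoef * root^(seq_len(deg) - 1))
  }
  list(r0 = unname(root), slope = unname(slope), defined = TRUE)
}

poly_root_in <- function(coefs, lo, hi) {
  coefs[is.na(coefs)] <- 0
  z <- polyroot(coefs)
  re <- Re(z)[abs(Im(z)) < 1e-8 * (1 + abs(Re(z)))]
  re <- re[re >= lo & re <= hi]
  if (length(re) == 0) NA_real_ else min(re)
}

#' Trial shuffling control
#'
#' Within each (stimulus, epoch) group, permutes each unit's trial-epoch
#' signal segments across repetitions, independently for every unit.
#' Within-trial co-fluctuations between units are destroyed while each
#' unit's set of single-trial responses (and anything locked to the
#' stimulus) is conserved. Frames outside trial epochs are untouched.
#'
#' @param rec a `population_recording` with a populated trial table.
#' @param seed RNG seed.
#' @return a shuffled `population_recording`.
#' @export
trial_shuffle <- function(rec, seed = 1L) {
  tt <- rec$trial_table
  if (nrow(tt) == 0) stop("trial shuffling needs a populated trial table")
  set.seed(seed)
  sig <- rec$signals
  groups <- split(seq_len(nrow(tt)), paste(tt$stimulus, tt$epoch, sep = "\r"))
  for (g in groups) {
    lens <- tt$offset[g] - tt$onset[g]
    if (length(unique(lens)) != 1)
      stop("unequal trial lengths within a stimulus group")
    if (length(g) < 2) next
    frames <- lapply(g, function(k) (tt$onset[k] + 1L):tt$offset[k])
    for (i in seq_len(nrow(sig))) {
      perm <- sample(length(g))
      orig <- sig[i, unlist(frames)]
      dim(orig) <- c(lens[1], length(g))
      sig[i, unlist(frames)] <- as.vector(orig[, perm])
    }
  }
  out <- rec
  out$signals <- sig
  out
}

#' Position shuffling control
#'
#' Randomly permutes the unit positions while leaving all signals
#' untouched, destroying any true spatial organisation of the
#' correlations; the pairwise-distance multiset is conserved.
#'
#' @param rec a `population_recording`.
#' @param seed RNG seed.
#' @return a `population_recording` with permuted positions.
#' @export
position_shuffle <- function(rec, seed = 1L) {
  if (length(rec$unit_ids) < 2) stop("need at least 2 units")
  set.seed(seed)
  out <- rec
  out$positions <- rec$positions[sample(nrow(rec$positions)), , drop = FALSE]
  out
}

#' Plain Pearson correlation versus distance
#'
#' The no-subtraction counter-analysis: ordinary pairwise Pearson
#' correlation of the raw signals, averaged per distance bin. In the
#' presence of common input this stays positive at all distances (even
#' after trial shuffling), unlike the connected correlation.
#'
#' @param signals units x frames matrix (raw, no mean subtraction).
#' @param positions units x 2 matrix.
#' @param breaks distance-bin breaks (default [distance_breaks()]).
#' @param L provenance window side.
#' @return a `correlation_function` (C0 = 1); zero-variance units are
#'   dropped with a warning.
#' @export
pearson_vs_distance <- function(signals, positions, breaks = NULL, L = NULL) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 2) stop("need at least 2 frames")
  v <- apply(signals, 1, var)
  if (any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance unit(s)")
    signals <- signals[v > 0, , drop = FALSE]
    positions <- positions[v > 0, , drop = FALSE]
  }
  if (is.null(breaks)) breaks <- distance_breaks(positions)
  if (is.null(L)) L <- max(diff(apply(positions, 2, range)))
  R <- stats::cor(t(signals))
  iu <- which(upper.tri(R))
  d <- as.matrix(stats::dist(positions))[iu]
  b <- findInterval(d, breaks, left.open = TRUE)
  nb <- length(breaks) - 1L
  sums <- bin_sums(R[iu], b, nb)
  n_pairs <- tabulate(b, nbins = nb)
  C <- ifelse(n_pairs > 0, sums / pmax(n_pairs, 1L), NA_real_)
  new_correlation_function(L, breaks, C, n_pairs, 1, ncol(signals))
}

#' Averaged connected correlation over all windows of one size
#'
#' Efficient implementation of the per-window pipeline (restrict to
#' window, subtract the window's population mean, correlate versus
#' distance, pair-count-weighted average over windows) sharing the signal
#' cross-product across windows. Exactly equivalent to composing
#' [enumerate_windows()], [subtract_population_mean()],
#' [correlation_vs_distance()] and [average_over_windows()].
#'
#' @param signals units x frames matrix (epoch-restricted, smoothed).
#' @param positions units x 2 matrix.
#' @param L window side.
#' @param stride window stride (default `L / 8`; use the grid pitch to
#'   enumerate every subregion of gridded data).
#' @param breaks distance-bin breaks shared by all windows.
#' @param min_units minimum units per window (default 5).
#' @param V optional precomputed `tcrossprod(signals)` for reuse across
#'   multiple L.
#' @return an averaged `correlation_function`, or `NULL` when no window
#'   qualifies.
#' @export
windowed_correlation <- function(signals, positions, L, stride = L / 8,
                                 breaks = NULL, min_units = 5L, V = NULL) {
  sparse <- inherits(signals, "Matrix")
  if (!sparse) signals <- as.matrix(signals)
  if (is.null(breaks)) breaks <- distance_breaks(positions)
  wins <- enumerate_windows(positions, L, stride, min_units)
  if (length(wins) == 0) return(NULL)
  if (is.null(V)) V <- if (sparse) Matrix::tcrossprod(signals)
                       else tcrossprod(signals)
  Tn <- ncol(signals)
  nb <- length(breaks) - 1L
  num <- den <- numeric(nb)
  C0s <- numeric(length(wins))
  for (wi in seq_along(wins)) {
    m <- wins[[wi]]$members
    sw <- signals[m, , drop = FALSE]
    mu <- if (sparse) Matrix::colMeans(sw) else colMeans(sw)
    a <- as.vector(sw %*% mu)
    s2 <- sum(mu^2)
    pw <- positions[m, , drop = FALSE]
    if (length(m) > 2000L) {
      # large window: bin pairs in C++ without a dense pair-distance matrix
      Vw <- V[m, m, drop = FALSE]
      if (sparse) {
        Vw <- methods::as(Vw, "generalMatrix")
        C0 <- (mean(Matrix::diag(Vw)) - 2 * mean(a) + s2) / Tn
      } else {
        C0 <- (mean(diag(Vw)) - 2 * mean(a) + s2) / Tn
      }
      C0s[wi] <- C0
      if (C0 == 0) next
      vs <- if (sparse) {
        trip <- Matrix::summary(Vw)
        triplet_bin_sums_cpp(trip$i, trip$j, trip$x, pw[, 1], pw[, 2], breaks)
      } else {
        matrix_bin_sums_cpp(Vw, pw[, 1], pw[, 2], breaks)
      }
      st <- pair_bin_stats_cpp(pw[, 1], pw[, 2], a, breaks)
      ps <- vs - st$asum + st$count * s2
      np <- st$count
    } else {
      Vw <- as.matrix(V[m, m, drop = FALSE])
      C0 <- (mean(diag(Vw)) - 2 * mean(a) + s2) / Tn
      C0s[wi] <- C0
      if (C0 == 0) next
      iu <- which(upper.tri(Vw))
      Sw <- (Vw - outer(a, a, `+`) + s2)[iu]
      d <- as.matrix(stats::dist(pw))[iu]
      b <- findInterval(d, breaks, left.open = TRUE)
      ps <- bin_sums(Sw, b, nb)
      np <- tabulate(b, nbins = nb)
    }
    num <- num + ps / (Tn * C0)
    den <- den + np
  }
  if (all(den == 0)) return(NULL)
  C <- ifelse(den > 0, num / pmax(den, 1), NA_real_)
  new_correlation_function(L, breaks, C, den, mean(C0s),
                           Tn, n_windows = length(wins))
}
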