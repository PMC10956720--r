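#' Configuration of the excitable lattice model
#'
#' A square lattice of S x S three-state units (rest, active, two
#' refractory steps). Each unit projects to K targets drawn with
#' probability proportional to exp(-r / R0_conn) under a hard interaction
#' cutoff Ic = 4 * R0_conn, with periodic boundaries. An active unit
#' excites each resting target independently with probability P; a weak
#' Poisson drive h per unit per step keeps the network from dying out.
#' The branching control parameter is sigma = K * P; sweeping P moves the
#' network across subcritical, critical and supercritical regimes.
#'
#' @param S lattice side; the model has S^2 units.
#' @param P transmission probability per active presynaptic input.
#' @param K out-degree (default 8).
#' @param R0_conn connectivity decay length in lattice units (default 5).
#' @param h spontaneous firing probability per unit per step
#'   (default 1e-7).
#' @param steps recorded simulation steps (after burn-in).
#' @param burn_in discarded initial steps (default 10000).
#' @param seed RNG seed controlling both wiring and dynamics.
#' @return a `lattice_config` list; `Ic` and `sigma` are derived fields.
#' @export
lattice_config <- function(S, P, K = 8L, R0_conn = 5, h = 1e-7,
                           steps = 1e5, burn_in = 1e4, seed = 1L) {
  if (P < 0 || P > 1) stop("configuration error: P must lie in [0, 1]")
  if (h < 0 || h > 1) stop("configuration error: h must lie in [0, 1]")
  if (S^2 <= K) stop("configuration error: need S^2 > K")
  cfg <- list(S = as.integer(S), K = as.integer(K), P = P,
              R0_conn = R0_conn, Ic = 4 * R0_conn, h = h,
              steps = as.integer(steps), burn_in = as.integer(burn_in),
              seed = as.integer(seed), sigma = K * P)
  class(cfg) <- "lattice_config"
  cfg
}

#' Lattice coordinates of every unit
#'
#' Units are numbered row-major; coordinates are 0-based lattice columns
#' (x) and rows (y).
#' @param S lattice side.
#' @return S^2 x 2 integer matrix of (x, y).
#' @export
lattice_positions <- function(S) {
  idx <- seq_len(S^2) - 1L
  cbind(x = idx %% S, y = idx %/% S)
}

#' Build the distance-dependent random connectivity
#'
#' Every unit receives exactly K distinct targets (self excluded), sampled
#' without replacement with probability proportional to exp(-r / R0_conn),
#' where r is the periodic minimum-image Euclidean distance, restricted to
#' r <= Ic. The same displacement menu applies to every unit because the
#' torus is translation invariant.
#'
#' @param cfg a `lattice_config`.
#' @return integer matrix S^2 x K of 1-based target indices.
#' @export
build_connectivity <- function(cfg) {
  S <- cfg$S
  if (cfg$Ic >= S / 2)
    stop("configuration error: need Ic < S/2 for unambiguous minimum-image distances")
  rng <- seq(-floor(cfg$Ic), floor(cfg$Ic))
  off <- expand.grid(dx = rng, dy = rng)
  r <- sqrt(off$dx^2 + off$dy^2)
  keep <- r > 0 & r <= cfg$Ic
  off <- off[keep, ]
  w <- exp(-r[keep] / cfg$R0_conn)
  if (nrow(off) < cfg$K)
    stop("configuration error: fewer than K eligible targets per unit")
  set.seed(cfg$seed)
  n <- S^2
  idx0 <- seq_len(n) - 1L
  x0 <- idx0 %% S
  y0 <- idx0 %/% S
  adj <- matrix(0L, n, cfg$K)
  n_off <- nrow(off)
  for (u in seq_len(n)) {
    pick <- sample.int(n_off, cfg$K, prob = w)
    tx <- (x0[u] + off$dx[pick]) %% S
    ty <- (y0[u] + off$dy[pick]) %% S
    adj[u, ] <- ty * S + tx + 1L
  }
  adj
}

#' Interaction graph from the directed wiring
#'
#' Converts the directed K-target wiring into the interaction graph the
#' dynamics run on. With `coupling = "symmetric"` (the default) each link
#' acts as a symmetric coupling: a unit's neighbours are the union of its
#' targets and its sources, giving a mean degree close to 2K, so the
#' branching parameter at vanishing activity is approximately 2K * P and
#' the critical point for K = 8 sits near P = 1/16. With
#' `coupling = "directed"` activity propagates along out-links only
#' (branching ~ K * P).
#'
#' @param adjacency S^2 x K matrix from [build_connectivity()].
#' @param coupling `"symmetric"` or `"directed"`.
#' @return list with 0-based `offsets` (length S^2 + 1) and 1-based
#'   `neighbors`, in compressed sparse row form.
#' @export
interaction_graph <- function(adjacency, coupling = c("symmetric", "directed")) {
  coupling <- match.arg(coupling)
  n <- nrow(adjacency)
  K <- ncol(adjacency)
  from <- rep(seq_len(n), K)
  to <- as.vector(adjacency)
  if (coupling == "symmetric") {
    a <- pmin(from, to); b <- pmax(from, to)
    keep <- !duplicated(a + (b - 1) * n)  # one undirected edge per pair
    a <- a[keep]; b <- b[keep]
    from <- c(a, b); to <- c(b, a)
  }
  o <- order(from)
  from <- from[o]; to <- to[o]
  deg <- tabulate(from, nbins = n)
  list(offsets = c(0L, cumsum(deg)), neighbors = to)
}

#' Simulate the lattice model
#'
#' Synchronous stochastic update: a resting unit fires on the next step
#' with probability 1 - (1-h) * (1-P)^a, where a counts its currently
#' active inputs on the interaction graph; firing units then pass through
#' two refractory steps before resting again. All units start at rest and
#' the first `burn_in` steps are discarded. Dynamics are driven by R's
#' RNG, so a given `cfg$seed` is bit-reproducible.
#'
#' @param cfg a `lattice_config`.
#' @param adjacency matrix from [build_connectivity()] (built from `cfg`
#'   if omitted).
#' @param bin_steps time-bin width (in steps) of the recorded spike-count
#'   raster; 1 keeps the raw binary raster.
#' @param record_units 1-based unit indices to record (default all).
#' @param coupling link semantics for the dynamics, see
#'   [interaction_graph()]; `"symmetric"` reproduces the model whose
#'   critical transmission probability for K = 8 lies near 0.066.
#' @param raster_format `"matrix"`, `"sparse"` (a `dgCMatrix`, suited to
#'   fine time bins on long runs), or `"auto"` (sparse when the dense
#'   raster would exceed ~5e7 entries).
#' @return a `lattice_run` list: `config`, `raster` (recorded units x time
#'   bins spike counts), `bin_steps`, `positions` (of recorded units),
#'   `record_units`, `active_per_step`, `total_spikes`.
#' @export
simulate_lattice <- function(cfg, adjacency = NULL, bin_steps = 1L,
                             record_units = NULL,
                             coupling = c("symmetric", "directed"),
                             raster_format = c("auto", "matrix", "sparse")) {
  if (is.null(adjacency)) adjacency <- build_connectivity(cfg)
  raster_format <- match.arg(raster_format)
  graph <- interaction_graph(adjacency, coupling)
  n <- cfg$S^2
  if (is.null(record_units)) record_units <- seq_len(n)
  n_bins <- ceiling(cfg$steps / bin_steps)
  if (raster_format == "auto")
    raster_format <- if (length(record_units) * n_bins > 5e7) "sparse"
                     else "matrix"
  set.seed(cfg$seed + 1L)  # wiring used cfg$seed; dynamics get their own stream
  res <- sim_lattice_cpp(graph$offsets, graph$neighbors,
                         cfg$steps, cfg$burn_in, cfg$P, cfg$h,
                         as.integer(record_units), as.integer(bin_steps),
                         integer(0), raster_format == "sparse")
  raster <- if (raster_format == "sparse")
    Matrix::sparseMatrix(i = res$sp_unit, j = res$sp_bin, x = 1,
                         dims = c(length(record_units), res$n_bins))
  else res$counts
  structure(list(config = cfg, raster = raster,
                 bin_steps = as.integer(bin_steps),
                 positions = lattice_positions(cfg$S)[record_units, , drop = FALSE],
                 record_units = as.integer(record_units),
                 active_per_step = res$active_per_step,
                 total_spikes = res$total_spikes),
            class = "lattice_run")
}

#' Empirical branching ratio of a lattice run
#'
#' Ratio of the total number of units active at step t+1 to the total
#' number active at step t, over steps with non-zero activity. Near the
#' vanishing-activity limit this estimates the mean number of offspring
#' per firing unit; it grows monotonically with P at fixed K and
#' approaches 1 at criticality.
#'
#' @param run a `lattice_run`.
#' @return scalar branching estimate (NaN if the run is silent).
#' @export
measure_branching <- function(run) {
  a <- as.numeric(run$active_per_step)
  if (length(a) < 2) return(NaN)
  prev <- a[-length(a)]
  nxt <- a[-1]
  keep <- prev > 0
  if (!any(keep)) return(NaN)
  sum(nxt[keep]) / sum(prev[keep])
}

#' Convert a lattice run into a population recording
#'
#' Optionally re-bins the recorded raster in time (the new bin must be a
#' multiple of the run's bin), restricts observation to a central square
#' of side `obs_side` lattice units (the observation grid, much smaller
#' than the lattice to limit finite-size artifacts), and partitions the
#' frames into `n_trials` contiguous equal-length pseudo-trials (leftover
#' frames at the end are dropped).
#'
#' @param run a `lattice_run`.
#' @param bin_steps time bin of the output recording, in simulation steps.
#' @param obs_side side of the central observation square (lattice units);
#'   `NULL` keeps all recorded units.
#' @param n_trials number of contiguous pseudo-trials (default 1).
#' @return a `population_recording` (positions in lattice units, signals
#'   are spike counts per bin, epoch label `"stim_on"`).
#' @export
lattice_to_recording <- function(run, bin_steps = run$bin_steps,
                                 obs_side = NULL, n_trials = 1L) {
  if (bin_steps %% run$bin_steps != 0)
    stop("bin_steps must be a multiple of the run's bin (", run$bin_steps, ")")
  fac <- bin_steps %/% run$bin_steps
  sig <- run$raster
  if (fac > 1) {
    nb <- floor(ncol(sig) / fac)
    sig <- sig[, seq_len(nb * fac), drop = FALSE]
    grp <- rep(seq_len(nb), each = fac)
    if (inherits(sig, "Matrix")) {
      G <- Matrix::sparseMatrix(i = seq_len(nb * fac), j = grp, x = 1,
                                dims = c(nb * fac, nb))
      sig <- sig %*% G
    } else {
      sig <- t(rowsum(t(sig), grp))
    }
  }
  pos <- run$positions
  if (!is.null(obs_side)) {
    S <- run$config$S
    if (obs_side >= S)
      stop("obs_side must be smaller than the lattice side S = ", S)
    lo <- floor((S - obs_side) / 2)
    keep <- pos[, 1] >= lo & pos[, 1] < lo + obs_side &
            pos[, 2] >= lo & pos[, 2] < lo + obs_side
    pos <- pos[keep, , drop = FALSE]
    sig <- sig[keep, , drop = FALSE]
  }
  nf <- ncol(sig)
  n_trials <- as.integer(n_trials)
  tlen <- floor(nf / n_trials)
  if (tlen < 1) stop("too few frames for ", n_trials, " trials")
  sig <- sig[, seq_len(n_trials * tlen), drop = FALSE]
  tt <- data.frame(onset = (seq_len(n_trials) - 1L) * tlen,
                   offset = seq_len(n_trials) * tlen,
                   stimulus = "lattice", epoch = "stim_on",
                   stringsAsFactors = FALSE)
  population_recording(unit_ids = seq_len(nrow(pos)), positions = pos,
                       signals = sig, sample_rate = 1,
                       trial_table = tt, modality = "lattice")
}

#' Correlation-function family over lattice extents
#'
#' Builds the family C(r, L) used for the collapse-exponent estimate of
#' the critical model: each L is the extent of a simulated periodic
#' lattice observed in full, with the population mean over the whole grid
#' subtracted. Curves are averaged over `n_seeds` independent wirings and
#' runs per extent (pair-count weighted). Simulation length per run is
#' chosen as `unit_steps / S^2` so every extent accumulates comparable
#' spike statistics.
#'
#' @param P transmission probability.
#' @param sizes lattice extents (all must satisfy `4 * R0_conn < S/2`).
#' @param n_seeds independent runs averaged per extent.
#' @param seed master seed.
#' @param bin_steps time-bin width for the analysed raster.
#' @param unit_steps unit-time budget per run (steps = unit_steps / S^2).
#' @param K,R0_conn,h,burn_in model parameters, see [lattice_config()].
#' @return named list of averaged `correlation_function`s, one per extent.
#' @export
lattice_extent_family <- function(P, sizes = c(48, 64, 80, 96, 128),
                                  n_seeds = 5L, seed = 1L, bin_steps = 100L,
                                  unit_steps = 2e9, K = 8L, R0_conn = 5,
                                  h = 1e-7, burn_in = 1e4) {
  fam <- list()
  for (S in sizes) {
    steps <- max(1e5, round(unit_steps / S^2))
    percf <- list()
    for (k in seq_len(n_seeds)) {
      cfg <- lattice_config(S = S, P = P, K = K, R0_conn = R0_conn, h = h,
                            steps = steps, burn_in = burn_in,
                            seed = (seed * 131L + S) %% 100000L * 10L + k)
      run <- simulate_lattice(cfg, bin_steps = bin_steps,
                              raster_format = "sparse")
      rec <- lattice_to_recording(run, bin_steps = bin_steps)
      cf <- windowed_correlation(rec$signals, rec$positions, L = S,
                                 stride = S,
                                 breaks = seq(0, ceiling(1.5 * S), by = 1))
      if (!is.null(cf)) percf[[length(percf) + 1L]] <- cf
    }
    if (length(percf) > 0)
      fam[[as.character(S)]] <- average_over_windows(percf)
  }
  fam
}

#' Central observation-grid units of a lattice
#'
#' @param S lattice side.
#' @param obs_side side of the central square observation grid.
#' @return 1-based unit indices inside the grid.
#' @export
observation_units <- function(S, obs_side) {
  if (obs_side >= S) stop("obs_side must be smaller than S")
  pos <- lattice_positions(S)
  lo <- floor((S - obs_side) / 2)
  which(pos[, 1] >= lo & pos[, 1] < lo + obs_side &
        pos[, 2] >= lo & pos[, 2] < lo + obs_side)
}

#' Box-scaled correlation family from lattice simulations
#'
#' The standard workflow behind the model's criticality diagnostics:
#' simulate the lattice `n_seeds` times (independent wiring and dynamics),
#' restrict to a central observation grid, compute the connected
#' correlation C(r, L) averaged over all sub-windows of each size at the
#' given stride, and pool the per-seed curves (pair-count weighted).
#' High-activity (supercritical) rasters are analysed densely; sparse
#' rasters via sparse cross-products.
#'
#' @param P transmission probability.
#' @param S lattice side (default 128).
#' @param obs_side central observation grid side (default 48).
#' @param L_values window sides analysed within the grid.
#' @param steps recorded steps per run.
#' @param n_seeds independent runs pooled.
#' @param seed master seed.
#' @param bin_steps time-bin width of the analysed signals (steps).
#' @param stride window stride in lattice units.
#' @param K,R0_conn,h,burn_in model parameters, see [lattice_config()].
#' @param density_limit raster density above which the dense representation
#'   is used.
#' @return named list of pooled `correlation_function`s, one per L.
#' @export
lattice_box_family <- function(P, S = 128L, obs_side = 48L,
                               L_values = c(16, 20, 24, 32, 40, 48),
                               steps = 5e5, n_seeds = 5L, seed = 1L,
                               bin_steps = 100L, stride = 4,
                               K = 8L, R0_conn = 5, h = 1e-7, burn_in = 1e4,
                               density_limit = 0.05) {
  obs <- observation_units(S, obs_side)
  fams <- vector("list", n_seeds)
  positions <- NULL
  breaks <- seq(0, ceiling(1.5 * obs_side), by = 1)
  for (k in seq_len(n_seeds)) {
    cfg <- lattice_config(S = S, P = P, K = K, R0_conn = R0_conn, h = h,
                          steps = steps, burn_in = burn_in,
                          seed = seed * 1000L + k)
    run <- simulate_lattice(cfg, bin_steps = bin_steps, record_units = obs,
                            raster_format = "auto")
    rec <- lattice_to_recording(run, bin_steps = bin_steps)
    sig <- rec$signals
    if (inherits(sig, "Matrix") &&
        Matrix::nnzero(sig) / prod(dim(sig)) > density_limit)
      sig <- as.matrix(sig)
    positions <- rec$positions
    V <- if (inherits(sig, "Matrix")) Matrix::tcrossprod(sig)
         else tcrossprod(sig)
    fams[[k]] <- lapply(L_values, function(L)
      windowed_correlation(sig, positions, L, stride = stride,
                           breaks = breaks, V = V))
  }
  out <- list()
  for (i in seq_along(L_values)) {
    cl <- Filter(Negate(is.null), lapply(fams, `[[`, i))
    if (length(cl) > 0)
      out[[as.character(L_values[i])]] <- average_over_windows(cl)
  }
  out
}
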