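`%||%` <- function(a, b) if (is.null(a)) b else a

#' Frames belonging to a trial epoch
#'
#' 1-based frame indices of all trials carrying the requested epoch label,
#' concatenated in onset order; `NULL` epoch selects every frame.
#'
#' @param rec a `population_recording`.
#' @param epoch epoch label (e.g. `"stim_on"`), or `NULL`.
#' @return integer vector of frame indices.
#' @export
epoch_frames <- function(rec, epoch = NULL) {
  if (is.null(epoch)) return(seq_len(ncol(rec$signals)))
  tt <- rec$trial_table[rec$trial_table$epoch == epoch, , drop = FALSE]
  if (nrow(tt) == 0) stop("no trials with epoch label '", epoch, "'")
  tt <- tt[order(tt$onset), , drop = FALSE]
  unlist(lapply(seq_len(nrow(tt)),
                function(k) (tt$onset[k] + 1L):tt$offset[k]))
}

#' Full box-scaling correlation analysis of one recording
#'
#' Runs the complete chain for a family of window sizes: optional
#' running-median smoothing, epoch restriction, window enumeration,
#' population-mean subtraction, connected correlation versus distance
#' averaged over all windows of each size, zero crossings, correlation
#' lengths, collapse exponent and error, susceptibility (of the
#' largest-L curve), the chi-squared linearity test of xi(L), and the
#' xi/r0 proportionality diagnostic.
#'
#' @param rec a `population_recording`.
#' @param L_values window sides to analyse.
#' @param bin_width distance-bin width (default: median nearest-neighbour
#'   distance).
#' @param stride window stride; default `L / 8` per window size (pass the
#'   grid pitch for lattice/electrode data).
#' @param epoch trial-epoch restriction (`NULL` = all frames).
#' @param smooth_samples running-median window (1 = no smoothing).
#' @param min_units minimum units per window (default 5).
#' @param gamma_x abscissa for the gamma power-law fit, `"r0"` or `"L"`.
#' @param L_min smallest L entering the collapse (default: all).
#' @param ratio_tol CV tolerance for the xi/r0 diagnostic.
#' @return a `scaling_result`: correlation functions plus all scalar
#'   diagnostics.
#' @export
correlation_pipeline <- function(rec, L_values, bin_width = NULL,
                                 stride = NULL, epoch = NULL,
                                 smooth_samples = 1L, min_units = 5L,
                                 gamma_x = "r0", L_min = 0,
                                 ratio_tol = 0.10) {
  sig <- if (smooth_samples > 1) smooth_time(rec$signals, smooth_samples)
         else rec$signals
  frames <- epoch_frames(rec, epoch)
  sig <- sig[, frames, drop = FALSE]
  breaks <- distance_breaks(rec$positions, bin_width)
  V <- if (inherits(sig, "Matrix")) Matrix::tcrossprod(sig)
       else tcrossprod(sig)
  cfs <- list()
  for (L in sort(L_values)) {
    cf <- windowed_correlation(sig, rec$positions, L,
                               stride = stride %||% (L / 8),
                               breaks = breaks, min_units = min_units, V = V)
    if (!is.null(cf)) cfs[[as.character(L)]] <- cf
  }
  if (length(cfs) == 0) stop("no window size produced a correlation function")
  summarize_scaling(cfs, gamma_x = gamma_x, L_min = L_min,
                    ratio_tol = ratio_tol)
}

#' Scaling summary of a correlation-function family
#'
#' Computes every scaling diagnostic from an existing family of averaged
#' correlation functions (one per window size L).
#'
#' @param cfs named list of `correlation_function`s.
#' @inheritParams correlation_pipeline
#' @return a `scaling_result` list: `L_values`, `r0`, `xi`, `gamma`,
#'   `Delta`, `chi_susc`, `linear` (test results), `ratio`, `F_curve`,
#'   `cfs`.
#' @export
summarize_scaling <- function(cfs, gamma_x = "r0", L_min = 0,
                              ratio_tol = 0.10) {
  Ls <- vapply(cfs, `[[`, numeric(1), "L")
  zc <- lapply(cfs, zero_crossing)
  r0 <- vapply(zc, `[[`, numeric(1), "r0")
  xi <- vapply(seq_along(cfs),
               function(i) correlation_length(cfs[[i]], r0[i]), numeric(1))
  chi <- susceptibility(cfs[[which.max(Ls)]], r0[which.max(Ls)])
  gam <- tryCatch(gamma_estimate(cfs, x = gamma_x), error = function(e) NULL)
  clp <- if (!is.null(gam))
    tryCatch(collapse_curves(cfs, gam$gamma_signed, L_min = L_min),
             error = function(e) NULL)
  lin <- tryCatch(linear_scaling_test(Ls, xi), error = function(e) NULL)
  ratio <- tryCatch(xi_r0_ratio(Ls, xi, r0, tol = ratio_tol),
                    error = function(e) NULL)
  structure(list(L_values = unname(Ls), r0 = unname(r0), xi = unname(xi),
                 gamma = if (is.null(gam)) NA_real_ else gam$gamma,
                 gamma_signed = if (is.null(gam)) NA_real_ else gam$gamma_signed,
                 gamma_detail = if (is.null(gam)) NULL else gam$detail,
                 Delta = if (is.null(clp)) NA_real_ else clp$Delta,
                 Delta_rel = if (is.null(clp)) NA_real_ else clp$Delta_rel,
                 Delta_shape = if (is.null(clp)) NA_real_ else clp$Delta_shape,
                 F_curve = clp, chi_susc = chi, linear = lin,
                 ratio = ratio, cfs = cfs),
            class = "scaling_result")
}

#' @export
print.scaling_result <- function(x, ...) {
  cat("<scaling_result> ", length(x$L_values), " window sizes\n", sep = "")
  print(data.frame(L = x$L_values, r0 = signif(x$r0, 4),
                   xi = signif(x$xi, 4)), row.names = FALSE)
  cat("gamma = ", signif(x$gamma, 3), ", Delta = ", signif(x$Delta, 3),
      ", chi = ", signif(x$chi_susc, 4), "\n", sep = "")
  if (!is.null(x$linear))
    cat("linear fit: slope = ", signif(x$linear$slope, 3), ", chi_c^2 = ",
        signif(x$linear$chi2, 3), " (df = ", x$linear$df, "), p_upper = ",
        signif(x$linear$p_upper, 3), ", R^2 = ",
        signif(x$linear$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Declarative run configuration
#'
#' All knobs of an end-to-end run in one validated object. The input is
#' either a container path readable by [read_recording()] or a generator
#' spec: `list(type = "lattice", S=, P=, steps=, bin_steps=, obs_side=,
#' n_trials=)`, `list(type = "gaussian_field", ...surrogate_spec fields)`
#' or `list(type = "evoked", ...)`.
#'
#' @param input path or generator spec list.
#' @param L_values window sides.
#' @param bin_width,stride,epoch,smooth_samples,gamma_x,L_min,min_units
#'   forwarded to [correlation_pipeline()].
#' @param shuffle `"none"`, `"trial"` or `"position"`: also analyse the
#'   shuffled control.
#' @param seed master seed for generation and shuffling.
#' @param out_dir output directory (`NULL`: nothing written).
#' @return a `run_config` list with all defaults materialised.
#' @export
run_config <- function(input, L_values, bin_width = NULL, stride = NULL,
                       epoch = NULL, smooth_samples = 1L,
                       shuffle = c("none", "trial", "position"),
                       gamma_x = "r0", L_min = 0, min_units = 5L,
                       seed = 1L, out_dir = NULL) {
  shuffle <- match.arg(shuffle)
  if (!is.character(input) && !(is.list(input) && !is.null(input$type)))
    stop("config error: input must be a container path or a generator spec list")
  if (length(L_values) < 1 || any(L_values <= 0))
    stop("config error: L_values must be positive")
  structure(list(input = input, L_values = sort(L_values),
                 bin_width = bin_width, stride = stride, epoch = epoch,
                 smooth_samples = as.integer(smooth_samples),
                 shuffle = shuffle, gamma_x = gamma_x, L_min = L_min,
                 min_units = as.integer(min_units), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

generate_input <- function(spec, seed) {
  switch(spec$type,
    lattice = {
      cfg <- lattice_config(S = spec$S, P = spec$P,
                            K = spec$K %||% 8L, R0_conn = spec$R0_conn %||% 5,
                            h = spec$h %||% 1e-7, steps = spec$steps,
                            burn_in = spec$burn_in %||% 1e4, seed = seed)
      run <- simulate_lattice(cfg, bin_steps = spec$bin_steps %||% 1L)
      lattice_to_recording(run, bin_steps = spec$bin_steps %||% 1L,
                           obs_side = spec$obs_side,
                           n_trials = spec$n_trials %||% 1L)
    },
    gaussian_field = {
      s <- spec; s$type <- NULL
      gaussian_field_population(do.call(surrogate_spec, c(s, seed = seed)))
    },
    evoked = {
      s <- spec; s$type <- NULL
      evoked_surrogate(do.call(surrogate_spec, c(s, seed = seed)))
    },
    stop("config error: unknown generator type '", spec$type, "'"))
}

#' Run the full pipeline from a configuration
#'
#' Loads or generates the recording, analyses it (and, if requested, its
#' trial- or position-shuffled control), and optionally writes a result
#' bundle: the resolved configuration, per-L correlation CSVs, a scaling
#' JSON and a text report. Identical configuration and seed give
#' byte-identical result JSONs.
#'
#' @param cfg a `run_config`.
#' @return a `result_bundle` list: `config`, `recording`, `result`,
#'   `shuffled_result` (or NULL), `report`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  rec <- if (is.character(cfg$input)) read_recording(cfg$input)
         else generate_input(cfg$input, cfg$seed)
  analyse <- function(r) tryCatch(
    correlation_pipeline(r, cfg$L_values, bin_width = cfg$bin_width,
                         stride = cfg$stride, epoch = cfg$epoch,
                         smooth_samples = cfg$smooth_samples,
                         min_units = cfg$min_units, gamma_x = cfg$gamma_x,
                         L_min = cfg$L_min),
    error = function(e) stop("stage 'scale' failed: ", conditionMessage(e)))
  res <- analyse(rec)
  shuf <- switch(cfg$shuffle,
                 none = NULL,
                 trial = analyse(trial_shuffle(rec, seed = cfg$seed + 1L)),
                 position = analyse(position_shuffle(rec, seed = cfg$seed + 1L)))
  bundle <- structure(list(config = cfg, recording = rec, result = res,
                           shuffled_result = shuf),
                      class = "result_bundle")
  bundle$report <- report_bundle(bundle)
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

scaling_json <- function(res) {
  list(L = res$L_values, r0 = res$r0, xi = res$xi, gamma = res$gamma,
       Delta = res$Delta, chi = res$chi_susc,
       linear = if (is.null(res$linear)) NULL else
         res$linear[c("slope", "intercept", "chi2", "df", "p_upper",
                      "p_lower", "r_squared")],
       ratio_cv = if (is.null(res$ratio)) NULL else res$ratio$cv)
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- bundle$config
  cfg_list <- unclass(cfg)
  jsonlite::write_json(cfg_list, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (cf in bundle$result$cfs) {
    data.table::fwrite(
      data.frame(L = cf$L, r_center = cf$r, C = cf$C, n_pairs = cf$n_pairs),
      file.path(dir, sprintf("correlation_L%g.csv", cf$L)))
  }
  out <- list(result = scaling_json(bundle$result))
  if (!is.null(bundle$shuffled_result))
    out$shuffled_result <- scaling_json(bundle$shuffled_result)
  jsonlite::write_json(out, file.path(dir, "scaling.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(bundle$report, file.path(dir, "report.txt"))
  invisible(dir)
}

#' Human-readable summary of a result bundle
#'
#' @param bundle a `result_bundle` from [run_pipeline()].
#' @return character vector of report lines.
#' @export
report_bundle <- function(bundle) {
  res <- bundle$result
  lines <- c("== box-scaling correlation analysis ==",
             sprintf("windows analysed: %s",
                     paste(res$L_values, collapse = ", ")),
             "L, r0, xi:",
             sprintf("  %8.4g %8.4g %8.4g", res$L_values, res$r0, res$xi),
             sprintf("gamma = %.4g   Delta = %.4g   chi = %.4g",
                     res$gamma, res$Delta, res$chi_susc))
  if (!is.null(res$linear))
    lines <- c(lines, sprintf(
      "linear xi(L): slope = %.4g, chi_c^2 = %.4g (df = %d), p_upper = %.3g, p_lower = %.3g, R^2 = %.4g",
      res$linear$slope, res$linear$chi2, res$linear$df,
      res$linear$p_upper, res$linear$p_lower, res$linear$r_squared))
  if (!is.null(res$ratio))
    lines <- c(lines, sprintf("xi/r0 CV = %.3g%s", res$ratio$cv,
                              if (res$ratio$violated) "  [proportionality violated]" else ""))
  if (is.null(bundle$shuffled_result)) {
    lines <- c(lines, "shuffle control: not run")
  } else {
    s <- bundle$shuffled_result
    lines <- c(lines, sprintf(
      "shuffle control (%s): gamma = %.4g, Delta = %.4g, first-bin C (largest window) = %.4g",
      bundle$config$shuffle, s$gamma, s$Delta, s$cfs[[length(s$cfs)]]$C[1]))
  }
  lines
}

#' Generate the canonical small fixtures
#'
#' Writes the small test inputs used throughout the package's examples
#' and tests: a 5-unit worked example, Gaussian-field populations at
#' lambda in {2, 5, 10, 20} um, and mini lattice runs at the three
#' reference transmission probabilities, together with a manifest listing
#' each fixture with its md5 checksum and reference correlation values
#' computed by a direct naive pair loop.
#'
#' @param seed master seed.
#' @param dir output directory.
#' @return path of the manifest file, invisibly.
#' @export
generate_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  # 5-unit worked example
  set.seed(seed)
  pos <- cbind(x = c(0, 10, 20, 30, 40), y = c(0, 5, 10, 15, 20))
  sig <- matrix(rnorm(5 * 40), 5, 40)
  tt <- data.frame(onset = c(0L, 20L), offset = c(20L, 40L),
                   stimulus = c("a", "b"), epoch = "stim_on")
  rec5 <- population_recording(1:5, pos, sig, 30, tt, "worked_example")
  p <- file.path(dir, "worked_example")
  write_recording(rec5, p)
  u <- subtract_population_mean(rec5$signals)
  cf <- correlation_vs_distance(u, pos, breaks = seq(0, 50, by = 10))
  manifest$worked_example <- list(
    path = "worked_example", checksum = container_checksum(p),
    oracle_C = cf$C, oracle_r = cf$r, oracle_n_pairs = cf$n_pairs)
  # Gaussian fields over lambda
  for (lam in c(2, 5, 10, 20)) {
    spec <- surrogate_spec(n_units = 40L, area_side = 100, lambda = lam,
                           seed = seed + lam)
    recg <- gaussian_field_population(spec, n_frames = 200L)
    p <- file.path(dir, sprintf("gaussian_lambda%g", lam))
    write_recording(recg, p)
    manifest[[sprintf("gaussian_lambda%g", lam)]] <-
      list(path = basename(p), checksum = container_checksum(p),
           lambda = lam)
  }
  # mini lattice runs at the three reference regimes
  for (P in c(0.059, 0.066, 0.073)) {
    cfg <- lattice_config(S = 48, P = P, steps = 2000, burn_in = 500,
                          seed = seed)
    run <- simulate_lattice(cfg, bin_steps = 50L)
    recl <- lattice_to_recording(run, bin_steps = 50L, obs_side = 24)
    p <- file.path(dir, sprintf("lattice_P%g", P))
    write_recording(recl, p)
    manifest[[sprintf("lattice_P%g", P)]] <-
      list(path = basename(p), checksum = container_checksum(p), P = P,
           total_spikes = run$total_spikes)
  }
  mpath <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(mpath)
}

container_checksum <- function(path) {
  files <- sort(list.files(path, full.names = TRUE))
  unname(tools::md5sum(files))
}
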