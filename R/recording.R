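#' Population recording container
#'
#' Bundles everything the correlation pipeline needs about one recording:
#' unit identities, their 2D positions, a units x frames signal matrix
#' (dF/F, estimated spikes, LFP amplitude, or binned lattice activity),
#' the sampling rate, and a trial table. Frame indices are 0-based and
#' trial intervals half-open `[onset, offset)`.
#'
#' @param unit_ids vector of unit identifiers (one per row of `positions`).
#' @param positions numeric matrix with one row per unit and columns x, y,
#'   in micrometres (or lattice / electrode-pitch units).
#' @param signals numeric matrix, units x frames, rows ordered as
#'   `positions`.
#' @param sample_rate sampling rate in Hz.
#' @param trial_table data.frame with columns `onset`, `offset`
#'   (0-based frames, half-open), `stimulus` (label) and `epoch`
#'   (`"stim_on"` or `"stim_off"`). May have zero rows.
#' @param modality free-text tag describing the signal type.
#'
#' @return An object of class `population_recording`.
#' @export
population_recording <- function(unit_ids, positions, signals, sample_rate,
                                 trial_table = empty_trial_table(),
                                 modality = "unknown") {
  positions <- as.matrix(positions)
  if (is.null(colnames(positions))) colnames(positions) <- c("x", "y")
  if (!inherits(signals, "Matrix")) signals <- as.matrix(signals)
  rec <- structure(
    list(unit_ids = unit_ids, positions = positions, signals = signals,
         sample_rate = as.numeric(sample_rate),
         trial_table = as.data.frame(trial_table), modality = modality),
    class = "population_recording")
  validate_recording(rec)
  rec
}

#' Empty trial table with the canonical columns
#' @return zero-row data.frame with columns onset, offset, stimulus, epoch.
#' @export
empty_trial_table <- function() {
  data.frame(onset = integer(0), offset = integer(0),
             stimulus = character(0), epoch = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a population recording
#'
#' Checks the structural invariants: one position row per unit, one signal
#' row per unit, all trial frame ranges inside the signal length, trials
#' non-overlapping, half-open 0-based intervals.
#'
#' @param rec a `population_recording`.
#' @return `rec`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_recording <- function(rec) {
  n <- length(rec$unit_ids)
  if (nrow(rec$positions) != n)
    stop("validation error: ", nrow(rec$positions), " position rows for ",
         n, " unit ids")
  if (ncol(rec$positions) != 2)
    stop("validation error: positions must have two columns (x, y)")
  if (nrow(rec$signals) != n)
    stop("validation error: ", nrow(rec$signals), " signal rows for ",
         n, " units")
  tt <- rec$trial_table
  req <- c("onset", "offset", "stimulus", "epoch")
  if (!all(req %in% names(tt)))
    stop("format error: trial table must have columns ",
         paste(req, collapse = ", "))
  if (nrow(tt) > 0) {
    nf <- ncol(rec$signals)
    if (any(tt$onset < 0) || any(tt$offset > nf) || any(tt$onset >= tt$offset))
      stop("validation error: trial intervals must satisfy 0 <= onset < offset <= n_frames")
    o <- order(tt$onset)
    if (any(tt$offset[o][-nrow(tt)] > tt$onset[o][-1]))
      stop("validation error: trial epochs overlap")
  }
  if (length(rec$sample_rate) != 1 || !is.finite(rec$sample_rate) ||
      rec$sample_rate <= 0)
    stop("validation error: sample_rate must be a positive scalar")
  invisible(rec)
}

#' @export
print.population_recording <- function(x, ...) {
  cat("<population_recording> ", length(x$unit_ids), " units x ",
      ncol(x$signals), " frames @ ", x$sample_rate, " Hz [", x$modality,
      "], ", nrow(x$trial_table), " trial epochs\n", sep = "")
  invisible(x)
}

fmt_full <- function(x) {
  # full-precision decimal text so that read/write round-trips doubles
  if (is.integer(x)) format(x) else sprintf("%.17g", x)
}

#' Write a population recording to a sidecar directory
#'
#' The container is a directory of plain-text members: `positions.csv`
#' (unit_id, x_um, y_um), `signals.csv` (units x frames, row order equal
#' to positions), `trials.csv` (onset, offset, stimulus, epoch) and
#' `meta.json` (sample_rate_hz, modality, storage mode). Floating-point
#' values are written with 17 significant digits so a write/read cycle
#' reproduces them bit-exactly; integer matrices stay integer.
#'
#' @param rec a validated `population_recording`.
#' @param path directory to create (overwritten member-wise if it exists).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  validate_recording(rec)
  if (!dir.exists(path))
    if (!dir.create(path, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create container directory: ", path)
  pos <- data.frame(unit_id = rec$unit_ids,
                    x_um = fmt_full(rec$positions[, 1]),
                    y_um = fmt_full(rec$positions[, 2]))
  data.table::fwrite(pos, file.path(path, "positions.csv"))
  sig <- rec$signals
  is_int <- is.integer(sig)
  sig_chr <- matrix(fmt_full(sig), nrow = nrow(sig))
  colnames(sig_chr) <- paste0("f", seq_len(max(1L, ncol(sig))) - 1L)[
    seq_len(ncol(sig))]
  data.table::fwrite(data.table::as.data.table(sig_chr),
                     file.path(path, "signals.csv"))
  data.table::fwrite(rec$trial_table, file.path(path, "trials.csv"))
  meta <- list(sample_rate_hz = rec$sample_rate, modality = rec$modality,
               n_units = length(rec$unit_ids), n_frames = ncol(rec$signals),
               signals_integer = is_int,
               unit_ids_integer = is.integer(rec$unit_ids))
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a population recording from a sidecar directory
#'
#' Counterpart of [write_recording()]; validates the result.
#'
#' @param path container directory written by [write_recording()].
#' @return a `population_recording`.
#' @export
read_recording <- function(path) {
  members <- c("positions.csv", "signals.csv", "trials.csv", "meta.json")
  missing <- members[!file.exists(file.path(path, members))]
  if (length(missing))
    stop("format error: container at ", path, " is missing member(s): ",
         paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  pos <- data.table::fread(file.path(path, "positions.csv"),
                           colClasses = list(character = c("x_um", "y_um")))
  positions <- cbind(x = as.numeric(pos$x_um), y = as.numeric(pos$y_um))
  sig <- as.matrix(data.table::fread(file.path(path, "signals.csv"),
                                     colClasses = "character", header = TRUE))
  signals <- matrix(as.numeric(sig), nrow = nrow(sig))
  if (isTRUE(meta$signals_integer)) storage.mode(signals) <- "integer"
  if (meta$n_frames == 0) signals <- matrix(numeric(0), nrow = nrow(pos))
  trials <- as.data.frame(data.table::fread(
    file.path(path, "trials.csv"),
    colClasses = list(integer = c("onset", "offset"),
                      character = c("stimulus", "epoch"))))
  if (nrow(trials) == 0) trials <- empty_trial_table()
  unit_ids <- pos$unit_id
  if (isTRUE(meta$unit_ids_integer)) unit_ids <- as.integer(unit_ids)
  population_recording(unit_ids, positions, signals,
                       meta$sample_rate_hz, trials, meta$modality)
}
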