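#' Epoched multichannel recording
#'
#' The pipeline's raw-input container: a trials x channels x samples array
#' of voltages (uV) with stimulus timing and condition metadata. Epoch
#' sample `onset_index` is stimulus onset (time 0); the stimulation period
#' covers the half-open sample interval `[onset_index, offset_index)`.
#'
#' @param data Numeric array, trials x channels x samples.
#' @param sample_rate Sampling rate in Hz.
#' @param onset_index 1-based sample index of stimulus onset.
#' @param offset_index 1-based sample index of stimulus offset (exclusive).
#' @param condition Character vector of condition labels, one per trial.
#' @param channel_names Character vector of channel names.
#' @param participant_id Participant identifier.
#' @param group_label Optional group label.
#' @return An object of class `ssvep_epochs`.
#' @export
ssvep_epochs <- function(data, sample_rate, onset_index, offset_index,
                         condition, channel_names, participant_id,
                         group_label = NA_character_) {
  x <- structure(list(
    data = data, sample_rate = sample_rate,
    onset_index = as.integer(onset_index),
    offset_index = as.integer(offset_index),
    condition = as.character(condition),
    channel_names = as.character(channel_names),
    participant_id = as.character(participant_id),
    group_label = as.character(group_label)
  ), class = "ssvep_epochs")
  validate_ssvep_epochs(x)
}

validate_ssvep_epochs <- function(x) {
  d <- dim(x$data)
  if (length(d) != 3) abort("`data` must be a trials x channels x samples array.")
  if (length(x$condition) != d[1]) {
    abort(sprintf("Condition labels (%d) do not match trial count (%d).",
                  length(x$condition), d[1]))
  }
  if (length(x$channel_names) != d[2]) {
    abort(sprintf("Channel names (%d) do not match channel count (%d).",
                  length(x$channel_names), d[2]))
  }
  if (anyDuplicated(x$channel_names)) abort("Channel names must be unique.")
  if (!(x$onset_index >= 1 && x$onset_index < x$offset_index &&
        x$offset_index <= d[3] + 1L)) {
    abort("Require 1 <= onset_index < offset_index <= samples + 1.")
  }
  bad <- setdiff(unique(x$condition), ssvep_conditions())
  if (length(bad)) {
    abort(sprintf("Unknown condition label(s): %s.", paste(bad, collapse = ", ")))
  }
  if (!all(is.finite(x$data))) abort("Epoch data must be finite.")
  x
}

#' @export
print.ssvep_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ssvep_epochs> %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$participant_id, d[1], d[2], d[3], x$sample_rate))
  cat(sprintf("  stimulation: samples %d..%d (t = 0..%g s)\n",
              x$onset_index, x$offset_index - 1L,
              (x$offset_index - x$onset_index) / x$sample_rate))
  invisible(x)
}

#' Write an epoched recording to the portable container
#'
#' One little-endian float32 binary file (trial-major: samples fastest,
#' then channels, then trials) plus a JSON metadata sidecar, named
#' `<participant_id>.bin` / `<participant_id>.json`.
#'
#' @param rec An [ssvep_epochs] object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the path to the JSON sidecar.
#' @export
write_epochs <- function(rec, dir) {
  validate_ssvep_epochs(rec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, rec$participant_id)
  d <- dim(rec$data)
  # aperm so samples vary fastest within a trial
  con <- file(paste0(stem, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(aperm(rec$data, c(3, 2, 1))), con,
           size = 4, endian = "little")
  meta <- list(
    participant_id = rec$participant_id,
    group_label = rec$group_label,
    sample_rate = rec$sample_rate,
    n_trials = d[1], n_channels = d[2], n_samples = d[3],
    onset_index = rec$onset_index, offset_index = rec$offset_index,
    condition = rec$condition, channel_names = rec$channel_names,
    data_file = paste0(basename(stem), ".bin")
  )
  jsonlite::write_json(meta, paste0(stem, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(paste0(stem, ".json"))
}

#' Read an epoched recording from the portable container
#'
#' @param path Path to a JSON metadata sidecar written by [write_epochs()]
#'   (the binary array file is located via its `data_file` field, relative
#'   to the sidecar).
#' @return A validated [ssvep_epochs] object.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) abort(sprintf("No such metadata file: %s", path))
  meta <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("sample_rate", "n_trials", "n_channels", "n_samples",
            "onset_index", "offset_index", "condition", "channel_names",
            "participant_id", "data_file")
  missing <- setdiff(need, names(meta))
  if (length(missing)) {
    abort(sprintf("Metadata is missing field(s): %s.", paste(missing, collapse = ", ")))
  }
  bin <- file.path(dirname(path), meta$data_file)
  if (!file.exists(bin)) abort(sprintf("No such data file: %s", bin))
  n_expect <- meta$n_trials * meta$n_channels * meta$n_samples
  raw <- readBin(bin, what = "numeric", n = n_expect + 1L,
                 size = 4, endian = "little")
  if (length(raw) != n_expect) {
    abort(sprintf("Array size mismatch: metadata declares %d values, file holds %d.",
                  n_expect, length(raw)))
  }
  data <- aperm(array(raw, dim = c(meta$n_samples, meta$n_channels, meta$n_trials)),
                c(3, 2, 1))
  ssvep_epochs(
    data = data, sample_rate = meta$sample_rate,
    onset_index = meta$onset_index, offset_index = meta$offset_index,
    condition = meta$condition, channel_names = meta$channel_names,
    participant_id = meta$participant_id,
    group_label = meta$group_label %||% NA_character_
  )
}

#' Import a single trial from a delimited text table
#'
#' Reads a delimited file with one column per channel and one row per
#' sample (header row of channel names) into a 1-trial [ssvep_epochs].
#'
#' @param path Path to the delimited file.
#' @param sample_rate,onset_index,offset_index,condition,participant_id
#'   Metadata for the trial (see [ssvep_epochs()]).
#' @param sep Field separator.
#' @return An [ssvep_epochs] with one trial.
#' @export
read_trial_table <- function(path, sample_rate, onset_index, offset_index,
                             condition, participant_id = "P001", sep = ",") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE)
  m <- as.matrix(tab)
  data <- array(0, dim = c(1L, ncol(m), nrow(m)))
  data[1, , ] <- t(m)
  ssvep_epochs(data, sample_rate, onset_index, offset_index,
               condition = condition, channel_names = colnames(m),
               participant_id = participant_id)
}

#' Per-trial waveforms averaged over an analysis channel set
#'
#' Averages the named channels within each trial (arithmetic mean, trial
#' order preserved), collapsing the recording to one waveform per trial —
#' the classic occipital-electrode average feeding SSVEP analyses.
#'
#' @param rec An [ssvep_epochs] object.
#' @param channels Character vector of channel names to average. Defaults
#'   to all channels in the recording.
#' @return An `ssvep_waveforms` object: trials x samples matrix plus
#'   timing/condition metadata.
#' @export
average_channels <- function(rec, channels = rec$channel_names) {
  validate_ssvep_epochs(rec)
  idx <- match(channels, rec$channel_names)
  if (anyNA(idx)) {
    abort(sprintf("Unknown channel(s): %s.",
                  paste(channels[is.na(idx)], collapse = ", ")))
  }
  if (!length(idx)) abort("Channel set must be non-empty.")
  d <- dim(rec$data)
  wav <- if (length(idx) == 1L) {
    matrix(rec$data[, idx, ], d[1], d[3])
  } else {
    apply(rec$data[, idx, , drop = FALSE], c(1, 3), mean)
  }
  structure(list(
    waveforms = wav, sample_rate = rec$sample_rate,
    onset_index = rec$onset_index, offset_index = rec$offset_index,
    condition = rec$condition, participant_id = rec$participant_id,
    group_label = rec$group_label, channels = channels
  ), class = "ssvep_waveforms")
}

#' @export
print.ssvep_waveforms <- function(x, ...) {
  cat(sprintf("<ssvep_waveforms> %s: %d trials x %d samples (mean of %s)\n",
              x$participant_id, nrow(x$waveforms), ncol(x$waveforms),
              paste(x$channels, collapse = ", ")))
  invisible(x)
}

# seconds relative to stimulus onset for each epoch sample
waveform_times <- function(x) {
  (seq_len(ncol(x$waveforms)) - x$onset_index) / x$sample_rate
}

#' Tidy export of trial waveforms
#'
#' @param x An `ssvep_waveforms` object.
#' @param ... Unused.
#' @return A tibble with columns `participant`, `trial`, `condition`,
#'   `time_s`, `amplitude_uv`.
#' @method as_tibble ssvep_waveforms
#' @export
as_tibble.ssvep_waveforms <- function(x, ...) {
  t_s <- waveform_times(x)
  n_tr <- nrow(x$waveforms)
  tibble(
    participant = x$participant_id,
    trial = rep(seq_len(n_tr), each = length(t_s)),
    condition = rep(x$condition, each = length(t_s)),
    time_s = rep(t_s, times = n_tr),
    amplitude_uv = as.vector(t(x$waveforms))
  )
}

# subset trials of an ssvep_waveforms, preserving metadata
subset_trials <- function(x, keep) {
  x$waveforms <- x$waveforms[keep, , drop = FALSE]
  x$condition <- x$condition[keep]
  x
}
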