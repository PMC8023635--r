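#' Construct an EEG recording object
#'
#' A recording is the package's container for continuous multichannel EEG:
#' a channels-by-samples signal matrix in microvolts, its sampling rate,
#' ordered channel labels, and the name of the montage providing scalp
#' coordinates.
#'
#' @param signals numeric matrix, channels x samples, in microvolts.
#' @param sampling_rate sampling rate in Hz (positive integer).
#' @param channel_labels character vector, one unique label per signal row.
#' @param montage_ref name of the montage the labels belong to
#'   (see [load_montage()]).
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(signals, sampling_rate, channel_labels,
                          montage_ref = "ld1020") {
  signals <- as.matrix(signals)
  if (nrow(signals) != length(channel_labels))
    stop_eegprog("signals has %d rows but %d channel labels given",
                 nrow(signals), length(channel_labels), class = "eegprog_invalid")
  if (anyDuplicated(channel_labels))
    stop_eegprog("duplicate channel labels: %s",
                 paste(unique(channel_labels[duplicated(channel_labels)]), collapse = ", "),
                 class = "eegprog_invalid")
  if (length(sampling_rate) != 1L || sampling_rate <= 0)
    stop_eegprog("sampling_rate must be a positive scalar", class = "eegprog_invalid")
  rownames(signals) <- channel_labels
  structure(list(signals = signals,
                 sampling_rate = as.numeric(sampling_rate),
                 channel_labels = as.character(channel_labels),
                 montage_ref = montage_ref),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), montage '%s'\n",
              nrow(x$signals), ncol(x$signals), x$sampling_rate,
              ncol(x$signals) / x$sampling_rate, x$montage_ref))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param rec an `eeg_recording`.
#' @return scalar seconds.
#' @export
recording_duration <- function(rec) ncol(rec$signals) / rec$sampling_rate

#' Restrict a recording to a subset of channels
#'
#' Returns the requested channels in the requested order; signals are
#' otherwise untouched. Used to emulate a low-density montage by taking the
#' channel subset *before* any preprocessing.
#'
#' @param rec an `eeg_recording`.
#' @param labels channel labels to keep, in the desired output order.
#' @param montage_ref optional new montage name for the subset (defaults to
#'   the input's).
#' @return An `eeg_recording` with `length(labels)` channels.
#' @export
subset_channels <- function(rec, labels, montage_ref = rec$montage_ref) {
  missing <- setdiff(labels, rec$channel_labels)
  if (length(missing))
    stop_eegprog("channels not present in recording: %s",
                 paste(missing, collapse = ", "), class = "eegprog_missing_channel")
  idx <- match(labels, rec$channel_labels)
  new_recording(rec$signals[idx, , drop = FALSE], rec$sampling_rate,
                labels, montage_ref = montage_ref)
}

#' Crop a recording to its first `len_s` seconds
#' @param rec an `eeg_recording`.
#' @param len_s length to keep, seconds.
#' @return An `eeg_recording`.
#' @export
crop_recording <- function(rec, len_s) {
  n <- round(len_s * rec$sampling_rate)
  if (n < 1 || n > ncol(rec$signals))
    stop_eegprog("cannot crop to %g s: recording is %g s",
                 len_s, recording_duration(rec), class = "eegprog_invalid")
  new_recording(rec$signals[, seq_len(n), drop = FALSE], rec$sampling_rate,
                rec$channel_labels, rec$montage_ref)
}
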