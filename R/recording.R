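#' Multichannel EEG recording
#'
#' Container for a multichannel EEG signal with seizure annotations. This is
#' the interchange object between the reader/generator and every downstream
#' stage: rows of `signal` are channels (in `channel_labels` order), columns
#' are samples at `fs` Hz, amplitudes in microvolts.
#'
#' @param signal numeric matrix, channels x samples.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of channel names (10-20 system
#'   labels for real data), one per row of `signal`.
#' @param annotations data frame with columns `start_s`, `end_s` giving
#'   seizure intervals in seconds from recording start (half-open
#'   `[start, end)`), or `NULL` for none. Stored sorted by start.
#' @param subject_id subject identifier string.
#'
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(signal, fs, channel_labels = NULL,
                          annotations = NULL, subject_id = "") {
  signal <- as.matrix(signal)
  if (!is.numeric(signal)) stop("`signal` must be a numeric matrix")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  if (is.null(channel_labels))
    channel_labels <- paste0("CH", seq_len(nrow(signal)))
  if (length(channel_labels) != nrow(signal))
    stop("`channel_labels` must have one entry per signal row")
  rownames(signal) <- channel_labels
  dur <- ncol(signal) / fs
  annotations <- normalize_annotations(annotations, dur)
  structure(
    list(signal = signal, fs = fs, channel_labels = channel_labels,
         annotations = annotations, subject_id = subject_id),
    class = "eeg_recording")
}

# sort, validate and clip an annotation table against recording duration
normalize_annotations <- function(annotations, duration_s) {
  if (is.null(annotations) || NROW(annotations) == 0L)
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  annotations <- as.data.frame(annotations)
  if (!all(c("start_s", "end_s") %in% names(annotations)))
    stop("annotations need `start_s` and `end_s` columns")
  annotations <- annotations[order(annotations$start_s), , drop = FALSE]
  if (any(annotations$end_s <= annotations$start_s))
    stop("annotations must have end_s > start_s")
  if (any(annotations$start_s < 0) || any(annotations$end_s > duration_s))
    stop("annotations must lie within [0, duration]")
  if (nrow(annotations) > 1L &&
      any(annotations$start_s[-1L] < annotations$end_s[-nrow(annotations)]))
    stop("annotations must be non-overlapping")
  rownames(annotations) <- NULL
  annotations
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject '%s': %d channels x %d samples (%.1f s at %g Hz), %d seizure(s)\n",
              x$subject_id, nrow(x$signal), ncol(x$signal),
              ncol(x$signal) / x$fs, x$fs, nrow(x$annotations)))
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an [eeg_recording()].
#' @return length of the recording in seconds.
#' @export
recording_duration <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  ncol(rec$signal) / rec$fs
}
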