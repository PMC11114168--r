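#' Standard 16-channel 10-20 montage
#'
#' The fixed channel ordering used throughout the package: prefrontal
#' (Fp1/Fp2), frontal (F3/F4/F7/F8), temporal (T3/T4/T5/T6), central (C3/C4),
#' parietal (P3/P4) and occipital (O1/O2) electrodes of the 10-20
#' international system. Operations address channels by label, never by
#' position, but this ordering is the canonical one for I/O and display.
#'
#' @return Character vector of 16 channel labels.
#' @export
default_montage <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8",
    "T3", "T4", "T5", "T6", "C3", "C4",
    "P3", "P4", "O1", "O2")
}

#' Frontal channels of the default montage
#'
#' Used by the blink-component score: ocular artifacts project most strongly
#' onto prefrontal and frontal electrodes.
#'
#' @return Character vector of 6 frontal channel labels.
#' @export
frontal_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8")
}

#' Construct a multi-channel EEG recording
#'
#' A recording is a channels-by-samples matrix of microvolt values at a fixed
#' sampling rate, with labelled channels and a table of annotations (event
#' markers with onset and duration in seconds from recording start; intervals
#' are half-open `[onset, onset + duration)`).
#'
#' @param data Numeric matrix, channels x samples.
#' @param rate Sampling frequency in Hz (> 0).
#' @param channel_labels Character vector of unique channel names, one per
#'   row of `data`. Defaults to the first `nrow(data)` labels of
#'   [default_montage()] when 16 or fewer channels are supplied.
#' @param annotations Data frame with columns `label`, `onset`, `duration`
#'   (seconds). All annotated intervals must lie within the recording.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_labels = NULL, annotations = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (channels x samples)")
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (is.null(channel_labels)) {
    if (nrow(data) <= 16L) channel_labels <- default_montage()[seq_len(nrow(data))]
    else stop("`channel_labels` required for more than 16 channels")
  }
  channel_labels <- as.character(channel_labels)
  if (length(channel_labels) != nrow(data))
    stop("length of `channel_labels` must equal nrow(data)")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (is.null(annotations))
    annotations <- data.frame(label = character(), onset = numeric(),
                              duration = numeric(), stringsAsFactors = FALSE)
  annotations <- as.data.frame(annotations, stringsAsFactors = FALSE)
  req <- c("label", "onset", "duration")
  if (!all(req %in% names(annotations)))
    stop("`annotations` must have columns label, onset, duration")
  annotations <- annotations[req]
  annotations$label <- as.character(annotations$label)
  total <- ncol(data) / rate
  if (nrow(annotations)) {
    if (any(annotations$onset < 0) || any(annotations$duration < 0))
      stop("annotation onsets and durations must be non-negative")
    if (any(annotations$onset + annotations$duration > total + 1e-9))
      stop("annotations must lie within [0, ", format(total), "] seconds")
  }
  rownames(data) <- channel_labels
  structure(list(data = data, rate = rate, channel_labels = channel_labels,
                 annotations = annotations),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate))
  cat("  channels:", paste(x$channel_labels, collapse = " "), "\n")
  if (nrow(x$annotations))
    cat("  annotations:", paste(sprintf("%s[%g+%gs]", x$annotations$label,
                                        x$annotations$onset,
                                        x$annotations$duration),
                                collapse = " "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param recording An `eeg_recording`.
#' @return Duration in seconds.
#' @export
recording_duration <- function(recording) {
  stopifnot(inherits(recording, "eeg_recording"))
  ncol(recording$data) / recording$rate
}

# Extract the sample index range [i0, i1] covering [onset, onset+duration),
# 0-based time, half-open.
.sample_window <- function(rate, onset, duration) {
  i0 <- round(onset * rate) + 1L
  i1 <- round((onset + duration) * rate)
  c(i0, i1)
}
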