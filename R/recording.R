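#' Construct a multichannel EEG recording
#'
#' The in-memory representation of one subject's continuous recording:
#' a channels x samples matrix in microvolts plus provenance (subject id,
#' diagnostic class) and optional artifact-marked intervals.
#'
#' @param subject_id Subject identifier (string).
#' @param class_label One of `"AD"`, `"FTD"`, `"CN"`.
#' @param fs_hz Sampling rate in Hz.
#' @param channel_names Character vector of channel (montage) names.
#' @param samples Numeric matrix, `length(channel_names)` rows, one column
#'   per sample (microvolts).
#' @param artifact_intervals Optional list of `c(start_s, end_s)` spans
#'   (seconds from recording start, half-open) marked as artifact.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(subject_id, class_label, fs_hz, channel_names,
                          samples, artifact_intervals = list()) {
  class_label <- match.arg(class_label, c("AD", "FTD", "CN"))
  stopifnot(is.matrix(samples), nrow(samples) == length(channel_names),
            fs_hz > 0)
  dur <- ncol(samples) / fs_hz
  for (iv in artifact_intervals) {
    if (length(iv) != 2L || iv[1] < 0 || iv[2] <= iv[1] || iv[2] > dur + 1e-9) {
      stop("artifact interval outside recording or malformed", call. = FALSE)
    }
  }
  rownames(samples) <- channel_names
  structure(
    list(subject_id = as.character(subject_id), class_label = class_label,
         fs_hz = fs_hz, channel_names = channel_names, samples = samples,
         artifact_intervals = artifact_intervals),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): %d channels x %d samples @ %g Hz (%.1f s), %d artifact interval(s)\n",
              x$subject_id, x$class_label, nrow(x$samples), ncol(x$samples),
              x$fs_hz, ncol(x$samples) / x$fs_hz,
              length(x$artifact_intervals)))
  invisible(x)
}

# Internal constructor for an artifact-free contiguous stretch of signal.
new_clean_segment <- function(subject_id, class_label, fs_hz, samples,
                              start_offset_s) {
  structure(
    list(subject_id = subject_id, class_label = class_label, fs_hz = fs_hz,
         samples = samples, start_offset_s = start_offset_s),
    class = "clean_segment"
  )
}

#' @export
print.clean_segment <- function(x, ...) {
  cat(sprintf("<clean_segment> subject %s (%s): %d x %d @ %g Hz, offset %.2f s\n",
              x$subject_id, x$class_label, nrow(x$samples), ncol(x$samples),
              x$fs_hz, x$start_offset_s))
  invisible(x)
}
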