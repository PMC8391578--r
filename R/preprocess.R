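#' Remove artifact-marked intervals from a recording
#'
#' Splits a recording at its artifact-marked spans and returns the maximal
#' contiguous artifact-free stretches, in temporal order. Overlapping or
#' adjacent marked spans are merged first. The concatenated duration of the
#' returned segments equals the total duration minus the marked duration.
#'
#' @param rec An [eeg_recording()].
#' @return A list of `clean_segment` objects (possibly empty if the whole
#'   recording is marked).
#' @export
remove_artifacts <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$samples)
  dur <- n / rec$fs_hz
  ivs <- rec$artifact_intervals
  if (length(ivs) == 0L) {
    return(list(new_clean_segment(rec$subject_id, rec$class_label, rec$fs_hz,
                                  rec$samples, 0)))
  }
  for (iv in ivs) {
    if (iv[1] < 0 || iv[2] > dur + 1e-9) {
      stop("artifact interval outside recording", call. = FALSE)
    }
  }
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1]), , drop = FALSE]
  merged <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= merged[nrow(merged), 2]) {
      merged[nrow(merged), 2] <- max(merged[nrow(merged), 2], m[i, 2])
    } else {
      merged <- rbind(merged, m[i, ])
    }
  }
  # complement of the merged spans, in samples (half-open)
  bounds_s <- c(0, as.vector(t(merged)), dur)
  segs <- list()
  for (k in seq(1, length(bounds_s), by = 2)) {
    a <- round(bounds_s[k] * rec$fs_hz)
    b <- round(bounds_s[k + 1] * rec$fs_hz)
    if (b > a) {
      segs[[length(segs) + 1L]] <- new_clean_segment(
        rec$subject_id, rec$class_label, rec$fs_hz,
        rec$samples[, (a + 1L):b, drop = FALSE], a / rec$fs_hz)
    }
  }
  segs
}

#' Downsample a clean segment by an integer factor
#'
#' Applies a zero-phase anti-alias low-pass Butterworth (cutoff 0.8 times
#' the new Nyquist) before keeping every `factor`-th sample. The subsequent
#' 0.5--48 Hz band-pass at a 250 Hz working rate leaves little margin below
#' Nyquist, so explicit anti-aliasing is required for correctness.
#'
#' @param seg A `clean_segment`.
#' @param target_fs_hz Target rate; `seg$fs_hz` must be an integer multiple.
#' @param order Anti-alias Butterworth order.
#' @return A `clean_segment` at the target rate with
#'   `ceiling(n / factor)` samples per channel.
#' @export
downsample <- function(seg, target_fs_hz, order = 4L) {
  stopifnot(inherits(seg, "clean_segment"))
  if (target_fs_hz == seg$fs_hz) {
    return(seg)
  }
  factor <- seg$fs_hz / target_fs_hz
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stop(sprintf("sampling rate %g Hz is not an integer multiple of %g Hz",
                 seg$fs_hz, target_fs_hz), call. = FALSE)
  }
  factor <- as.integer(round(factor))
  ba <- design_butter(order, 0.8 * target_fs_hz / 2, seg$fs_hz, type = "low")
  filtered <- zerophase_filter_rows(ba, seg$samples)
  idx <- seq(1L, ncol(filtered), by = factor)
  new_clean_segment(seg$subject_id, seg$class_label, target_fs_hz,
                    filtered[, idx, drop = FALSE], seg$start_offset_s)
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the conditioning band-pass (default 0.5--48 Hz) per channel,
#' forward and backward for zero phase shift; the effective magnitude
#' response is the squared single-pass response. Signal length is
#' unchanged.
#'
#' @param seg A `clean_segment`.
#' @param low_hz,high_hz Band edges (Hz), `0 < low_hz < high_hz < fs/2`.
#' @param order Butterworth order (single pass).
#' @return A filtered `clean_segment`.
#' @export
butterworth_bandpass <- function(seg, low_hz = 0.5, high_hz = 48, order = 4L) {
  stopifnot(inherits(seg, "clean_segment"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < seg$fs_hz / 2)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2", call. = FALSE)
  }
  ba <- design_butter(order, c(low_hz, high_hz), seg$fs_hz)
  new_clean_segment(seg$subject_id, seg$class_label, seg$fs_hz,
                    zerophase_filter_rows(ba, seg$samples),
                    seg$start_offset_s)
}

#' Full signal-conditioning chain for one recording
#'
#' Artifact-interval removal, then decimation to the working rate, then the
#' conditioning band-pass -- in that order, matching standard clinical EEG
#' preprocessing for band-energy features.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs_hz Working sampling rate (default 250 Hz).
#' @param low_hz,high_hz Conditioning band edges (default 0.5--48 Hz).
#' @param order Butterworth order for both stages.
#' @return A list of conditioned `clean_segment` objects.
#' @export
preprocess_recording <- function(rec, target_fs_hz = 250, low_hz = 0.5,
                                 high_hz = 48, order = 4L) {
  segs <- remove_artifacts(rec)
  lapply(segs, function(s) {
    butterworth_bandpass(downsample(s, target_fs_hz, order = order),
                         low_hz, high_hz, order = order)
  })
}
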