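# Minimal EDF (European Data Format) writer/reader, 16-bit integer samples.
# Plain EDF only: one data record per second, no annotation signal;
# artifact intervals travel in the cohort sidecar table instead. Written
# headers follow the published field layout so standard EDF tools can read
# the files.

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled per channel to the 16-bit digital range with a
#' symmetric physical range (microvolts), so the round-trip quantisation
#' error is below `max(abs(x)) / 32767` per channel. The subject id is
#' stored in the patient-identification field and the class label in the
#' recording-identification field. The signal is truncated to a whole
#' number of 1-second data records.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs_hz
  if (abs(fs - round(fs)) > 1e-9) {
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  nch <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1L) {
    stop("recording shorter than one EDF data record (1 s)", call. = FALSE)
  }
  if (n_rec * fs < ncol(rec$samples)) {
    warning("signal truncated to a whole number of 1 s data records")
  }
  x <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmax_ch <- apply(abs(x), 1L, max)
  pmax_ch[pmax_ch == 0] <- 1
  pmax_ch <- signif(pmax_ch * 1.0001, 7)
  dmin <- -32768L
  dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * nch
  wr <- function(s, w) writeChar(pad_field(s, w), con, nchars = w,
                                 eos = NULL)
  wr("0", 8)
  wr(rec$subject_id, 80)
  wr(rec$class_label, 80)
  wr("01.01.00", 8)
  wr("00.00.00", 8)
  wr(hdr_bytes, 8)
  wr("", 44)
  wr(n_rec, 8)
  wr("1", 8)
  wr(nch, 4)
  for (ch in rec$channel_names) wr(ch, 16)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr("uV", 8)
  for (i in seq_len(nch)) wr(format(-pmax_ch[i], digits = 7), 8)
  for (i in seq_len(nch)) wr(format(pmax_ch[i], digits = 7), 8)
  for (i in seq_len(nch)) wr(dmin, 8)
  for (i in seq_len(nch)) wr(dmax, 8)
  for (i in seq_len(nch)) wr("", 80)
  for (i in seq_len(nch)) wr(fs, 8)
  for (i in seq_len(nch)) wr("", 32)

  gain <- (2 * pmax_ch) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(nch)) {
      d <- round((x[i, cols] + pmax_ch[i]) / gain[i]) + dmin
      writeBin(as.integer(pmin(pmax(d, dmin), dmax)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' Reads plain EDF with a common sampling rate across signals. The subject
#' id and class label default to the patient- and recording-identification
#' header fields (as written by [write_edf()]) but can be overridden.
#'
#' @param path EDF file path.
#' @param subject_id,class_label Optional overrides for the header fields.
#' @param artifact_intervals Optional list of `c(start_s, end_s)` artifact
#'   spans to attach (e.g. from a sidecar table).
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path, subject_id = NULL, class_label = NULL,
                     artifact_intervals = list()) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  patient <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)                      # start date, time
  rd(8)                             # header bytes
  rd(44)                            # reserved
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), character(1))
  for (i in seq_len(nch)) rd(80)    # transducer
  for (i in seq_len(nch)) rd(8)     # physical dimension
  pmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  pmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmin <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  dmax <- vapply(seq_len(nch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(nch)) rd(80)    # prefiltering
  spr <- vapply(seq_len(nch), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(nch)) rd(32)    # reserved
  if (length(unique(spr)) != 1L) {
    stop("signals with differing sampling rates are not supported",
         call. = FALSE)
  }
  fs <- spr[1] / rec_dur
  gain <- (pmax - pmin) / (dmax - dmin)
  samples <- matrix(0, nrow = nch, ncol = n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(nch)) {
      d <- readBin(con, integer(), n = spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      cols <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      samples[i, cols] <- (d - dmin[i]) * gain[i] + pmin[i]
    }
  }
  eeg_recording(subject_id %||% patient,
                class_label %||% recording,
                fs, labels, samples, artifact_intervals)
}

#' Write a cohort as EDF files with a sidecar table
#'
#' One EDF per subject plus `cohort.csv` listing `subject_id`, `class`,
#' `duration_s`, `fs_hz` and `file`.
#'
#' @param cohort List of [eeg_recording()] objects.
#' @param dir Output directory (created if needed).
#' @return Path of the sidecar CSV, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(rec) {
    fname <- paste0(rec$subject_id, ".edf")
    write_edf(rec, file.path(dir, fname))
    data.frame(subject_id = rec$subject_id, class = rec$class_label,
               duration_s = ncol(rec$samples) / rec$fs_hz,
               fs_hz = rec$fs_hz, file = fname, stringsAsFactors = FALSE)
  })
  sidecar <- file.path(dir, "cohort.csv")
  utils::write.csv(do.call(rbind, rows), sidecar, row.names = FALSE)
  invisible(sidecar)
}

#' Read a cohort written by [write_cohort_edf()]
#'
#' @param dir Directory containing `cohort.csv` and the EDF files.
#' @return List of [eeg_recording()] objects.
#' @export
read_cohort_edf <- function(dir) {
  sidecar <- file.path(dir, "cohort.csv")
  if (!file.exists(sidecar)) {
    stop("no cohort.csv sidecar in ", dir, call. = FALSE)
  }
  meta <- utils::read.csv(sidecar, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    read_edf(file.path(dir, meta$file[i]),
             subject_id = meta$subject_id[i],
             class_label = meta$class[i])
  })
}
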