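#' Cut a clean segment into overlapping epochs
#'
#' Epochs start at `start_offset + k * stride_s` for `k = 0, 1, ...`; the
#' trailing partial window is discarded, so the count is
#' `floor((segment_duration - duration_s) / stride_s) + 1` (zero when the
#' segment is shorter than one epoch). The epoch grid restarts within each
#' clean segment; epochs never span removed artifact intervals.
#'
#' @param seg A `clean_segment`.
#' @param duration_s Epoch length in seconds (default 5).
#' @param stride_s Stride between consecutive epoch starts in seconds
#'   (default 2.5, i.e. 50% overlap); must satisfy
#'   `0 < stride_s <= duration_s`.
#' @return A list of `eeg_epoch` objects (possibly empty).
#' @export
extract_epochs <- function(seg, duration_s = 5, stride_s = 2.5) {
  stopifnot(inherits(seg, "clean_segment"))
  if (!(stride_s > 0 && stride_s <= duration_s)) {
    stop("need 0 < stride_s <= duration_s", call. = FALSE)
  }
  fs <- seg$fs_hz
  L <- round(duration_s * fs)
  S <- stride_s * fs
  n <- ncol(seg$samples)
  if (n < L) {
    return(list())
  }
  n_epochs <- floor((n - L) / S) + 1L
  lapply(seq_len(n_epochs), function(k) {
    a <- round((k - 1L) * S)
    structure(
      list(subject_id = seg$subject_id, class_label = seg$class_label,
           samples = seg$samples[, (a + 1L):(a + L), drop = FALSE],
           start_time_s = seg$start_offset_s + a / fs,
           duration_s = duration_s, fs_hz = fs),
      class = "eeg_epoch")
  })
}

#' Band energy of one epoch channel
#'
#' Sum of squared samples of the band-filtered signal (zero-phase
#' Butterworth), in microvolt-squared sample units. Absolute, not
#' epoch-normalised.
#'
#' @param x Numeric vector, one channel of one epoch.
#' @param band One-row band table (see [band_definition()]).
#' @param fs_hz Sampling rate (Hz); the band must lie below Nyquist.
#' @param order Butterworth order.
#' @return Non-negative scalar energy.
#' @export
band_energy <- function(x, band, fs_hz, order = 4L) {
  check_bands(band, fs_hz)
  ba <- design_butter(order, c(band$low_hz, band$high_hz), fs_hz)
  sum(zerophase_filter(ba, x)^2)
}

#' Time-domain features of one epoch channel
#'
#' @param x Numeric vector with at least two samples.
#' @return Named vector `c(mean, variance, iqr)`: arithmetic mean,
#'   population variance (divisor `length(x)`), and interquartile range
#'   Q3 - Q1.
#' @export
time_domain_features <- function(x) {
  if (length(x) < 2L) {
    stop("need at least two samples", call. = FALSE)
  }
  m <- mean(x)
  c(mean = m,
    variance = sum((x - m)^2) / length(x),
    iqr = unname(stats::quantile(x, 0.75) - stats::quantile(x, 0.25)))
}

feature_suffixes <- function(bands) {
  c(paste0("energy_", bands$name), "mean", "variance", "iqr")
}

#' Assemble the per-epoch classification table
#'
#' One row per epoch. Columns, in channel order, are the five band energies
#' followed by mean, variance and IQR for each channel (named
#' `<channel>_<feature>` with non-alphanumeric characters in channel names
#' replaced by `.`), then a final `class` factor column. For a 17-channel
#' montage this yields 137 columns. Subject ids are carried as the
#' `"subject_id"` attribute -- grouping metadata, never a predictor; use
#' [feature_subjects()] to retrieve them.
#'
#' @param epochs List of `eeg_epoch` objects sharing one channel schema and
#'   sampling rate.
#' @param bands Band definition table (default [eeg_bands()]).
#' @param order Butterworth order for the band-energy filters.
#' @param channel_names Channel schema to use when `epochs` is empty (a
#'   header-only table is then returned); ignored otherwise.
#' @return A data frame of class `feature_table`.
#' @export
build_feature_table <- function(epochs, bands = eeg_bands(), order = 4L,
                                channel_names = NULL) {
  check_bands(bands)
  if (length(epochs) == 0L) {
    if (is.null(channel_names)) {
      stop("no epochs and no channel_names; cannot infer the schema",
           call. = FALSE)
    }
    safe_ch <- gsub("[^A-Za-z0-9]", ".", channel_names)
    cols <- as.vector(vapply(safe_ch, function(cn) {
      paste(cn, feature_suffixes(bands), sep = "_")
    }, character(nrow(bands) + 3L)))
    out <- as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(cols)), cols))
    out$class <- factor(character(0), levels = c("AD", "FTD", "CN"))
    attr(out, "subject_id") <- character(0)
    class(out) <- c("feature_table", "data.frame")
    return(out)
  }
  ch <- rownames(epochs[[1]]$samples)
  fs <- epochs[[1]]$fs_hz
  for (e in epochs) {
    if (!identical(rownames(e$samples), ch) || e$fs_hz != fs) {
      stop("epochs have mixed channel schemas or sampling rates",
           call. = FALSE)
    }
  }
  check_bands(bands, fs)
  bas <- lapply(seq_len(nrow(bands)), function(k) {
    design_butter(order, c(bands$low_hz[k], bands$high_hz[k]), fs)
  })
  nfeat <- nrow(bands) + 3L
  feats <- t(vapply(epochs, function(e) {
    as.vector(vapply(seq_along(ch), function(ci) {
      x <- e$samples[ci, ]
      energies <- vapply(bas, function(ba) sum(zerophase_filter(ba, x)^2),
                         numeric(1))
      c(energies, time_domain_features(x))
    }, numeric(nfeat)))
  }, numeric(nfeat * length(ch))))

  safe_ch <- gsub("[^A-Za-z0-9]", ".", ch)
  colnames(feats) <- as.vector(vapply(safe_ch, function(cn) {
    paste(cn, feature_suffixes(bands), sep = "_")
  }, character(nfeat)))
  out <- as.data.frame(feats)
  out$class <- factor(vapply(epochs, `[[`, character(1), "class_label"),
                      levels = intersect(c("AD", "FTD", "CN"),
                                         unique(vapply(epochs, `[[`,
                                                       character(1),
                                                       "class_label"))))
  attr(out, "subject_id") <- vapply(epochs, `[[`, character(1), "subject_id")
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Subject ids of a feature table
#'
#' @param table A `feature_table`.
#' @return Character vector, one subject id per row.
#' @export
feature_subjects <- function(table) {
  s <- attr(table, "subject_id")
  if (is.null(s)) {
    stop("table carries no subject_id attribute", call. = FALSE)
  }
  s
}

# Row-subset a feature table keeping the subject_id attribute in sync.
ft_rows <- function(table, idx) {
  out <- table[idx, , drop = FALSE]
  attr(out, "subject_id") <- feature_subjects(table)[idx]
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' The features and the label column go to `path`; the subject grouping
#' vector goes to a parallel `<path>.groups.csv` (columns `row`,
#' `subject_id`, `class`) so that subject identity stays out of the
#' predictor matrix but survives a round trip.
#'
#' @param table A `feature_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  grp <- data.frame(row = seq_len(nrow(table)),
                    subject_id = feature_subjects(table),
                    class = as.character(table$class))
  utils::write.csv(grp, paste0(path, ".groups.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df$class <- factor(df$class,
                     levels = intersect(c("AD", "FTD", "CN"),
                                        unique(df$class)))
  gpath <- paste0(path, ".groups.csv")
  if (file.exists(gpath)) {
    grp <- utils::read.csv(gpath)
    attr(df, "subject_id") <- as.character(grp$subject_id)
  }
  class(df) <- c("feature_table", "data.frame")
  df
}

#' Features for a whole recording
#'
#' Convenience wrapper: preprocess, epoch every clean segment, and build
#' the feature table for one recording.
#'
#' @param rec An [eeg_recording()].
#' @param duration_s,stride_s Epoching parameters.
#' @param bands Band definitions.
#' @param target_fs_hz Working rate for preprocessing.
#' @return A `feature_table` (or `NULL` if no segment holds a full epoch).
#' @export
recording_features <- function(rec, duration_s = 5, stride_s = 2.5,
                               bands = eeg_bands(), target_fs_hz = 250) {
  segs <- preprocess_recording(rec, target_fs_hz = target_fs_hz)
  epochs <- unlist(lapply(segs, extract_epochs, duration_s = duration_s,
                          stride_s = stride_s), recursive = FALSE)
  if (length(epochs) == 0L) {
    return(NULL)
  }
  build_feature_table(epochs, bands)
}

#' Features for a cohort of recordings
#'
#' @param cohort List of [eeg_recording()] objects.
#' @inheritParams recording_features
#' @return A single `feature_table` with all subjects' epochs stacked.
#' @export
cohort_features <- function(cohort, duration_s = 5, stride_s = 2.5,
                            bands = eeg_bands(), target_fs_hz = 250) {
  tables <- lapply(cohort, recording_features, duration_s = duration_s,
                   stride_s = stride_s, bands = bands,
                   target_fs_hz = target_fs_hz)
  empty <- vapply(tables, is.null, logical(1))
  if (all(empty)) {
    stop("no recording yielded a full epoch", call. = FALSE)
  }
  if (any(empty)) {
    warning(sprintf("%d recording(s) yielded no epochs and were dropped",
                    sum(empty)))
    tables <- tables[!empty]
  }
  subjects <- unlist(lapply(tables, feature_subjects))
  out <- do.call(rbind, lapply(tables, as.data.frame))
  out$class <- factor(out$class,
                      levels = intersect(c("AD", "FTD", "CN"),
                                         unique(as.character(out$class))))
  attr(out, "subject_id") <- subjects
  class(out) <- c("feature_table", "data.frame")
  out
}
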