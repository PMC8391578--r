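# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, expr, envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# A 4-subject null cohort (no class effect, strong subject fingerprints)
# on the default 17-channel montage: the smallest cohort on which both
# validation schemes run.
tiny_null_spec <- function() {
  cohort_spec(n_per_class = c(AD = 2, CN = 2), duration_s = 60,
              sigma_subject = 1, class_effect_scale = 0, seed = 101)
}

tiny_null_cohort <- function() {
  cached("tiny_null_cohort", generate_cohort(tiny_null_spec()))
}

tiny_null_features <- function() {
  cached("tiny_null_features", cohort_features(tiny_null_cohort()))
}

# Hand-built feature table: two numeric features per epoch, Gaussian blobs
# per subject around a class centre. Deterministic given seed.
toy_feature_table <- function(n_subj_per_class = 2L, epochs_per_subj = 10L,
                              class_sep = 10, subject_sep = 0, noise = 0.5,
                              classes = c("AD", "CN"), seed = 7L) {
  set.seed(seed)
  rows <- list()
  subjects <- character(0)
  for (ci in seq_along(classes)) {
    for (s in seq_len(n_subj_per_class)) {
      centre <- c(ci * class_sep, -ci * class_sep) +
        stats::rnorm(2, 0, subject_sep)
      f <- matrix(stats::rnorm(2 * epochs_per_subj, 0, noise),
                  ncol = 2, byrow = TRUE)
      f <- sweep(f, 2, centre, "+")
      rows[[length(rows) + 1L]] <- data.frame(
        f1 = f[, 1], f2 = f[, 2],
        class = classes[ci], stringsAsFactors = FALSE)
      subjects <- c(subjects, rep(sprintf("%s%02d", classes[ci], s),
                                  epochs_per_subj))
    }
  }
  out <- do.call(rbind, rows)
  out$class <- factor(out$class, levels = classes)
  attr(out, "subject_id") <- subjects
  class(out) <- c("feature_table", "data.frame")
  out
}

# Build a recording directly from a samples matrix.
matrix_recording <- function(samples, fs_hz, subject_id = "S01",
                             class_label = "CN",
                             artifact_intervals = list()) {
  eeg_recording(subject_id, class_label, fs_hz,
                paste0("ch", seq_len(nrow(samples))), samples,
                artifact_intervals)
}

# One clean segment wrapping a single-channel signal.
signal_segment <- function(x, fs_hz, subject_id = "S01",
                           class_label = "CN") {
  segs <- remove_artifacts(matrix_recording(matrix(x, nrow = 1), fs_hz,
                                            subject_id, class_label))
  segs[[1]]
}

# Relative band-power oracle: raw periodogram integrated over the band,
# normalised by the 0.5-48 Hz total. Independent of the Butterworth
# filter-bank used by both the generator and the feature extractor.
periodogram_band_share <- function(x, fs_hz, low_hz, high_hz,
                                   total = c(0.5, 48)) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs_hz / n
  half <- freqs <= fs_hz / 2
  p <- p[half]; freqs <- freqs[half]
  num <- sum(p[freqs >= low_hz & freqs < high_hz])
  den <- sum(p[freqs >= total[1] & freqs < total[2]])
  num / den
}
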