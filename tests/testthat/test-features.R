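test_that("epoch counts follow floor((T - dur)/stride) + 1", {
  fs <- 100
  mk <- function(dur_s) signal_segment(seq_len(round(dur_s * fs)), fs)
  expect_length(extract_epochs(mk(60), 5, 2.5), 23L)
  expect_length(extract_epochs(mk(5), 5, 2.5), 1L)
  expect_length(extract_epochs(mk(4.9), 5, 2.5), 0L)
  expect_error(extract_epochs(mk(10), 5, 6), "stride")
})

test_that("consecutive epochs overlap by duration minus stride", {
  fs <- 100
  seg <- signal_segment(seq_len(20 * fs), fs)
  eps <- extract_epochs(seg, 5, 2.5)
  L <- 5 * fs
  shared <- 2.5 * fs  # samples shared between consecutive epochs
  for (i in seq_len(length(eps) - 1L)) {
    expect_identical(eps[[i]]$samples[1, (L - shared + 1):L],
                     eps[[i + 1]]$samples[1, 1:shared])
    expect_equal(eps[[i + 1]]$start_time_s - eps[[i]]$start_time_s, 2.5)
  }
})

test_that("band energies localise sinusoids and match the Parseval oracle", {
  fs <- 250
  t <- seq_len(5 * fs) / fs
  bands <- eeg_bands()
  for (zero_band in bands$name) {
    e <- band_energy(numeric(1000), bands[bands$name == zero_band, ], fs)
    expect_equal(e, 0)
  }
  x <- sin(2 * pi * 10 * t)
  e <- vapply(seq_len(nrow(bands)), function(k) {
    band_energy(x, bands[k, ], fs)
  }, numeric(1))
  names(e) <- bands$name
  expect_gte(e[["alpha"]] / sum(e), 0.95)
  # Parseval oracle: total signal energy = sum x^2; the alpha filter should
  # pass nearly all of it for an in-band sinusoid
  expect_lt(abs(e[["alpha"]] - sum(x^2)) / sum(x^2), 0.05)

  x2 <- sin(2 * pi * 2 * t)
  e2 <- vapply(seq_len(nrow(bands)), function(k) {
    band_energy(x2, bands[k, ], fs)
  }, numeric(1))
  expect_equal(bands$name[which.max(e2)], "delta")

  expect_error(band_energy(x, band_definition("hf", 100, 130), fs),
               "Nyquist")
})

test_that("time-domain features use population variance and Q3 - Q1", {
  expect_equal(time_domain_features(rep(3.2, 100)),
               c(mean = 3.2, variance = 0, iqr = 0))
  expect_equal(time_domain_features(c(1, 2, 3, 4)),
               c(mean = 2.5, variance = 1.25, iqr = 1.5))
  set.seed(8)
  x <- rnorm(500)
  a <- time_domain_features(x)
  b <- time_domain_features(x + 10)
  expect_equal(b[["mean"]], a[["mean"]] + 10)
  expect_equal(b[["variance"]], a[["variance"]])
  expect_equal(b[["iqr"]], a[["iqr"]])
  expect_error(time_domain_features(numeric(1)), "two samples")
})

test_that("the feature table has 8 features per channel plus one label", {
  fs <- 250
  seg <- signal_segment(rnorm(5 * fs), fs)
  eps <- extract_epochs(seg, 5, 2.5)
  tab1 <- build_feature_table(eps)
  expect_equal(ncol(tab1), 9L)  # 8 x 1 channel + class
  expect_equal(nrow(tab1), 1L)
  expect_identical(names(tab1)[1:8],
                   paste0("ch1_", c("energy_delta", "energy_theta",
                                    "energy_alpha", "energy_beta",
                                    "energy_gamma", "mean", "variance",
                                    "iqr")))
  expect_identical(names(tab1)[9], "class")
  expect_true(all(tab1[, grep("energy|variance|iqr", names(tab1))] >= 0))

  # empty epoch list with a declared schema: header-only table
  tab0 <- build_feature_table(list(), channel_names = c("a", "b"))
  expect_equal(nrow(tab0), 0L)
  expect_equal(ncol(tab0), 17L)

  # mixed channel schemas are rejected
  seg2 <- remove_artifacts(
    eeg_recording("S02", "CN", fs, c("x", "y"),
                  matrix(rnorm(2 * 5 * fs), nrow = 2)))[[1]]
  eps2 <- extract_epochs(seg2, 5, 2.5)
  expect_error(build_feature_table(c(eps, eps2)), "mixed channel")
})

test_that("feature tables survive a CSV round trip", {
  ft <- cached("csv_ft", {
    spec <- cohort_spec(n_per_class = c(AD = 1, CN = 1), duration_s = 20,
                        channel_names = c("a", "b"), seed = 12)
    cohort_features(generate_cohort(spec))
  })
  path <- tempfile(fileext = ".csv")
  write_feature_csv(ft, path)
  back <- read_feature_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-8)
  expect_identical(feature_subjects(back), feature_subjects(ft))
})

test_that("the five band energies approximately partition broadband energy", {
  fs <- 250
  set.seed(31)
  seg <- signal_segment(rnorm(30 * fs), fs)
  seg <- butterworth_bandpass(seg, 0.5, 48)
  eps <- extract_epochs(seg, 5, 2.5)
  bands <- eeg_bands()
  for (e in eps[c(1, 5, 9)]) {
    x <- e$samples[1, ]
    be <- vapply(seq_len(nrow(bands)), function(k) {
      band_energy(x, bands[k, ], fs)
    }, numeric(1))
    # the -3 dB crossovers lose ~25% of the energy in the seam bins under
    # zero-phase (squared-response) filtering, so the partition is
    # approximate: 15% tolerance
    expect_lt(abs(sum(be) - sum(x^2)) / sum(x^2), 0.15)
  }
})

test_that("epoch-mean band energies recover the generator's shares", {
  shares <- c(delta = 0.25, theta = 0.15, alpha = 0.35, beta = 0.18,
              gamma = 0.07)
  spec <- cohort_spec(n_per_class = c(CN = 1), duration_s = 60,
                      sigma_subject = 0, noise_floor = 0, seed = 77,
                      channel_names = c("a", "b"))
  ft <- cohort_features(generate_cohort(spec, list(CN = log(shares))))
  for (ch in c("a", "b")) {
    e_cols <- paste0(ch, "_energy_", names(shares))
    em <- as.matrix(as.data.frame(ft)[e_cols])
    rec_shares <- colMeans(em / rowSums(em))
    expect_lt(max(abs(rec_shares - shares) / shares), 0.10)
  }
})
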