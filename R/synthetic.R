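#' Default class-level spectral profiles (EEG slowing)
#'
#' Mean log relative band powers for the three cohorts. The AD and FTD
#' profiles encode EEG slowing relative to controls -- elevated delta and
#' theta shares, reduced alpha and beta -- with FTD intermediate between
#' AD and CN. Magnitudes are package defaults chosen to be plausible for
#' eyes-closed resting recordings; direction, not magnitude, is the
#' modelled phenomenon.
#'
#' @return A named list mapping class label to a named numeric vector of
#'   log relative band power (delta..gamma, summing to 1 after `exp`).
#' @export
class_profiles_default <- function() {
  shares <- list(
    AD  = c(delta = 0.40, theta = 0.25, alpha = 0.18, beta = 0.12, gamma = 0.05),
    FTD = c(delta = 0.35, theta = 0.22, alpha = 0.22, beta = 0.14, gamma = 0.07),
    CN  = c(delta = 0.25, theta = 0.15, alpha = 0.35, beta = 0.18, gamma = 0.07)
  )
  lapply(shares, log)
}

#' Default 17-channel bipolar anterior-posterior montage labels
#'
#' Channel labels for a double-banana style bipolar montage reduced to 17
#' derivations: the four lateral chains plus a single midline derivation.
#' The generator treats these labels as opaque names; any character vector
#' may be substituted.
#'
#' @return Character vector of 17 channel names.
#' @export
default_montage_channels <- function() {
  c("Fp1-F7", "F7-T3", "T3-T5", "T5-O1",
    "Fp2-F8", "F8-T4", "T4-T6", "T6-O2",
    "Fp1-F3", "F3-C3", "C3-P3", "P3-O1",
    "Fp2-F4", "F4-C4", "C4-P4", "P4-O2",
    "Fz-Cz")
}

#' Specify a synthetic EEG cohort
#'
#' Collects every knob of the cohort generator. Defaults reproduce the
#' shape of the clinical study the package models: 10 AD, 10 FTD and 8 CN
#' subjects; 13-minute recordings for the patient groups and 21 minutes
#' for controls; 500 Hz native sampling over a 17-channel bipolar montage.
#'
#' @param n_per_class Named integer vector, subjects per class (labels from
#'   AD/FTD/CN). All counts must be >= 1.
#' @param duration_s Recording duration in seconds: a scalar applied to all
#'   classes, or a named vector per class.
#' @param fs_hz Native sampling rate (Hz); must exceed twice the highest
#'   band edge.
#' @param channel_names Ordered channel labels.
#' @param sigma_subject Standard deviation of the per-band log-power subject
#'   fingerprint offsets (dimensionless, log scale). Larger values make
#'   individual subjects more spectrally distinctive and therefore make
#'   epoch-level leakage stronger.
#' @param class_effect_scale Multiplier on between-class profile
#'   differences: 1 uses the class profiles as given, 0 removes all class
#'   signal (every class shares the grand-mean profile).
#' @param noise_floor Relative power of an additional broadband (0.5--48 Hz)
#'   noise term shared across bands.
#' @param sigma_gain Log-scale SD of per-channel multiplicative gains.
#' @param bands Band definition table, see [eeg_bands()].
#' @param band_margin Fraction of each band's width by which the
#'   synthesized component is inset from the nominal band edges, so that a
#'   band's power is never parked on the seam where adjacent analysis
#'   filters split it.
#' @param max_component_hz Ceiling on synthesized rhythm content (Hz).
#'   Scalp gamma is typically reported up to ~45 Hz; the default keeps the
#'   gamma component clear of both the conditioning filter's 48 Hz corner
#'   and the 50 Hz line-noise region.
#' @param seed Integer seed; the single source of randomness for profile
#'   and signal generation.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_class = c(AD = 10, FTD = 10, CN = 8),
                        duration_s = c(AD = 780, FTD = 780, CN = 1260),
                        fs_hz = 500,
                        channel_names = default_montage_channels(),
                        sigma_subject = 0.5,
                        class_effect_scale = 1,
                        noise_floor = 0.02,
                        sigma_gain = 0.1,
                        bands = eeg_bands(),
                        band_margin = 0.15,
                        max_component_hz = 42,
                        seed = 1L) {
  stopifnot(length(n_per_class) >= 1, all(n_per_class >= 1),
            !is.null(names(n_per_class)))
  if (!all(names(n_per_class) %in% c("AD", "FTD", "CN"))) {
    stop("class labels must be among AD, FTD, CN", call. = FALSE)
  }
  check_bands(bands, fs_hz)
  if (length(duration_s) == 1L && is.null(names(duration_s))) {
    duration_s <- stats::setNames(rep(duration_s, length(n_per_class)),
                                  names(n_per_class))
  }
  if (!all(names(n_per_class) %in% names(duration_s))) {
    stop("duration_s must cover every class in n_per_class", call. = FALSE)
  }
  stopifnot(all(duration_s > 0), noise_floor >= 0, sigma_subject >= 0,
            class_effect_scale >= 0, sigma_gain >= 0,
            band_margin >= 0, band_margin < 0.5)
  structure(
    list(n_per_class = n_per_class, duration_s = duration_s, fs_hz = fs_hz,
         channel_names = channel_names, sigma_subject = sigma_subject,
         class_effect_scale = class_effect_scale, noise_floor = noise_floor,
         sigma_gain = sigma_gain, bands = bands, band_margin = band_margin,
         max_component_hz = max_component_hz, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# Spectral support of one synthesized band component: the nominal band
# inset by band_margin x width at each edge and capped at max_component_hz.
component_support <- function(low_hz, high_hz, band_margin, max_component_hz) {
  w <- high_hz - low_hz
  lo <- low_hz + band_margin * w
  hi <- min(high_hz - band_margin * w, max_component_hz)
  if (hi <= lo) {
    stop(sprintf("band %g-%g Hz has empty component support", low_hz,
                 high_hz), call. = FALSE)
  }
  c(lo, hi)
}

# Unit-variance Gaussian noise whose spectrum is confined to [lo, hi] Hz:
# white noise masked in the frequency domain (padded to a fast FFT length,
# then truncated and re-normalised).
band_limited_noise <- function(n, lo_hz, hi_hz, fs_hz) {
  m <- stats::nextn(n, c(2L, 3L, 5L))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  freq <- (seq_len(m) - 1) * fs_hz / m
  folded <- pmin(freq, fs_hz - freq)
  W[folded < lo_hz | folded >= hi_hz] <- 0
  x <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

# derived per-subject seed, kept within 32-bit integer range
subject_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * i) %% 2147483647)
}

#' Draw subject profiles for a cohort
#'
#' Each subject's log band powers are the grand-mean profile plus
#' `class_effect_scale` times the class deviation from that mean, plus an
#' i.i.d. Normal(0, sigma_subject^2) fingerprint offset per band. With
#' `class_effect_scale = 0` the expected profile is identical across
#' classes while subjects still differ -- the null configuration used to
#' isolate epoch leakage. Per-channel gains are log-normal.
#'
#' @param spec A [cohort_spec()].
#' @param profiles Named list of class log-power vectors, one per class in
#'   `spec$n_per_class`; see [class_profiles_default()].
#' @return A list of `subject_profile` objects, one per subject, in
#'   deterministic order given `spec$seed`.
#' @export
make_subject_profiles <- function(spec, profiles = class_profiles_default()) {
  stopifnot(inherits(spec, "cohort_spec"))
  classes <- names(spec$n_per_class)
  missing <- setdiff(classes, names(profiles))
  if (length(missing)) {
    stop(sprintf("no spectral profile for class(es): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  band_names <- spec$bands$name
  prof_mat <- do.call(rbind, lapply(profiles[classes], function(p) {
    if (!all(band_names %in% names(p))) {
      stop("class profile missing band(s)", call. = FALSE)
    }
    p[band_names]
  }))
  grand_mean <- colMeans(prof_mat)

  set.seed(spec$seed)
  out <- list()
  i <- 0L
  for (cl in classes) {
    class_lp <- grand_mean +
      spec$class_effect_scale * (prof_mat[cl, ] - grand_mean)
    for (j in seq_len(spec$n_per_class[[cl]])) {
      i <- i + 1L
      fingerprint <- stats::rnorm(length(band_names), 0, spec$sigma_subject)
      gains <- exp(stats::rnorm(length(spec$channel_names), 0, spec$sigma_gain))
      out[[i]] <- structure(
        list(subject_id = sprintf("%s%02d", cl, j),
             class_label = cl,
             band_log_power = stats::setNames(class_lp + fingerprint,
                                              band_names),
             channel_gain = stats::setNames(gains, spec$channel_names),
             seed = subject_seed(spec$seed, i)),
        class = "subject_profile")
    }
  }
  out
}

#' Synthesize one subject's recording from a profile
#'
#' Each channel is a sum over bands of band-limited unit-variance Gaussian
#' noise weighted by the square root of the profile's band power, scaled by
#' the channel gain, plus a broadband (0.5--48 Hz) Butterworth-filtered
#' noise-floor term. Each band component is synthesized strictly inside its
#' nominal band (see `band_margin` and `max_component_hz` in
#' [cohort_spec()]): power is never parked on the seams where adjacent
#' analysis filters split it, which is what makes the specified band-power
#' shares recoverable from the downstream band-energy features. The
#' waveform is reproducible from the profile's seed alone.
#'
#' @param profile A `subject_profile` from [make_subject_profiles()].
#' @param spec The [cohort_spec()] that produced the profile.
#' @param order Butterworth order for the noise-floor filter.
#' @return An [eeg_recording()].
#' @export
synthesize_recording <- function(profile, spec, order = 4L) {
  stopifnot(inherits(profile, "subject_profile"),
            inherits(spec, "cohort_spec"))
  check_bands(spec$bands, spec$fs_hz)
  fs <- spec$fs_hz
  dur <- spec$duration_s[[profile$class_label]]
  n <- round(dur * fs)
  nch <- length(spec$channel_names)
  supports <- lapply(seq_len(nrow(spec$bands)), function(k) {
    component_support(spec$bands$low_hz[k], spec$bands$high_hz[k],
                      spec$band_margin, spec$max_component_hz)
  })
  ba_broad <- design_butter(order, c(min(spec$bands$low_hz),
                                     max(spec$bands$high_hz)), fs)
  amp <- sqrt(exp(profile$band_log_power))

  set.seed(profile$seed)
  samples <- matrix(0, nrow = nch, ncol = n,
                    dimnames = list(spec$channel_names, NULL))
  for (ch in seq_len(nch)) {
    sig <- numeric(n)
    for (k in seq_along(supports)) {
      sig <- sig + amp[k] * band_limited_noise(n, supports[[k]][1],
                                               supports[[k]][2], fs)
    }
    if (spec$noise_floor > 0) {
      bb <- zerophase_filter(ba_broad, stats::rnorm(n))
      sig <- sig + sqrt(spec$noise_floor) * bb / stats::sd(bb)
    }
    samples[ch, ] <- sig * profile$channel_gain[ch]
  }
  eeg_recording(profile$subject_id, profile$class_label, fs,
                spec$channel_names, samples)
}

#' Generate a full synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @param profiles Class spectral profiles; see [class_profiles_default()].
#' @return A list of [eeg_recording()] objects, one per subject, with
#'   unique subject ids and class labels attached. Deterministic given
#'   `spec$seed`.
#' @export
generate_cohort <- function(spec, profiles = class_profiles_default()) {
  subject_profiles <- make_subject_profiles(spec, profiles)
  lapply(subject_profiles, synthesize_recording, spec = spec)
}
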