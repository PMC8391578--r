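#' @importFrom signal butter
NULL

# Design a Butterworth filter for a sampling rate. type is "pass" or "low".
design_butter <- function(order, edges_hz, fs_hz, type = c("pass", "low")) {
  type <- match.arg(type)
  nyq <- fs_hz / 2
  if (any(edges_hz <= 0) || any(edges_hz >= nyq)) {
    stop(sprintf("filter edge(s) [%s] Hz outside (0, Nyquist = %g Hz)",
                 paste(edges_hz, collapse = ", "), nyq), call. = FALSE)
  }
  signal::butter(order, edges_hz / nyq, type = type)
}

# Zero-phase (forward-backward) IIR filtering with odd-reflection padding.
# Padding length is 3 x (number of filter coefficients - 1), enough to let
# the filter state settle before the retained samples begin, so epoch-edge
# transients do not contaminate the output.
zerophase_filter <- function(ba, x) {
  b <- ba$b
  a <- ba$a
  np <- 3L * (max(length(a), length(b)) - 1L)
  n <- length(x)
  if (n <= np) {
    stop(sprintf("signal too short for zero-phase filtering (need > %d samples)",
                 np), call. = FALSE)
  }
  pre <- 2 * x[1L] - x[(np + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - np)]
  xp <- c(pre, x, post)
  y <- as.numeric(signal::filter(b, a, xp))
  y <- rev(as.numeric(signal::filter(b, a, rev(y))))
  y[(np + 1L):(np + n)]
}

# Apply zero-phase filter to each row of a channels x samples matrix.
zerophase_filter_rows <- function(ba, mat) {
  out <- t(apply(mat, 1L, function(ch) zerophase_filter(ba, ch)))
  dimnames(out) <- dimnames(mat)
  out
}

# Magnitude response of a designed filter at given frequencies (Hz),
# single-pass; square it for the zero-phase (filtfilt) response.
butter_response <- function(ba, freqs_hz, fs_hz) {
  w <- 2 * pi * freqs_hz / fs_hz
  z <- exp(1i * w)
  num <- vapply(z, function(zz) sum(ba$b * zz^(-(seq_along(ba$b) - 1L))),
                complex(1))
  den <- vapply(z, function(zz) sum(ba$a * zz^(-(seq_along(ba$a) - 1L))),
                complex(1))
  Mod(num / den)
}
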