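#' Canonical EEG rhythm bands
#'
#' The five classical scalp-EEG rhythm bands used throughout the package.
#' The defaults partition 0.5--48 Hz without gaps or overlaps:
#' delta 0.5--4, theta 4--8, alpha 8--12, beta 12--25, gamma 25--48 Hz.
#'
#' @return A data frame with columns `name`, `low_hz`, `high_hz`, one row
#'   per band, in delta..gamma order.
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low_hz = c(0.5, 4, 8, 12, 25),
    high_hz = c(4, 8, 12, 25, 48),
    stringsAsFactors = FALSE
  )
}

#' Define a single frequency band
#'
#' @param name Band name (a non-empty string).
#' @param low_hz,high_hz Band edges in Hz; `low_hz` must be strictly below
#'   `high_hz` and both must be positive.
#' @return A one-row data frame matching the schema of [eeg_bands()].
#' @export
band_definition <- function(name, low_hz, high_hz) {
  stopifnot(is.character(name), nzchar(name), length(name) == 1L)
  if (!is.numeric(low_hz) || !is.numeric(high_hz) || low_hz <= 0 ||
      low_hz >= high_hz) {
    stop("band edges must satisfy 0 < low_hz < high_hz", call. = FALSE)
  }
  data.frame(name = name, low_hz = low_hz, high_hz = high_hz,
             stringsAsFactors = FALSE)
}

# validate a band table and check edges against a Nyquist frequency
check_bands <- function(bands, fs_hz = NULL) {
  stopifnot(is.data.frame(bands),
            all(c("name", "low_hz", "high_hz") %in% names(bands)))
  if (any(bands$low_hz >= bands$high_hz) || any(bands$low_hz <= 0)) {
    stop("invalid band edges: need 0 < low_hz < high_hz", call. = FALSE)
  }
  if (anyDuplicated(bands$name)) {
    stop("duplicated band names", call. = FALSE)
  }
  if (!is.null(fs_hz) && any(bands$high_hz >= fs_hz / 2)) {
    stop(sprintf("band edge at or above Nyquist (%g Hz)", fs_hz / 2),
         call. = FALSE)
  }
  invisible(bands)
}
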