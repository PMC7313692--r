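#' One-sided periodogram of a 2-s sub-epoch
#'
#' Windowed periodogram on the full window (0.5 Hz bins for a 2-s window
#' at 250 Hz), one-sided, normalized so that Parseval holds for the
#' windowed signal: `sum(power) == mean((x * w)^2)`.
#'
#' @param x numeric samples (a sub-epoch, nominally 500 samples) or a
#'   `sub_epoch`.
#' @param fs sample rate (Hz).
#' @param window `"hann"` (default) or `"rect"`.
#' @return an `eeg_spectrum`: list with `frequencies` (Hz, from 0 to
#'   Nyquist), `power`, `fs`, `n`.
#' @export
compute_spectrum <- function(x, fs = 250, window = c("hann", "rect")) {
  if (inherits(x, "sub_epoch")) x <- x$eeg
  window <- match.arg(window)
  n <- length(x)
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) else rep(1, n)
  X <- stats::fft(x * w)
  p <- Mod(X)^2 / n^2
  half <- floor(n / 2) + 1
  pow <- p[seq_len(half)]
  if (n %% 2 == 0) {
    pow[2:(half - 1)] <- 2 * pow[2:(half - 1)]
  } else {
    pow[2:half] <- 2 * pow[2:half]
  }
  sp <- list(frequencies = (seq_len(half) - 1) * fs / n, power = pow,
             fs = fs, n = n, window = window)
  class(sp) <- "eeg_spectrum"
  sp
}

#' Summed spectral power in a frequency band
#'
#' Sums periodogram bins in a band. Bins are assigned by the
#' lower-edge-open rule `low < f <= high`, so contiguous bands partition
#' exactly; the 0.5 Hz analysis floor is included when `low` equals it
#' (`lower_closed = TRUE` by default at 0.5 Hz).
#'
#' @param spec an `eeg_spectrum`.
#' @param low,high band edges (Hz).
#' @param lower_closed include a bin at exactly `low`.
#' @return summed power in the band.
#' @export
band_power <- function(spec, low, high, lower_closed = (low <= 0.5)) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  f <- spec$frequencies
  sel <- if (lower_closed) f >= low & f <= high else f > low & f <= high
  sum(spec$power[sel])
}

#' Band-power ratio features from one sub-epoch spectrum
#'
#' Computes the seven spectral ratio parameters:
#' \describe{
#'   \item{alpha_pr}{P(8-13] / P\[0.5-47\]}
#'   \item{beta_pr}{P(13-30] / P\[0.5-47\]}
#'   \item{delta_pr}{P\[0.5-4\] / P\[0.5-47\]}
#'   \item{theta_pr}{P(4-8] / P\[0.5-47\]}
#'   \item{bg_alpha_plus}{P(8-47] / P\[0.5-47\]}
#'   \item{beta_r}{log(P(30-47] / P(11-20])}
#'   \item{delta_r}{log(P(8-20] / P(1-4])}
#' }
#' Shared band edges belong to the lower band, so
#' `delta_pr + theta_pr + bg_alpha_plus == 1` exactly. A zero denominator
#' yields `NA` with a warning (degenerate signal).
#'
#' @param spec an `eeg_spectrum` covering 0.5-47 Hz.
#' @param log_base base for the log-ratio features.
#' @return named list of the seven ratio features.
#' @export
compute_power_ratios <- function(spec, log_base = exp(1)) {
  stopifnot(inherits(spec, "eeg_spectrum"))
  total <- band_power(spec, 0.5, 47, lower_closed = TRUE)
  safe_ratio <- function(num, den, what, take_log = FALSE) {
    if (den <= 0 || (take_log && num <= 0)) {
      warning("undefined feature ", what, ": degenerate band power")
      return(NA_real_)
    }
    if (take_log) log(num / den, base = log_base) else num / den
  }
  list(
    alpha_pr = safe_ratio(band_power(spec, 8, 13, FALSE), total, "alpha_pr"),
    beta_pr = safe_ratio(band_power(spec, 13, 30, FALSE), total, "beta_pr"),
    delta_pr = safe_ratio(band_power(spec, 0.5, 4, TRUE), total, "delta_pr"),
    theta_pr = safe_ratio(band_power(spec, 4, 8, FALSE), total, "theta_pr"),
    bg_alpha_plus = safe_ratio(band_power(spec, 8, 47, FALSE), total, "bg_alpha_plus"),
    beta_r = safe_ratio(band_power(spec, 30, 47, FALSE),
                        band_power(spec, 11, 20, FALSE), "beta_r", TRUE),
    delta_r = safe_ratio(band_power(spec, 8, 20, FALSE),
                         band_power(spec, 1, 4, FALSE), "delta_r", TRUE)
  )
}
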