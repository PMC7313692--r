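#' Direct (FFT-based) bispectrum over the three sub-epochs
#'
#' For each 2-s sub-epoch window the triple product
#' `X(f1) * X(f2) * Conj(X(f1 + f2))` is evaluated on the principal
#' bifrequency domain (`f1 <= f2`, `f1 + f2 <=` Nyquist). The three
#' windows form the averaging ensemble: the complex triple products are
#' averaged across windows first and the magnitude of the mean is
#' reported, so phase-random (uncoupled) content cancels while
#' quadratically phase-coupled triples survive.
#'
#' @param subs list of three sub-epochs (numeric vectors or `sub_epoch`
#'   objects, 500 samples each at 250 Hz).
#' @param fs sample rate (Hz).
#' @param window `"hann"` or `"rect"` taper per window.
#' @return a `bispectrum`: list with `f1`, `f2`, `fsum` (= f1 + f2),
#'   `magnitude`, `n_windows`, `fs`, `n`.
#' @export
compute_bispectrum <- function(subs, fs = 250, window = c("hann", "rect")) {
  window <- match.arg(window)
  xs <- lapply(subs, function(s) if (inherits(s, "sub_epoch")) s$eeg else as.numeric(s))
  n <- length(xs[[1]])
  stopifnot(all(vapply(xs, length, integer(1)) == n))
  w <- if (window == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1)) else rep(1, n)

  half <- floor(n / 2)                      # Nyquist index (bin = index * fs/n)
  k1 <- unlist(lapply(0:floor(half / 2), function(i) rep(i, half - 2 * i + 1)))
  k2 <- unlist(lapply(0:floor(half / 2), function(i) i:(half - i)))
  keep <- k1 <= k2 & (k1 + k2) <= half & k2 <= half
  k1 <- k1[keep]; k2 <- k2[keep]

  acc <- complex(length.out = length(k1))
  for (x in xs) {
    X <- stats::fft(x * w) / n
    acc <- acc + X[k1 + 1] * X[k2 + 1] * Conj(X[k1 + k2 + 1])
  }
  acc <- acc / length(xs)
  bis <- list(f1 = k1 * fs / n, f2 = k2 * fs / n, fsum = (k1 + k2) * fs / n,
              magnitude = Mod(acc), n_windows = length(xs), fs = fs, n = n)
  class(bis) <- "bispectrum"
  bis
}

#' Summed bispectral activity over a bifrequency-sum band
#'
#' Sums bispectral magnitudes over pairs with `low <= f1 + f2 <= high`
#' (inclusive), counting the principal domain `f1 <= f2` once.
#'
#' @param bis a `bispectrum`.
#' @param low,high band edges on f1 + f2 (Hz).
#' @return summed bispectral magnitude.
#' @export
band_bispectrum <- function(bis, low, high) {
  stopifnot(inherits(bis, "bispectrum"))
  sum(bis$magnitude[bis$fsum >= low & bis$fsum <= high])
}

#' SynchFastSlow from a bispectrum estimate
#'
#' `log(B[0.5, 47] / B[40, 47])` on the bifrequency-sum bands: the summed
#' bispectral activity over the whole 0.5-47 Hz band relative to the fast
#' 40-47 Hz band, following the bifrequency-sum convention of the
#' bispectral-index literature.
#'
#' @param bis a `bispectrum`.
#' @param log_base base of the logarithm.
#' @return SynchFastSlow value; `NA` with a warning when the denominator
#'   band is zero.
#' @export
compute_synch_fast_slow <- function(bis, log_base = exp(1)) {
  num <- band_bispectrum(bis, 0.5, 47)
  den <- band_bispectrum(bis, 40, 47)
  if (den <= 0 || num <= 0) {
    warning("undefined feature synch_fast_slow: zero bispectral band")
    return(NA_real_)
  }
  log(num / den, base = log_base)
}
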