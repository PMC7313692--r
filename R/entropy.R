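#' Probability / energy model of a sub-epoch
#'
#' Builds the distribution `p(x_i)` that the two entropy parameters are
#' evaluated on. Four sources are available:
#' \describe{
#'   \item{`"energy"` (default)}{`p_i = x_i^2`, the per-sample energy in
#'     uV^2, *not* normalized (zero samples excluded). This is the
#'     wavelet-entropy convention of common EEG toolboxes; it makes both
#'     entropies scale with log-amplitude, so they rise as the EEG
#'     recovers with carotid flow.}
#'   \item{`"sample_energy"`}{`p_i = x_i^2 / sum(x^2)` (normalized,
#'     scale-invariant).}
#'   \item{`"spectral_bins"`}{normalized one-sided power over the 94
#'     0.5-47 Hz bins (0.5 Hz resolution), a pure spectral-shape
#'     measure.}
#'   \item{`"amplitude_histogram"`}{normalized counts over `n_bins`
#'     equal-width amplitude bins.}
#' }
#'
#' @param x numeric samples (a sub-epoch) or a `sub_epoch`.
#' @param source one of the four sources above.
#' @param n_bins histogram bins for `"amplitude_histogram"`.
#' @param log_base log base recorded for downstream entropies.
#' @param fs sample rate, used by `"spectral_bins"`.
#' @return a `probability_model`: list with `p`, `source`, `log_base`,
#'   `normalized`.
#' @export
probability_model <- function(x,
                              source = c("energy", "sample_energy",
                                         "spectral_bins", "amplitude_histogram"),
                              n_bins = 32, log_base = exp(1), fs = 250) {
  source <- match.arg(source)
  if (inherits(x, "sub_epoch")) x <- x$eeg
  p <- switch(source,
    energy = x^2,
    sample_energy = {
      e <- x^2
      if (sum(e) <= 0) stop("probability model has empty support (all-zero signal)")
      e / sum(e)
    },
    spectral_bins = {
      sp <- compute_spectrum(x, fs = fs)
      sel <- sp$frequencies >= 0.5 & sp$frequencies <= 47
      pw <- sp$power[sel]
      if (sum(pw) <= 0) stop("probability model has empty support (no band power)")
      pw / sum(pw)
    },
    amplitude_histogram = {
      h <- graphics::hist(x, breaks = seq(min(x) - 1e-12, max(x) + 1e-12,
                                          length.out = n_bins + 1), plot = FALSE)
      h$counts / length(x)
    }
  )
  pm <- list(p = p, source = source, log_base = log_base,
             normalized = source != "energy")
  class(pm) <- "probability_model"
  pm
}

.pm_p <- function(pm) {
  if (inherits(pm, "probability_model")) {
    if (pm$normalized && abs(sum(pm$p) - 1) > 1e-8)
      stop("probability model does not sum to 1")
    pm$p
  } else {
    as.numeric(pm)
  }
}

.pm_base <- function(pm, log_base) {
  if (inherits(pm, "probability_model")) pm$log_base else log_base
}

#' Log energy entropy
#'
#' `sum over bins with p > 0 of log(p_i)^2`. Zero-probability bins are
#' excluded from the sum; an empty support is an error.
#'
#' @param pm a `probability_model` or a numeric probability vector.
#' @param log_base log base when `pm` is a plain vector.
#' @return log energy entropy (dimensionless).
#' @export
compute_log_energy_entropy <- function(pm, log_base = exp(1)) {
  p <- .pm_p(pm)
  base <- .pm_base(pm, log_base)
  if (any(p < 0)) stop("probabilities must be nonnegative")
  p <- p[p > 0]
  if (length(p) == 0) stop("empty support: no bins with p > 0")
  sum(log(p, base = base)^2)
}

#' Renyi entropy of order alpha
#'
#' `(1 / (1 - alpha)) * log(sum(p_i^alpha))` for `alpha >= 0`,
#' `alpha != 1`. The order used throughout the analysis is 0.5.
#'
#' @param pm a `probability_model` or a numeric probability vector.
#' @param alpha entropy order (>= 0, != 1).
#' @param log_base log base when `pm` is a plain vector.
#' @return Renyi entropy (nats for base e).
#' @export
compute_renyi_entropy <- function(pm, alpha = 0.5, log_base = exp(1)) {
  if (alpha == 1)
    stop("alpha = 1 is the Shannon limit; use -sum(p * log(p)) instead")
  if (alpha < 0) stop("alpha must be >= 0")
  p <- .pm_p(pm)
  base <- .pm_base(pm, log_base)
  if (any(p < 0)) stop("probabilities must be nonnegative")
  p <- p[p > 0]
  if (length(p) == 0) stop("empty support: no bins with p > 0")
  log(sum(p^alpha), base = base) / (1 - alpha)
}
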