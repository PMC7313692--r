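#' Feature-extraction configuration
#'
#' Collects every estimator choice behind the eleven EEG parameters.
#'
#' @param probability_source source of the entropy probability model;
#'   see [probability_model()].
#' @param log_base base of every logarithm (ratio features, entropies,
#'   SynchFastSlow).
#' @param renyi_alpha Renyi order (0.5 in this analysis).
#' @param window spectral taper, `"hann"` or `"rect"`.
#' @param filter apply the 0.5-47 Hz zero-phase bandpass to the epoch
#'   before segmentation.
#' @param low_hz,high_hz analysis band edges (Hz).
#' @param fs analysis sample rate (Hz).
#' @param hist_bins amplitude-histogram bins (only used for that source).
#' @return a `feature_config` list.
#' @export
feature_config <- function(probability_source = "energy",
                           log_base = exp(1),
                           renyi_alpha = 0.5,
                           window = "hann",
                           filter = TRUE,
                           low_hz = 0.5, high_hz = 47,
                           fs = 250,
                           hist_bins = 32) {
  cfg <- list(probability_source = probability_source, log_base = log_base,
              renyi_alpha = renyi_alpha, window = window, filter = filter,
              low_hz = low_hz, high_hz = high_hz, fs = fs,
              hist_bins = hist_bins)
  class(cfg) <- "feature_config"
  cfg
}

#' Peak absolute amplitude of a sub-epoch
#'
#' Maximal absolute amplitude over the samples, in uV (a signal ranging
#' from -12 to +7 uV has magnitude 12).
#'
#' @param x numeric samples or a `sub_epoch`.
#' @return peak |amplitude| in uV.
#' @export
compute_magnitude <- function(x) {
  if (inherits(x, "sub_epoch")) x <- x$eeg
  if (length(x) == 0) stop("empty signal")
  max(abs(x))
}

#' Names of the eleven EEG parameters
#' @return character vector in canonical order.
#' @export
feature_names <- function() {
  c("magnitude", "synch_fast_slow", "beta_r", "delta_r",
    "alpha_pr", "beta_pr", "delta_pr", "theta_pr", "bg_alpha_plus",
    "log_energy_entropy", "renyi_entropy")
}

#' Compute the eleven-parameter feature vector of one epoch
#'
#' The epoch is bandpass filtered (once, at epoch level), trimmed to its
#' final 3 s and segmented into the three overlapping 2-s sub-epochs.
#' Each scalar parameter is computed per sub-epoch and arithmetically
#' averaged; SynchFastSlow is computed once from the bispectrum averaged
#' over the three windows. Undefined sub-epoch values (degenerate
#' denominators) propagate to an undefined (`NA`) epoch value.
#'
#' @param epoch an `eeg_epoch` or numeric vector (>= 750 samples at
#'   250 Hz).
#' @param config a [feature_config()].
#' @return named numeric vector of the eleven parameters (see
#'   [feature_names()]).
#' @export
compute_feature_vector <- function(epoch, config = feature_config()) {
  x <- if (inherits(epoch, "eeg_epoch")) epoch$eeg else as.numeric(epoch)
  if (config$filter)
    x <- bandpass(x, config$low_hz, config$high_hz, fs = config$fs)
  subs <- make_subepochs(x, fs = config$fs)

  per_sub <- lapply(subs, function(se) {
    sp <- compute_spectrum(se$eeg, fs = config$fs, window = config$window)
    ratios <- compute_power_ratios(sp, log_base = config$log_base)
    pm <- probability_model(se$eeg, source = config$probability_source,
                            n_bins = config$hist_bins,
                            log_base = config$log_base, fs = config$fs)
    c(magnitude = compute_magnitude(se$eeg),
      unlist(ratios),
      log_energy_entropy = compute_log_energy_entropy(pm),
      renyi_entropy = compute_renyi_entropy(pm, alpha = config$renyi_alpha))
  })
  avg <- Reduce(`+`, per_sub) / length(per_sub)   # NA propagates

  bis <- compute_bispectrum(subs, fs = config$fs, window = config$window)
  sfs <- compute_synch_fast_slow(bis, log_base = config$log_base)

  out <- c(avg["magnitude"], synch_fast_slow = sfs,
           avg[c("beta_r", "delta_r", "alpha_pr", "beta_pr", "delta_pr",
                 "theta_pr", "bg_alpha_plus", "log_energy_entropy",
                 "renyi_entropy")])
  names(out) <- feature_names()
  out
}

#' Feature table for a list of epochs
#'
#' One row per epoch: subject, session, epoch time, and the eleven
#' parameters.
#'
#' @param epochs list of `eeg_epoch` objects.
#' @param config a [feature_config()].
#' @return data.frame with columns `subject`, `session`, `epoch_time_s`
#'   and the eleven features.
#' @export
feature_table <- function(epochs, config = feature_config()) {
  if (length(epochs) == 0)
    return(data.frame(subject = character(0), session = character(0),
                      epoch_time_s = numeric(0)))
  rows <- lapply(epochs, function(ep) {
    fv <- compute_feature_vector(ep, config)
    cbind(data.frame(subject = ep$subject %||% NA_character_,
                     session = ep$session %||% NA_character_,
                     epoch_time_s = ep$linked_event %||% NA_real_),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}
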