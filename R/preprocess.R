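#' Zero-phase 0.5-47 Hz analysis bandpass
#'
#' Digital realization of the analysis band: a 2nd-order Butterworth
#' high-pass at `low_hz` cascaded with a 6th-order Butterworth low-pass
#' at `high_hz`, each applied forward-backward (`signal::filtfilt`) so
#' epoch timing is preserved. The cascade attenuates by more than 20 dB
#' at 0.1 Hz and at 60 Hz while keeping the 1-40 Hz passband within 1 dB.
#'
#' @param x numeric samples.
#' @param low_hz high-pass edge (Hz).
#' @param high_hz low-pass edge (Hz).
#' @param fs sample rate (Hz); the analysis rate is 250 Hz.
#' @param hp_order,lp_order Butterworth orders of the two stages.
#' @return filtered samples, same length as `x`.
#' @export
bandpass <- function(x, low_hz = 0.5, high_hz = 47, fs = 250,
                     hp_order = 2, lp_order = 6) {
  order_total <- 2 * (hp_order + lp_order)   # forward-backward doubles order
  if (length(x) < 3 * order_total)
    stop("input shorter than 3x the filter order (", 3 * order_total,
         " samples needed)")
  nyq <- fs / 2
  if (high_hz >= nyq) stop("high_hz must be below the Nyquist frequency")
  key <- paste0("bp_", fs, "_", low_hz, "_", high_hz, "_", hp_order, "_", lp_order)
  flt <- .cpreeg_cache[[key]]
  if (is.null(flt)) {
    flt <- list(hp = signal::butter(hp_order, low_hz / nyq, type = "high"),
                lp = signal::butter(lp_order, high_hz / nyq, type = "low"))
    .cpreeg_cache[[key]] <- flt
  }
  signal::filtfilt(flt$lp, signal::filtfilt(flt$hp, x))
}

#' Segment an epoch into three overlapping 2-s sub-epochs
#'
#' A 3-s (750-sample at 250 Hz) epoch is split into three 2-s sub-epochs
#' with 1.5-s overlaps, at offsets 0, 0.5 and 1.0 s (0-2 s, 0.5-2.5 s,
#' 1-3 s). Epochs longer than 3 s are trimmed to their final 3 s — the
#' samples nearest the defibrillation. Shorter epochs are an error.
#'
#' @param epoch an `eeg_epoch` or a numeric vector of samples.
#' @param fs sample rate (Hz).
#' @return list of three `sub_epoch` objects, each `list(eeg, offset_s,
#'   duration_s)` with exactly `2 * fs` samples.
#' @export
make_subepochs <- function(epoch, fs = 250) {
  x <- if (inherits(epoch, "eeg_epoch")) epoch$eeg else as.numeric(epoch)
  need <- round(3 * fs)
  if (length(x) < need)
    stop("epoch has ", length(x), " samples; at least ", need, " required (3 s)")
  x <- x[(length(x) - need + 1):length(x)]   # keep the samples nearest the shock
  len <- round(2 * fs)
  offsets <- c(0, 0.5, 1.0)
  lapply(offsets, function(off) {
    i0 <- round(off * fs) + 1
    se <- list(eeg = x[i0:(i0 + len - 1)], offset_s = off, duration_s = 2.0)
    class(se) <- "sub_epoch"
    se
  })
}
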