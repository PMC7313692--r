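#' Extract pre-defibrillation EEG epochs
#'
#' Selects, for every defibrillation event, the `window_s` seconds of EEG
#' immediately preceding the event (the hands-off pause right before the
#' shock). Epochs with insufficient history are dropped with a warning.
#' The session label (BLS-k / ACLS-k) is taken from the nearest preceding
#' session-start event.
#'
#' @param rec a `recording` with an `eeg` channel and defibrillation
#'   events.
#' @param window_s epoch duration (s), nominally 3.
#' @param event_label label of the defibrillation events.
#' @return list of `eeg_epoch` objects: `eeg` samples (uV),
#'   `start_time_s`, `duration_s`, `linked_event` (event time),
#'   `subject`, `session`. Empty list when no defibrillation events.
#' @export
extract_preshock_epochs <- function(rec, window_s = 3.0, event_label = "defib") {
  stopifnot(inherits(rec, "recording"))
  ch <- rec$channels$eeg
  if (is.null(ch)) stop("missing channel: eeg")
  fs <- ch$fs
  ev <- rec$events
  shocks <- ev$time_s[ev$label == event_label]
  sess_ev <- ev[grepl("^(bls|acls)_\\d+_start$", ev$label), , drop = FALSE]
  session_of <- function(t) {
    prior <- sess_ev[sess_ev$time_s < t, , drop = FALSE]
    if (nrow(prior) == 0) return(NA_character_)
    lab <- prior$label[nrow(prior)]
    m <- regmatches(lab, regexec("^(bls|acls)_(\\d+)_start$", lab))[[1]]
    paste0(toupper(m[2]), "-", m[3])
  }
  n_samp <- round(window_s * fs)
  epochs <- list()
  for (t in shocks) {
    end <- floor(t * fs)            # last sample strictly before the shock
    start <- end - n_samp + 1
    if (start < 1 || end > length(ch$data)) {
      warning(sprintf("dropping epoch before defibrillation at %.1f s: fewer than %d samples available",
                      t, n_samp))
      next
    }
    ep <- list(eeg = ch$data[start:end],
               start_time_s = (start - 1) / fs,
               duration_s = n_samp / fs,
               linked_event = t,
               subject = rec$meta$subject_id %||% NA_character_,
               session = session_of(t))
    class(ep) <- "eeg_epoch"
    epochs[[length(epochs) + 1]] <- ep
  }
  epochs
}

#' @export
print.eeg_epoch <- function(x, ...) {
  cat(sprintf("<eeg_epoch %s %s: %.2f s at t=%.1f s before shock at %.1f s>\n",
              x$subject, x$session, x$duration_s, x$start_time_s, x$linked_event))
  invisible(x)
}

#' Mean hemodynamic value over an epoch window
#'
#' Averages the named channel over the epoch's time window
#' `[start_time_s, start_time_s + duration_s)`. Partial overlap is
#' averaged over the overlapping part with a warning; no overlap is an
#' error.
#'
#' @param rec a `recording`.
#' @param epoch an `eeg_epoch`.
#' @param channel channel name, e.g. `"cbf"`.
#' @return mean channel value over the window.
#' @export
epoch_hemodynamic_value <- function(rec, epoch, channel = "cbf") {
  stopifnot(inherits(rec, "recording"), inherits(epoch, "eeg_epoch"))
  ch <- rec$channels[[channel]]
  if (is.null(ch)) stop("missing channel: ", channel)
  fs <- ch$fs
  i0 <- floor(epoch$start_time_s * fs) + 1
  i1 <- ceiling((epoch$start_time_s + epoch$duration_s) * fs)
  lo <- max(i0, 1); hi <- min(i1, length(ch$data))
  if (lo > hi) stop("channel '", channel, "' does not overlap the epoch window")
  if (lo > i0 || hi < i1)
    warning("partial overlap: averaging channel '", channel,
            "' over the overlapping part only")
  mean(ch$data[lo:hi])
}
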