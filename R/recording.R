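#' Multichannel recording container
#'
#' A `recording` holds named sampled channels (each with its own sample
#' rate and unit), an ordered event list, and subject metadata. All times
#' are seconds from the recording origin.
#'
#' @param channels named list; each element is `list(data, fs, unit)`.
#' @param events data.frame with columns `label`, `time_s`, strictly
#'   increasing in time.
#' @param meta list of metadata (subject id, source files, ...).
#' @return an object of class `recording`.
#' @export
new_recording <- function(channels, events, meta = list()) {
  stopifnot(is.list(channels), length(channels) >= 1, !is.null(names(channels)))
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!all(c("data", "fs") %in% names(ch)))
      stop("channel '", nm, "' must have elements data and fs")
    if (ch$fs <= 0) stop("channel '", nm, "' has non-positive sample rate")
  }
  events <- as.data.frame(events)
  if (!all(c("label", "time_s") %in% names(events)))
    stop("events must have columns label and time_s")
  if (is.unsorted(events$time_s, strictly = TRUE))
    stop("event times must be strictly increasing")
  rec <- list(channels = channels, events = events, meta = meta)
  class(rec) <- "recording"
  rec
}

#' @export
print.recording <- function(x, ...) {
  cat("<recording: ", paste(names(x$channels), collapse = ", "),
      "; ", nrow(x$events), " events>\n", sep = "")
  invisible(x)
}

#' Convert a simulated subject to a recording
#'
#' @param subject a `subject_record` from [simulate_subject()].
#' @return a [new_recording()] with channels `eeg` (uV), `cbf` (mL/min)
#'   and `map` (mmHg).
#' @export
as_recording <- function(subject) {
  stopifnot(inherits(subject, "subject_record"))
  new_recording(
    channels = list(
      eeg = list(data = subject$eeg, fs = subject$fs, unit = "uV"),
      cbf = list(data = subject$cbf, fs = subject$fs, unit = "mL/min"),
      map = list(data = subject$map_pressure, fs = subject$fs, unit = "mmHg")
    ),
    events = subject$events,
    meta = list(subject_id = subject$subject_id,
                true_recovery_per_epoch = subject$true_recovery_per_epoch,
                rosc = subject$rosc)
  )
}

#' Write a recording to CSV files
#'
#' Writes a data CSV (`time_s, eeg_uv, cbf_ml_min, map_mmhg`) and an
#' events CSV (`label, time_s`). All channels must share one sample rate.
#'
#' @param rec a `recording`.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix, default the subject id.
#' @return invisibly, named character vector of the two paths.
#' @export
write_recording_csv <- function(rec, dir, prefix = NULL) {
  stopifnot(inherits(rec, "recording"))
  if (is.null(prefix)) prefix <- rec$meta$subject_id %||% "recording"
  fss <- vapply(rec$channels, function(ch) ch$fs, numeric(1))
  if (length(unique(fss)) != 1L)
    stop("CSV writer requires all channels at one sample rate")
  fs <- fss[[1]]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- max(vapply(rec$channels, function(ch) length(ch$data), numeric(1)))
  df <- data.frame(time_s = (seq_len(n) - 1) / fs)
  pick <- function(nm) {
    ch <- rec$channels[[nm]]
    if (is.null(ch)) rep(NA_real_, n) else c(ch$data, rep(NA_real_, n - length(ch$data)))
  }
  df$eeg_uv <- pick("eeg")
  df$cbf_ml_min <- pick("cbf")
  df$map_mmhg <- pick("map")
  data_path <- file.path(dir, paste0(prefix, "_data.csv"))
  events_path <- file.path(dir, paste0(prefix, "_events.csv"))
  ## %.17g guarantees an exact text round trip for doubles
  dfc <- as.data.frame(lapply(df, function(col)
    if (is.double(col)) sprintf("%.17g", col) else col))
  names(dfc) <- names(df)
  utils::write.table(dfc, data_path, sep = ",", quote = FALSE,
                     row.names = FALSE)
  utils::write.csv(rec$events, events_path, row.names = FALSE)
  invisible(c(data = data_path, events = events_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a recording from CSV or EDF sources
#'
#' CSV mode expects the dialect written by [write_recording_csv()]:
#' a data file with columns `time_s`, `eeg_uv` and optionally
#' `cbf_ml_min`, `map_mmhg`, plus an events file with columns
#' `label`, `time_s`. EDF mode reads the EEG channel from an EDF file
#' (physical dimension honored, converted to uV) and, optionally,
#' hemodynamic channels from a companion data CSV.
#'
#' The EEG channel is resampled to `analysis_rate_hz` (polyphase
#' resampling, logged via `message()`) when the source rate differs.
#'
#' @param paths named list: CSV mode `list(data=, events=)`; EDF mode
#'   `list(edf=, events=, data=)` (`data` optional).
#' @param format `"csv"` or `"edf"`.
#' @param analysis_rate_hz EEG analysis rate (Hz).
#' @return a [new_recording()].
#' @export
read_recording <- function(paths, format = c("csv", "edf"),
                           analysis_rate_hz = 250) {
  format <- match.arg(format)
  for (p in unlist(paths)) if (!file.exists(p)) stop("file not found: ", p)
  ev <- utils::read.csv(paths$events, stringsAsFactors = FALSE)
  if (!all(c("label", "time_s") %in% names(ev)))
    stop("events file must have columns label and time_s")
  if (is.unsorted(ev$time_s, strictly = TRUE))
    stop("event times must be strictly increasing")

  channels <- list()
  if (format == "csv") {
    df <- utils::read.csv(paths$data)
    if (!"time_s" %in% names(df)) stop("missing channel: time_s")
    if (is.unsorted(df$time_s, strictly = TRUE))
      stop("non-monotone timestamps in data file")
    dt <- diff(df$time_s)
    fs <- 1 / stats::median(dt)
    if (max(abs(dt - 1 / fs)) > 0.1 / fs)
      stop("data file does not have a constant sample rate")
    if (!"eeg_uv" %in% names(df)) stop("missing channel: eeg_uv")
    eeg <- df$eeg_uv
    if (abs(fs - analysis_rate_hz) > 1e-6) {
      message(sprintf("resampling EEG from %.6g Hz to %g Hz", fs, analysis_rate_hz))
      eeg <- .resample_to(eeg, fs, analysis_rate_hz)
      channels$eeg <- list(data = eeg, fs = analysis_rate_hz, unit = "uV")
    } else {
      channels$eeg <- list(data = eeg, fs = fs, unit = "uV")
    }
    if ("cbf_ml_min" %in% names(df))
      channels$cbf <- list(data = df$cbf_ml_min, fs = fs, unit = "mL/min")
    if ("map_mmhg" %in% names(df))
      channels$map <- list(data = df$map_mmhg, fs = fs, unit = "mmHg")
  } else {
    edf <- read_edf(paths$edf)
    eeg <- edf$data
    fs <- edf$fs
    if (abs(fs - analysis_rate_hz) > 1e-6) {
      message(sprintf("resampling EEG from %.6g Hz to %g Hz", fs, analysis_rate_hz))
      eeg <- .resample_to(eeg, fs, analysis_rate_hz)
      fs <- analysis_rate_hz
    }
    channels$eeg <- list(data = eeg, fs = fs, unit = "uV")
    if (!is.null(paths$data)) {
      df <- utils::read.csv(paths$data)
      if (is.unsorted(df$time_s, strictly = TRUE))
        stop("non-monotone timestamps in data file")
      hfs <- 1 / stats::median(diff(df$time_s))
      if ("cbf_ml_min" %in% names(df))
        channels$cbf <- list(data = df$cbf_ml_min, fs = hfs, unit = "mL/min")
      if ("map_mmhg" %in% names(df))
        channels$map <- list(data = df$map_mmhg, fs = hfs, unit = "mmHg")
    }
  }
  new_recording(channels, ev, meta = list(source = unlist(paths)))
}

# polyphase rational resampling via signal::resample
.resample_to <- function(x, fs_in, fs_out) {
  frac <- .rat_approx(fs_out / fs_in)
  signal::resample(x, frac$p, frac$q)
}

.rat_approx <- function(ratio, max_den = 1000) {
  best <- c(1, 1); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    e <- abs(p / q - ratio)
    if (e < err) { err <- e; best <- c(p, q) }
    if (err < 1e-9) break
  }
  list(p = best[1], q = best[2])
}
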