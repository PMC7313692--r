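## Synthetic cardiac-arrest EEG + hemodynamics generator.
##
## EEG state model: two unit-RMS filtered-Gaussian components (low band
## <~7 Hz, high band 8-30 Hz) mixed according to spectral_curve(r), scaled
## to the RMS given by amp_curve(r) and softly saturated so the r = 0
## state stays inside the isoelectric +/-5 uV band.

.cpreeg_cache <- new.env(parent = emptyenv())

.shaping_filters <- function(fs) {
  key <- paste0("shape_", fs)
  if (!is.null(.cpreeg_cache[[key]])) return(.cpreeg_cache[[key]])
  nyq <- fs / 2
  lo <- signal::butter(2, c(0.5, 7) / nyq, type = "pass")
  hi <- signal::butter(2, c(8, 30) / nyq, type = "pass")
  gain <- function(flt) {
    h <- signal::filter(flt, c(1, numeric(4999)))
    sqrt(sum(h^2))
  }
  res <- list(lo = lo, hi = hi, g_lo = gain(lo), g_hi = gain(hi))
  .cpreeg_cache[[key]] <- res
  res
}

# r may be a scalar or a per-sample vector of length n
.eeg_state_noise <- function(n, r, coupling, fs) {
  flt <- .shaping_filters(fs)
  pad <- 2L * fs                       # discard the filter start-up transient
  w_lo <- stats::rnorm(n + pad)
  w_hi <- stats::rnorm(n + pad)
  n_lo <- signal::filter(flt$lo, w_lo)[-seq_len(pad)] / flt$g_lo
  n_hi <- signal::filter(flt$hi, w_hi)[-seq_len(pad)] / flt$g_hi
  if (length(r) == 1L) r <- rep(r, n)
  r <- pmin(pmax(r, 0), 1)
  s <- coupling$spectral_curve(r)
  sigma <- coupling$amp_isoelectric_uv +
    (coupling$amp_baseline_uv - coupling$amp_isoelectric_uv) * coupling$amp_curve(r)
  x <- sigma * (sqrt(1 - s) * n_lo + sqrt(s) * n_hi)
  clip <- coupling$clip_isoelectric_uv + coupling$clip_slope_uv * r
  clip * tanh(x / clip)
}

#' Generate stationary 3-s EEG epochs at a fixed recovery rate
#'
#' Draws `n_epochs` contiguous, non-overlapping 3-s epochs from the
#' stationary EEG state model at recovery rate `r`. This is the state
#' model used inside [simulate_subject()], exposed directly so the
#' amplitude and spectral anchors of each state can be checked in bulk.
#'
#' @param n_epochs number of epochs.
#' @param r recovery rate in \[0, 1\]; `r = 0` is the isoelectric state,
#'   `r = 1` the pre-VF baseline state.
#' @param coupling a [coupling_model()].
#' @param sample_rate_hz sampling rate (Hz).
#' @param epoch_s epoch duration (s).
#' @param seed integer seed.
#' @return numeric matrix, `n_epochs` rows of `epoch_s * sample_rate_hz`
#'   samples (uV).
#' @export
simulate_state_epochs <- function(n_epochs, r, coupling = coupling_model(),
                                  sample_rate_hz = 250, epoch_s = 3,
                                  seed = 1L) {
  validate_coupling_model(coupling)
  set.seed(as.integer(seed))
  len <- round(epoch_s * sample_rate_hz)
  x <- .eeg_state_noise(n_epochs * len, r, coupling, sample_rate_hz)
  matrix(x, nrow = n_epochs, ncol = len, byrow = TRUE)
}

#' Default per-session recovery-rate distribution
#'
#' Beta(1.5, 3): right-skewed over \[0, 1\] with median close to 0.30,
#' emulating a cohort whose median CBF recovery sits near 30% of the
#' pre-VF baseline.
#'
#' @param n number of draws.
#' @return numeric vector of recovery rates in \[0, 1\].
#' @export
default_r_distribution <- function(n) stats::rbeta(n, 1.5, 3)

.subseed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

# phase table row helper
.phase <- function(name, dur_s, type, r0, r1 = r0) {
  data.frame(name = name, dur_s = dur_s, type = type,
             r0 = r0, r1 = r1, stringsAsFactors = FALSE)
}

#' Simulate one subject of the cardiac-arrest scenario
#'
#' Generates a full coupled EEG + hemodynamics recording following the
#' scenario timeline: pre-VF baseline, VF onset, untreated VF with
#' exponential EEG decay to the isoelectric state, `n_bls_cycles` BLS
#' cycles, then ACLS cycles until ROSC or `max_acls_cycles`, each cycle
#' ending in a hands-off pause whose final seconds precede a
#' defibrillation attempt. Each compression session has one recovery rate
#' r (piecewise constant); the carotid-flow channel is approximately
#' `r * baseline` during that session and the EEG follows the coupling
#' model at the same r.
#'
#' @param config a [scenario_config()].
#' @param coupling a [coupling_model()].
#' @param r_sessions optional vector of per-session recovery rates; drawn
#'   from `r_distribution` when `NULL`. Recycled/truncated to the number
#'   of sessions actually played out.
#' @param r_distribution function of `n` returning recovery-rate draws.
#' @param subject_id identifier stored in the record.
#' @return a `subject_record`: list with elements `eeg`, `cbf`,
#'   `map_pressure` (numeric series at `sample_rate_hz`), `fs`, `events`
#'   (data.frame `label`, `time_s`), `true_recovery_per_epoch`, `rosc`,
#'   `subject_id`, and the generating `config`/`coupling`.
#' @export
simulate_subject <- function(config = scenario_config(),
                             coupling = coupling_model(),
                             r_sessions = NULL,
                             r_distribution = default_r_distribution,
                             subject_id = "S1") {
  validate_scenario_config(config)
  validate_coupling_model(coupling)
  fs <- config$sample_rate_hz
  max_sessions <- config$n_bls_cycles + config$max_acls_cycles

  set.seed(.subseed(config$seed, 0))
  if (is.null(r_sessions)) r_sessions <- r_distribution(max_sessions)
  if (length(r_sessions) < max_sessions)
    r_sessions <- rep_len(r_sessions, max_sessions)
  r_sessions <- pmin(pmax(as.numeric(r_sessions), 0), 1)

  ## --- lay out the timeline ------------------------------------------------
  phases <- .phase("baseline", config$baseline_s, "baseline", 1)
  events <- data.frame(label = character(0), time_s = numeric(0))
  t_now <- config$baseline_s
  add_event <- function(label, time_s) {
    events <<- rbind(events, data.frame(label = label, time_s = time_s))
  }
  add_event("vf_onset", t_now)
  phases <- rbind(phases, .phase("untreated_vf", config$untreated_vf_s, "vf", 1, 0))
  t_now <- t_now + config$untreated_vf_s

  rosc <- FALSE
  epoch_r <- numeric(0)
  n_session <- 0L
  rosc_wanted <- function(k, r) {
    if (isTRUE(config$rosc_outcome)) return(k >= config$n_bls_cycles)
    if (isFALSE(config$rosc_outcome)) return(FALSE)
    k >= config$n_bls_cycles && r >= config$rosc_threshold
  }
  for (k in seq_len(max_sessions)) {
    n_session <- k
    r_k <- r_sessions[k]
    lab <- if (k <= config$n_bls_cycles) {
      sprintf("bls_%d_start", k)
    } else {
      sprintf("acls_%d_start", k - config$n_bls_cycles)
    }
    add_event(lab, t_now)
    sess <- if (k <= config$n_bls_cycles) sprintf("BLS-%d", k)
            else sprintf("ACLS-%d", k - config$n_bls_cycles)
    phases <- rbind(phases,
                    .phase(paste0(sess, "_comp"), config$compression_s, "compression", r_k),
                    .phase(paste0(sess, "_pause"), config$pause_s, "pause", r_k))
    t_now <- t_now + config$compression_s + config$pause_s
    add_event("defib", t_now)
    epoch_r <- c(epoch_r, r_k)
    if (rosc_wanted(k, r_k)) { rosc <- TRUE; break }
    if (k < max_sessions) {             # shock delivery before the next cycle
      phases <- rbind(phases, .phase(paste0(sess, "_shock"), 1, "pause", r_k))
      t_now <- t_now + 1
    }
  }
  r_last <- r_sessions[n_session]
  if (rosc) {
    add_event("rosc", t_now + 1)
    ramp_s <- min(60, config$monitoring_s)
    phases <- rbind(phases,
                    .phase("rosc_ramp", ramp_s, "monitoring", r_last, 1),
                    .phase("monitoring", config$monitoring_s - ramp_s, "monitoring", 1))
    t_now <- t_now + config$monitoring_s
  } else {
    add_event("termination", t_now + 1)
    phases <- rbind(phases, .phase("post", 2, "vf", 0))
    t_now <- t_now + 2
  }

  ## --- per-sample envelopes ------------------------------------------------
  phases$n <- round(phases$dur_s * fs)
  phases <- phases[phases$n > 0, , drop = FALSE]
  n_total <- sum(phases$n)
  r_env <- numeric(n_total)
  type <- character(nrow(phases))
  idx0 <- cumsum(c(0, phases$n))
  for (i in seq_len(nrow(phases))) {
    ii <- (idx0[i] + 1):(idx0[i] + phases$n[i])
    if (phases$type[i] == "vf") {
      # exponential decay towards the isoelectric state, delayed onset
      tt <- (seq_len(phases$n[i]) - 1) / fs
      r_env[ii] <- phases$r0[i] *
        exp(-pmax(tt - config$vf_decay_delay_s, 0) / config$vf_decay_tau_s)
      if (phases$name[i] == "post") r_env[ii] <- 0
    } else if (phases$r0[i] != phases$r1[i]) {
      r_env[ii] <- seq(phases$r0[i], phases$r1[i], length.out = phases$n[i])
    } else {
      r_env[ii] <- phases$r0[i]
    }
    type[i] <- phases$type[i]
  }
  phase_of_sample <- rep(phases$type, phases$n)

  set.seed(.subseed(config$seed, 101))
  eeg <- .eeg_state_noise(n_total, r_env, coupling, fs)

  ## hemodynamics: flow follows r during CPR, ~0 during VF, baseline after ROSC
  tvec <- (seq_len(n_total) - 1) / fs
  comp_hz <- 100 / 60                       # 100 compressions per minute
  cbf_b <- config$cbf_baseline_ml_min
  map_b <- config$map_baseline_mmhg
  level <- r_env
  level[phase_of_sample == "vf"] <- 0
  pulsatile <- numeric(n_total)
  is_comp <- phase_of_sample == "compression"
  is_spont <- phase_of_sample %in% c("baseline", "monitoring")
  pulsatile[is_comp] <- 0.15 * sin(2 * pi * comp_hz * tvec[is_comp])
  pulsatile[is_spont] <- 0.05 * sin(2 * pi * 1.6 * tvec[is_spont])
  level[is_spont] <- pmax(level[is_spont], r_env[is_spont])

  set.seed(.subseed(config$seed, 202))
  cbf <- pmax(cbf_b * level * (1 + pulsatile) + stats::rnorm(n_total, sd = 0.01 * cbf_b), 0)
  set.seed(.subseed(config$seed, 303))
  map_floor <- ifelse(phase_of_sample == "vf", map_b * config$map_residual_frac, 0)
  map <- pmax(map_b * level * (1 + pulsatile), map_floor) +
    stats::rnorm(n_total, sd = 2)

  rec <- list(
    eeg = eeg, cbf = cbf, map_pressure = map,
    fs = fs,
    events = events,
    true_recovery_per_epoch = epoch_r,
    rosc = rosc,
    n_sessions = n_session,
    subject_id = subject_id,
    config = config,
    coupling = coupling
  )
  class(rec) <- "subject_record"
  rec
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject_record %s: %.0f s at %g Hz, %d sessions, %s>\n",
              x$subject_id, length(x$eeg) / x$fs, x$fs, x$n_sessions,
              if (x$rosc) "ROSC" else "non-ROSC"))
  invisible(x)
}

#' Simulate a cohort of subjects
#'
#' Independent subjects whose per-session recovery rates are drawn from
#' `r_distribution`. The empirical median of all drawn rates is attached
#' as attribute `median_r` (used downstream for median-split checks).
#'
#' @param n_subjects number of subjects (>= 1).
#' @param config a [scenario_config()]; subject k uses seed
#'   `config$seed + 1000 * k`.
#' @param coupling a [coupling_model()].
#' @param r_distribution function of `n` returning recovery-rate draws.
#' @return list of `subject_record`s with attribute `median_r`.
#' @export
simulate_cohort <- function(n_subjects, config = scenario_config(),
                            coupling = coupling_model(),
                            r_distribution = default_r_distribution) {
  stopifnot(n_subjects >= 1)
  probe <- r_distribution(1000L)
  if (stats::sd(probe) < 1e-12)
    message("simulate_cohort: degenerate recovery-rate distribution ",
            "(all mass at ", signif(probe[1], 3), ")")
  records <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cfg_i <- config
    cfg_i$seed <- .subseed(config$seed, 1000 * i)
    records[[i]] <- simulate_subject(cfg_i, coupling,
                                     r_distribution = r_distribution,
                                     subject_id = sprintf("S%d", i))
  }
  rs <- unlist(lapply(records, function(r) r$true_recovery_per_epoch))
  attr(records, "median_r") <- stats::median(rs)
  records
}
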