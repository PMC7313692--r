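#' Scenario configuration for the cardiac-arrest CPR timeline
#'
#' Describes the witnessed out-of-hospital arrest scenario the simulator
#' follows: a pre-VF baseline, an untreated ventricular-fibrillation (VF)
#' interval, a fixed number of bystander basic-life-support (BLS)
#' compression cycles, up to `max_acls_cycles` advanced-life-support (ACLS)
#' cycles each ending in a defibrillation attempt, and a post-ROSC
#' monitoring period.
#'
#' @param sample_rate_hz sampling rate of every generated channel (Hz).
#'   Must exceed twice the 47 Hz analysis band edge.
#' @param baseline_s duration of the pre-VF baseline recording (s).
#' @param untreated_vf_s untreated VF interval before CPR starts (s).
#' @param n_bls_cycles number of BLS compression cycles (>= 1).
#' @param max_acls_cycles maximum number of ACLS cycles before the
#'   attempt is abandoned.
#' @param compression_s duration of the compression part of each cycle (s).
#' @param pause_s duration of the hands-off pause that ends each cycle;
#'   the final ~3 s of this pause is the analysis epoch (s).
#' @param monitoring_s post-ROSC monitoring duration (s); sustained ROSC
#'   requires 20 min of spontaneous circulation, hence the 1200 s default.
#' @param rosc_outcome `TRUE` (ROSC at the first defibrillation), `FALSE`
#'   (never), or `"auto"`: ROSC at the first defibrillation whose session
#'   recovery rate reaches `rosc_threshold`.
#' @param rosc_threshold recovery-rate threshold used when
#'   `rosc_outcome = "auto"`.
#' @param vf_decay_delay_s seconds after VF onset before the EEG amplitude
#'   starts to fall (observed onset of decay at 10-15 s).
#' @param vf_decay_tau_s exponential time constant of the amplitude decay,
#'   placed so the EEG is isoelectric well before the end of the 60 s
#'   untreated interval.
#' @param cbf_baseline_ml_min pre-VF carotid blood flow (mL/min).
#' @param map_baseline_mmhg pre-VF mean arterial pressure (mmHg).
#' @param map_residual_frac fraction of baseline MAP remaining as residual
#'   vessel pressure during untreated VF (about 20% in the model).
#' @param seed integer seed governing the whole subject.
#'
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(sample_rate_hz = 250,
                            baseline_s = 60,
                            untreated_vf_s = 60,
                            n_bls_cycles = 4,
                            max_acls_cycles = 10,
                            compression_s = 115,
                            pause_s = 5,
                            monitoring_s = 1200,
                            rosc_outcome = "auto",
                            rosc_threshold = 0.5,
                            vf_decay_delay_s = 12,
                            vf_decay_tau_s = 10,
                            cbf_baseline_ml_min = 300,
                            map_baseline_mmhg = 90,
                            map_residual_frac = 0.2,
                            seed = 1L) {
  cfg <- list(
    sample_rate_hz = sample_rate_hz,
    baseline_s = baseline_s,
    untreated_vf_s = untreated_vf_s,
    n_bls_cycles = as.integer(n_bls_cycles),
    max_acls_cycles = as.integer(max_acls_cycles),
    compression_s = compression_s,
    pause_s = pause_s,
    monitoring_s = monitoring_s,
    rosc_outcome = rosc_outcome,
    rosc_threshold = rosc_threshold,
    vf_decay_delay_s = vf_decay_delay_s,
    vf_decay_tau_s = vf_decay_tau_s,
    cbf_baseline_ml_min = cbf_baseline_ml_min,
    map_baseline_mmhg = map_baseline_mmhg,
    map_residual_frac = map_residual_frac,
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  if (cfg$sample_rate_hz <= 2 * 47)
    stop("sample_rate_hz must exceed 94 Hz (twice the 47 Hz analysis band edge)")
  if (cfg$untreated_vf_s <= 0) stop("untreated_vf_s must be positive")
  if (cfg$n_bls_cycles < 1L) stop("n_bls_cycles must be >= 1")
  if (cfg$max_acls_cycles < 0L) stop("max_acls_cycles must be >= 0")
  if (cfg$pause_s < 3) stop("pause_s must allow a 3-s pre-shock epoch")
  if (!(isTRUE(cfg$rosc_outcome) || isFALSE(cfg$rosc_outcome) ||
        identical(cfg$rosc_outcome, "auto")))
    stop("rosc_outcome must be TRUE, FALSE or \"auto\"")
  invisible(cfg)
}

#' Coupling model between CBF recovery and the EEG state
#'
#' Maps a per-session recovery rate r in [0, 1] to the amplitude and
#' spectral content of the generated EEG. The EEG is filtered Gaussian
#' noise: two unit-variance shaped-noise components (a low band below
#' about 7 Hz and a high band at 8-30 Hz) are mixed so that
#' `spectral_curve(r)` is the fraction of power contributed above 8 Hz,
#' then scaled to the target RMS
#' `amp_isoelectric_uv + (amp_baseline_uv - amp_isoelectric_uv) * amp_curve(r)`
#' and passed through a soft saturation that bounds the isoelectric state
#' within the +/-5 uV band.
#'
#' @param amp_baseline_uv RMS amplitude of the r = 1 (pre-VF baseline)
#'   state, in uV. The default gives epoch peaks well above +/-20 uV.
#' @param amp_isoelectric_uv RMS amplitude of the r = 0 (isoelectric)
#'   state, in uV. Together with `clip_isoelectric_uv` this keeps peaks
#'   inside +/-5 uV.
#' @param amp_curve nondecreasing function from r in [0,1] to a
#'   normalized amplitude gain in [0,1]; `amp_curve(0) = 0` selects the
#'   isoelectric RMS, `amp_curve(1) = 1` the baseline RMS.
#' @param spectral_curve nondecreasing function from r to the fraction of
#'   signal power above 8 Hz.
#' @param clip_isoelectric_uv soft-saturation bound of the r = 0 state
#'   (uV); the bound relaxes linearly with r (`clip_slope_uv` per unit r)
#'   so that high-r signals are essentially unclipped.
#' @param clip_slope_uv increase of the saturation bound per unit r (uV).
#' @param noise_model free-text description of the stochastic family,
#'   recorded in run logs.
#'
#' @return an object of class `coupling_model`.
#' @export
coupling_model <- function(amp_baseline_uv = 18,
                           amp_isoelectric_uv = 1.3,
                           amp_curve = function(r) r,
                           spectral_curve = function(r) 0.15 + 0.25 * r,
                           clip_isoelectric_uv = 4.6,
                           clip_slope_uv = 85,
                           noise_model = "state-shaped filtered Gaussian noise") {
  cm <- list(
    amp_baseline_uv = amp_baseline_uv,
    amp_isoelectric_uv = amp_isoelectric_uv,
    amp_curve = amp_curve,
    spectral_curve = spectral_curve,
    clip_isoelectric_uv = clip_isoelectric_uv,
    clip_slope_uv = clip_slope_uv,
    noise_model = noise_model
  )
  class(cm) <- "coupling_model"
  validate_coupling_model(cm)
  cm
}

validate_coupling_model <- function(cm) {
  stopifnot(inherits(cm, "coupling_model"))
  r <- seq(0, 1, by = 0.05)
  a <- vapply(r, cm$amp_curve, numeric(1))
  s <- vapply(r, cm$spectral_curve, numeric(1))
  if (any(diff(a) < -1e-12))
    stop("coupling model invalid: amp_curve must be nondecreasing in r")
  if (any(diff(s) < -1e-12))
    stop("coupling model invalid: spectral_curve must be nondecreasing in r")
  if (any(s < 0) || any(s > 1))
    stop("coupling model invalid: spectral_curve must map into [0, 1]")
  if (cm$amp_isoelectric_uv <= 0 || cm$amp_baseline_uv <= cm$amp_isoelectric_uv)
    stop("coupling model invalid: need 0 < amp_isoelectric_uv < amp_baseline_uv")
  invisible(cm)
}
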