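---
title: "Quantitative EEG and carotid blood flow recovery during CPR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative EEG and carotid blood flow recovery during CPR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During cardiopulmonary resuscitation (CPR) after cardiac arrest, the
quality of cerebral perfusion determines neurological outcome, but
carotid blood flow (CBF) can only be measured invasively. Frontal
single-channel EEG is cheap and non-invasive, and cortical electrical
activity is tightly coupled to cerebral perfusion: untreated ventricular
fibrillation (VF) drives the EEG into an isoelectric state (within
±5 µV) within roughly a minute, while effective compressions restore
amplitude and higher-frequency content. `cpreeg` implements the full
chain needed to study that coupling on simulated data: a scenario
simulator, epoch extraction, an eleven-parameter quantitative-EEG
feature set, and the association statistics (correlation, quartile
ANOVA with Dunnett T3, ROC cut-offs).

## The scenario simulator

`simulate_subject()` plays out a witnessed out-of-hospital arrest
timeline: a pre-VF baseline (60 s by default), VF onset, 60 s of
untreated VF, four basic-life-support (BLS) compression cycles, then up
to ten advanced-life-support (ACLS) cycles. Every cycle ends in a
hands-off pause (5 s) whose final 3 s precede a defibrillation attempt;
return of spontaneous circulation (ROSC) leads to a 20-min monitoring
phase. Each compression session carries one recovery rate
$r \in [0, 1]$ (piecewise constant, matching the one-observation-per-
pause structure of the analysis), drawn from a Beta(1.5, 3)
distribution whose median is close to 0.30 — a cohort whose median CBF
recovery sits near 30% of baseline.

### The EEG state model

The EEG is *state-shaped filtered Gaussian noise*, not a physiological
model. Two unit-RMS components — a low band (≤ ~7 Hz) and a high band
(8–30 Hz), each white noise through a 2nd-order Butterworth bandpass —
are mixed so that `spectral_curve(r)` is the fraction of power above
8 Hz (default $0.15 + 0.25\,r$), then scaled to an RMS of
$\sigma(r) = \sigma_{\mathrm{iso}} + (\sigma_{\mathrm{base}} -
\sigma_{\mathrm{iso}})\,\mathrm{amp\_curve}(r)$ with
$\sigma_{\mathrm{iso}} = 1.3$ µV and $\sigma_{\mathrm{base}} = 18$ µV.
A soft saturation $c \tanh(x / c)$ with a state-dependent bound
$c(r) = 4.6 + 85\,r$ µV keeps the isoelectric state strictly inside the
±5 µV band (residual activity at zero flow is bounded, which a plain
Gaussian is not) while leaving high-amplitude states essentially
linear. The defaults were chosen once so that isoelectric epochs peak
near ±4 µV (below the ±5 µV isoelectric limit, above the ±3 µVp-p
device noise floor) and baseline epochs peak near ±50 µV, comfortably
beyond the ±20 µV irregular baseline morphology the coupling is
anchored to. During untreated VF the effective $r$ decays
exponentially (12 s onset delay, 10 s time constant), so amplitude
starts to fall at 10–15 s and the trace is isoelectric well before
compressions start.

Both coupling curves must be nondecreasing in $r$; `coupling_model()`
rejects anything else. One integer seed drives a whole subject, with
per-channel streams derived at fixed offsets (session rates, EEG, CBF,
arterial pressure) so partial reruns are reproducible.

The hemodynamics are deliberately minimal: CBF is
$r \times 300$ mL/min plus compression-rate (100/min) pulsatility and
1% noise during sessions, near zero during untreated VF, and ramps back
to baseline after ROSC; mean arterial pressure behaves analogously with
a 20% residual during VF. CBF is held at the session level through the
hands-off pause (flow decays slowly relative to a 5-s pause), so the
pre-shock window pairing below recovers the generated $r$.

### What the simulator does and does not emulate

It reproduces the *statistical structure* the analysis assumes:
amplitude and spectral content monotone in CBF recovery, an isoelectric
floor, session-level recovery rates, a realistic timeline with
extractable pre-shock pauses. It does **not** contain compression
artifacts, electrode noise transients, drug effects, burst–suppression
dynamics, or any cardiovascular physiology. Tests passing on this
generator therefore validate the *pipeline's math and calibration*, not
claims about real recordings; the coupling curves at intermediate flow
are simulator assumptions, since no quantitative spectral data exist at
intermediate CBF levels.

## Epochs and preprocessing

`extract_preshock_epochs()` takes, for every defibrillation event, the
3 s of EEG that end at the event (configurable window and tolerance —
"approximately 3 s" is deliberately loose; epochs with insufficient
history are dropped and counted). A defibrillation marker is emitted at
the end of *every* compression cycle's pause, BLS cycles included, so
that each cycle contributes one analyzable pause.

The analysis band is 0.5–47 Hz at 250 Hz. The digital realization is a
2nd-order Butterworth high-pass at 0.5 Hz cascaded with a 6th-order
low-pass at 47 Hz, each run forward–backward (zero phase, so epoch
timing is preserved). The measured response is flat within 1 dB over
1–40 Hz and more than 20 dB down at 0.1 Hz and 60 Hz. The filter is
applied once per 3-s epoch, *before* segmentation, to avoid tripling
edge transients; sub-epochs are bitwise slices of the filtered epoch.
Epochs longer than 3 s are trimmed to their final 3 s — the samples
nearest the shock. No artifact rejection is applied: the pauses are
analyzed precisely because compressions are suspended during them.

`make_subepochs()` yields the three 2-s sub-epochs with 1.5-s overlaps
(0–2, 0.5–2.5, 1–3 s; exactly 500 samples each). Scalar parameters are
computed per sub-epoch and arithmetically averaged — the same
sub-epoch-averaging scheme as bispectral-index processing — except
SynchFastSlow, which is computed once from the bispectrum averaged over
the three windows (only three windows exist per epoch; averaging the
complex triple products first is the lower-variance estimator).

## The eleven parameters

| Parameter | Definition |
|---|---|
| magnitude | max |x| over the sub-epoch (µV) |
| synch_fast_slow | log(B[0.5–47] / B[40–47]) on bifrequency sums |
| beta_r | log(P(30–47] / P(11–20]) |
| delta_r | log(P(8–20] / P(1–4]) |
| alpha_pr | P(8–13] / P[0.5–47] |
| beta_pr | P(13–30] / P[0.5–47] |
| delta_pr | P[0.5–4] / P[0.5–47] |
| theta_pr | P(4–8] / P[0.5–47] |
| bg_alpha_plus | P(8–47] / P[0.5–47] |
| log_energy_entropy | Σ (log p(x_i))² over p > 0 |
| renyi_entropy | (1/(1−α)) log Σ p(x_i)^α, α = 0.5 |

**Spectra.** Hann-windowed periodograms on the full 2-s window (0.5 Hz
bins), one-sided and normalized so Parseval holds for the windowed
signal. Band sums use the lower-edge-open rule (a bin at a shared edge
belongs to the lower band, with the 0.5 Hz floor included), which makes
`delta_pr + theta_pr + bg_alpha_plus = 1` an exact partition and gives
the flat-spectrum identity `delta_r = log 4` (24 bins over 6 bins).

**Bispectrum.** Direct FFT method: per window the triple product
$X(f_1) X(f_2) X^*(f_1 + f_2)$ over the principal domain
($f_1 \le f_2$, $f_1 + f_2 \le$ Nyquist), complex-averaged across the
three sub-epoch windows, then magnitudes. Band sums run over
$f_1 + f_2$ (inclusive), the bifrequency-sum convention of the
bispectral-index literature.

**Entropies and the probability model.** The distribution $p(x_i)$ is
configurable (`probability_model()`), because no unique convention
exists. The default source is `"energy"`: $p_i = x_i^2$ per sample in
µV², *unnormalized*, zeros excluded — the wavelet-entropy convention of
widely used EEG toolboxes. Under it the log energy entropy grows with
log-amplitude (values in the hundreds to thousands on 500-sample
windows) and the Rényi entropy of order 0.5 becomes
$2 \log \Sigma |x_i|$, so both indices *rise* as the EEG recovers with
carotid flow — the direction and magnitude range this feature set is
designed around. Three normalized, scale-invariant alternatives are
provided (`spectral_bins` over the 94 half-Hz bins, `sample_energy`,
`amplitude_histogram`); note that a normalized model turns both
entropies into pure shape measures, and the log energy entropy then
*falls* as the spectrum broadens — a sign flip worth being aware of
when comparing conventions. All logs are natural by default
(configurable to base 2); the Rényi order is 0.5.

Degenerate denominators (an all-zero band on a flat signal) yield `NA`
markers with a logged warning; `NA`s propagate to the epoch value and
are removed pairwise in the statistics, with counts reported.

## Recovery rates and statistics

Each epoch's CBF value is the mean over the *same* 3-s pre-shock window
as the EEG (the most defensible pairing absent a stated convention;
configurable), expressed as a percent of the pre-VF baseline (mean CBF
over the baseline phase with 5-s guard margins). Quartile groups are
1: < 25%, 2: 25–50%, 3: 50–75%, 4: > 75%, with boundary values assigned
upward (the printed brackets are ambiguous at the edges; the rule is
configurable). The median split is computed from the analyzed epochs —
the ~30% threshold is a property of the data, not a constant — with a
fixed-threshold override available.

*Pearson* correlations use the exact t transform (base R `cor.test`).
*ANOVA* is the classical between/within decomposition; a zero
within-group sum of squares is rejected as degenerate. *Dunnett T3*
is implemented from first principles: Welch statistics with
Welch–Satterthwaite degrees of freedom, referred to the studentized
maximum modulus distribution with $k$ = number of pairwise comparisons.
The SMM CDF has no closed form; it is evaluated by adaptive quadrature
of $(2\Phi(qu) - 1)^k$ against the $\chi_\nu/\sqrt{\nu}$ density
(accuracy well below 10⁻⁴; at $k = 1$ it reduces exactly to the Welch
t-test, which the tests verify). *ROC* curves are empirical threshold
sweeps; the trapezoid AUC equals the normalized Mann–Whitney U
(verified as an identity), the standard error is Hanley–McNeil, and the
optimal cut-off maximizes Youden's J, ties broken toward higher
specificity. Youden's J is the standard single-number reading of an
"optimal cut-off" and is consistent with reporting one
sensitivity/specificity pair per parameter.

One caveat is inherited deliberately: epochs are pooled across subjects
without modelling within-subject correlation, mirroring the pooled
design this analysis reproduces. A mixed-effects treatment is out of
scope.

## Numerical choices and problem sizes

* Periodogram, bispectrum and entropy estimators are checked against
  brute-force direct-DFT / explicit-summation oracles at 10⁻⁹ relative
  tolerance.
* The statistical calibration checks use 2000 null replicates at n = 80
  epochs (Pearson and ANOVA type-I within 3.5–6.5%) and 1000
  label-permuted ROC replicates; the pipeline-level null (all coupling
  dials flat, including the saturation bound) uses 100 seeds of a
  two-subject, shortened-cycle cohort with a per-feature rejection
  bound of 0.15 set a priori from Binomial(100, 0.05) across eleven
  features.
* The cohort-level recovery check runs the full default eight-subject
  scenario; amplitude anchors use 200 simulated 3-s epochs per state.
* CSV output uses `%.17g`, so written recordings round-trip exactly;
  EDF output is 16-bit quantized (tested within one quantization step).

## Known limitations

Single channel only; no compression-artifact model, so the pipeline's
robustness to artifact-contaminated pauses is untested; the coupling
curves at intermediate flow are assumptions; entropy magnitudes depend
on the chosen probability convention and are comparable only within a
convention; the proprietary bispectral index itself is not computed.
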