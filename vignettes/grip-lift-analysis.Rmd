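---
title: "Grip-lift analysis across gravitoinertial environments: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grip-lift analysis across gravitoinertial environments: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(griplift)
```

## The task and the signals

In a precision grip-lift task a participant grasps a small instrumented
object (here 0.13 kg) between thumb and finger(s), lifts it, holds it
stationary for about two seconds and sets it down. Three channels are
recorded at 120 Hz: grip force `gf` (normal force on the grip surfaces),
stand load force `lf_stand` (tangential load, valid until lift-off), and
the combined gravitational plus kinematic acceleration `az` along the
object's axis. After lift-off the load force on the digits is
reconstructed as `mass * az`. Under centrifugation the background
gravitoinertial level Gz is stepped through 1, 1.5, 2, 2.5, 2, 1.5, 1 g
(18.4 s stable phases; 1.6 s fast transitions; slower 13.4 s transitions
into and out of 1 g; 27.4 s idle bookends), with four lifts per stable
phase.

Healthy adults scale grip force *predictively*: grip and load force rates
rise together, the preload phase (finger contact before load onset) is
tens of milliseconds, and grip peaks are linearly related to load peaks.
The scientific question behind the session-level analysis is how this
predictive scaling behaves when the background gravity — and hence object
weight — switches.

## Per-trial pipeline

`analyze_trial()` composes the stages below; each is exported separately.

**Filtering.** All channels are low-pass filtered at 20 Hz with a
second-order Butterworth filter applied forward and backward
(`lowpass_filter()`), giving zero phase lag and an effective fourth-order
magnitude response. Recursive filters have edge transients, so the input
is extended by odd reflection at both ends (half a second) and the
extension discarded; a constant signal passes through unchanged to within
1e-8. Force rates are central finite differences with one-sided stencils
at the boundaries (`force_rate()`). Non-finite samples anywhere are a hard
error: records are short, and silent imputation would bias the rates.

**Events.** Onsets are detected on the filtered force rates: the first
sample from which the rate stays strictly above 0.4 N/s for at least
125 ms (`ceiling(0.125 * 120)` = 15 samples; `detect_onset()`). The onset
is the *first* sample of the qualifying run, the convention that maximizes
consistency of the preload duration. The grip onset is searched from the
record start, the load onset only from the grip onset onward (fingers
contact first). Object weight is estimated from the pre-lift accelerometer
baseline as `mass * mean(az)` before the grip onset, so a trial measures
its own gravity level. Lift-off `tLFw` is the load force's first crossing
of that weight, linearly interpolated between bracketing samples — the one
event defined by a level crossing rather than a sample test
(`weight_crossing_time()`). The trial end is the first time the load-force
rate stays below −2 N/s for 125 ms (the release), minus 250 ms
(`detect_trial_end()`). Peaks are global maxima over the analysis window
with ties broken toward the earliest time.

**Metrics.** Plateau forces are means over the final second before the
trial end. The post-peak grip-force relaxation is fitted as
`GF(t) = a + b * exp(-c * (t - tGFmax))` by bounded nonlinear least
squares (`minpack.lm::nlsLM`): starting values `a0` = last-second mean,
`b0 = GF(tGFmax) - a0`, `c0 = 2/s`; bounds `a, b >= 0`,
`c` in `[1e-3, 50]` 1/s; up to five restarts with `c0` rescaled by
{1, 0.5, 2, 0.1, 10}. A segment with vanishing variance short-circuits to
the degenerate no-decay fit (`b = 0`, `c` at its lower bound). The offset
`a` is a robust plateau estimate; across a noisy synthetic session it
correlates with the last-second mean at r > 0.8, which is what makes the
fit useful on real data where the hold is short. Grip–load coupling is the
Pearson correlation between the load-force rate over the loading phase
`[tLFo, tLFw]` (reference) and the grip-force rate shifted by every
integer-sample lag within ±150 ms (±18 samples); `xcorr_rates()` returns
the maximizing pair, positive lags meaning grip leads. Correlation ties
resolve toward the smallest |lag|; segments with variance below
1e-12 N²/s² raise an undefined-correlation error rather than returning a
spurious value.

## The switching model

For each pair of consecutive stable phases and each participant,
`switching_indices()` computes `dGF = GFmax(trial 1 of the next phase) -
GFmax(trial 4 of the previous phase)` and the analogous `dLF`. The
prediction model decomposes the mean switch as

`dGF = alpha * m * delta_g * g0 + beta`

where the first term is the anticipatory scaling to the expected weight
change and `beta` a safety margin reflecting uncertainty. Two readings are
implemented (`decompose_fixed_gain()`, `decompose_fixed_margin()`): gain
fixed at `alpha = 1.5` (the mean first-trial grip/load ratio) with the
margin free, or margin fixed at `beta = 1.44` N (its 1 g value) with the
gain free. Both satisfy `predictive_term + beta == dGF` identically; the
identity and the round-trip duality (feeding one mode's output into the
other recovers the fixed parameter) are tested to 1e-9 N.
`build_table2()` aggregates participant-level indices into transition
means — per-participant first, then across participants, matching the
degrees of freedom of the phase-level t statistics — and applies both
decompositions. `g0 = 9.81` m/s² throughout; gravity is carried in
multiples of g in session tables and converted only inside the
decompositions.

## The synthetic generator

Raw centrifuge recordings of this task are not publicly deposited, so the
package carries a first-class generator (`simulate_trial()`,
`simulate_session()`) whose defaults encode the study conditions: 0.13 kg
object, 120 Hz sampling, white Gaussian force noise of SD 0.05 N (inside
the ±0.1 N stated sensor accuracy; accelerometer noise 0.1 m/s²),
per-trial gravity jitter of SD 0.07 g (the dispersion observed across
stable phases), a 12% load-peak overshoot, four trials per phase, and the
seven-phase schedule above.

A trial is synthesized as a piecewise C¹ profile: baseline; a single
smoothstep grip-force rise spanning preload and loading (one contiguous
suprathreshold rate run, as the onset rule assumes); a load-force
smoothstep from its onset (47 ms after grip onset on trials 2–4, 71 ms on
trial 1, reflecting the longer first-trial preload) through the weight to
the overshooting peak over 300 ms; exponential grip relaxation with time
constant `decay_tau` to the plateau; load settling to `m * g * g0`
exactly; a 2 s hold; and a smoothstep release whose mean rate (6 N/s)
comfortably exceeds the −2 N/s end rule. The grip-force peak is

`GFmax = grip_gain * LFmax + base_margin + peak_margin + first_trial_margin * [trial = 1]`

with plateau `a = grip_gain * m * g * g0 + base_margin`. `grip_gain`
defaults to 1.5 (the observed plateau and first-trial ratio);
`first_trial_margin` to 1.44 N (the 1 g uncertainty margin), so ascending
switches exceed descending ones exactly as in the task; `peak_margin`
(0.7 N) is the transient within-trial grip overshoot that relaxes away
with `decay_tau` — being additive it cancels in every switching index, and
its size makes the generator's first-trial peak regression intercept
(`peak_margin + first_trial_margin` ≈ 2.1 N) match the magnitude reported
for this task. `decay_tau` defaults to 0.55 s, between the ~0.71 s
(ascending) and ~0.38 s (descending) phase means reported; the generator
does not emulate that phase asymmetry. An imposed grip–load lag is
realized as an integer-sample shift of the grip trace; because the grip
rise is a single ramp rather than a scaled copy of the load rise, the
absolute cross-correlation lag of a synthetic trial also carries a small
profile-asymmetry component (a few samples, grip leading), and the
imposed lag is therefore asserted in difference form — lag(k) − lag(0) is
exactly k samples.

Ground truth records every imposed quantity (event times, plateau forces,
decay parameters, margins, lag), which is what the recovery tests compare
against.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: tremor and physiological force variability
(noise is white and additive), slip events and friction, within-phase
learning or fatigue trends (trials 2–4 are statistically identical), the
phase-dependence of the relaxation rate, ECG/stress covariates, and
genuinely asymmetric descending switches (the generator's descending
behaviour follows the same gain/margin rule as ascending; the empirical
asymmetry beyond the first-trial margin is exactly what the decomposition
is for).

## Numerical choices and degenerate inputs

- Run lengths round conservatively: 15 samples for 125 ms at 120 Hz,
  30 samples for the 250 ms backoff. Thresholds are strict (`>`, `<`).
- Intervals are half-open in file formats; event times are seconds from
  record start.
- All thresholds (0.4 N/s, 125 ms, −2 N/s, 250 ms, 20 Hz, ±150 ms, 1 s
  plateau window) are exposed in `analysis_params()` with the protocol's
  values as defaults.
- Degenerate cases are errors, not guesses: absent lift (onset never
  sustained), no release, weight never reached, plateau window preceding
  lift-off, zero-variance correlation segments, non-finite samples,
  `delta_g = 0` under the fixed-margin mode.
- Problem sizes in the test suite: oracle equivalence on 1000 random rate
  signals and 500 random smooth pairs; 200-replicate noisy decay
  recovery; one 196-trial noiseless session recovered within 2 samples
  per event; 20 replicate noisy sessions for gain/margin recovery. At the
  default 0.05 N noise, all six events land within 5 samples of ground
  truth on ≈95% of trials (94.8 ± 0.7% at n = 1000); the suite bounds
  this at 90% with a median worst-event error ≤ 4 samples, so the check
  is not hostage to Monte-Carlo fluctuation around the point estimate.

## Known limitations

- The "zero phase lag autoregressive" filter is underspecified in the
  protocol; the Butterworth-squared implementation here is the standard
  choice in the grip-force literature but other recursive designs would
  shift event times by a sample or two.
- The coupling lag of synthetic trials is not a pure readout of the
  imposed lag (see above); on real data the analogous bias depends on the
  true profile shapes.
- `fit_gf_decay()` fits from the grip peak onward; when the peak is barely
  above the plateau (small `b`), `c` is weakly identified and its
  uncertainty is large — the fit reports `rmse` so such trials can be
  screened.
- The weight estimate uses the pre-lift accelerometer baseline; a trial
  started during a gravity transition would violate that assumption.
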