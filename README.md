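# griplift

Analysis of precision grip-lift trials recorded under changing
gravitoinertial load (Gz), e.g. in a long-arm human centrifuge where
participants repeatedly lift a small instrumented object at 1–2.5 g.

When we lift an object, grip force (the normal force of the digits on the
grip surfaces) is scaled *predictively* to load force (the tangential force
that destabilizes the grasp: weight plus inertia). This package implements
the standard grip-lift analysis chain for force/acceleration time series
sampled at 120 Hz, and the session-level *switching* analysis that asks how
grip force is re-scaled on the very first lift after gravity changes:

- **Signal conditioning** — zero-phase 20 Hz low-pass filtering
  (second-order recursive filter run forward and backward),
  finite-difference force rates, and reconstruction of the post-lift-off
  load force from object mass × measured gravito-inertial acceleration.
- **Event segmentation** — force onsets (rate > 0.4 N/s sustained 125 ms),
  lift-off as the load force's crossing of object weight, trial end (load
  force rate < −2 N/s sustained 125 ms, minus 250 ms), force peaks, and the
  preload / loading phase durations.
- **Trial metrics** — grip/load ratios at the load peak and plateau
  (last-second means), peak grip-force rate, the exponential grip-force
  relaxation `GF(t) = a + b·e^(−ct)` fitted between the grip peak and trial
  end, and grip–load coupling as the maximal lagged cross-correlation of
  the force rates over the loading phase (lags within ±150 ms; positive lag
  = grip leads).
- **Switching analysis** — per transition between gravity environments,
  `ΔGF = GFmax(trial 1, next) − GFmax(trial 4, previous)` (and `ΔLF`
  likewise), decomposed under the prediction model

  `ΔGF = α·m·Δg·g0 + β`

  either with a fixed predictive gain `α = 1.5` and a free safety margin
  `β` ("correct prediction"), or with a fixed margin `β = 1.44 N` and a
  free gain ("incorrect prediction").
- **Synthetic trial generator** — produces grip-lift sessions with the full
  temporal structure of the task (preload, loading with a ~12% load
  overshoot, exponential grip relaxation to plateau, 2 s hold, release)
  under a programmable gravity schedule, with complete ground truth, so
  that every stage of the pipeline is testable without raw centrifuge data.

## Worked example

```r
library(griplift)

ses <- simulate_session(gravity_schedule(), n_participants = 7,
                        sim_config(), seed = 1)
mt  <- analyze_session(ses)          # 196 trial-metric rows
sw  <- switching_indices(mt)         # 42 participant x transition records
build_table2(sw)                     # transition means + both decompositions
```

```
  transition delta_g    dLF   dGF fg_pred fg_beta fm_pred fm_alpha
1      1-1.5     0.5  0.744 2.547   0.956    1.59   1.107     1.74
2      1.5-2     0.5  0.684 2.451   0.956    1.49   1.011     1.59
3      2-2.5     0.5  0.594 2.334   0.956    1.38   0.894     1.40
4      2.5-2    -0.5 -0.661 0.451  -0.956    1.41  -0.989     1.55
5      2-1.5    -0.5 -0.752 0.322  -0.956    1.28  -1.118     1.75
6      1.5-1    -0.5 -0.690 0.385  -0.956    1.34  -1.055     1.65
```

Each row is one gravity transition. `dLF` is the weight step seen across
the transition (≈ `m·Δg·g0` = ±0.64 N, plus the load peak overshoot);
`dGF` is the grip-force switch. Ascending switches (~2.4 N) are far larger
than the weight step alone, descending switches (~0.4 N) are far smaller
than a pure prediction would allow — the asymmetry the decomposition
quantifies. `fg_pred`/`fg_beta` split `dGF` under the fixed gain
(`α·m·Δg·g0 = ±0.956 N`, margin free), `fm_pred`/`fm_alpha` under the
fixed 1.44 N margin (gain free). Fitting the model across the six
transition means recovers the generator's programmed behaviour:

```r
fit_switch_model(build_table2(sw))
#> alpha = 1.50, beta = 1.44 N (r = 1.000)

mean_switch_by_phase(sw, "ascending")
#> mean 2.44 N (SEM 0.04, n = 21, t = 68.1)

trial1_peak_regression(mt, "pooled")
#> slope = 1.50, intercept = 2.13 N, r = 1.000
```

and a single trial prints as

```
<trial_metrics> P02 g=1.50 trial 1: GFmax=5.38 N, LFmax=2.18 N,
  plateau ratio=1.59, preload=75 ms, tau=552 ms, r=0.773
```

From a shell, the same pipeline runs as
`exec/griplift-simulate --out raw/ --seed 1`, then
`exec/griplift-analyze --manifest raw/manifest.tsv --out an/`, then
`exec/griplift-session --metrics an/metrics.tsv --out ses/`.

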