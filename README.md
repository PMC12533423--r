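# rtfluency

Distributional response-time and recognition-memory analysis for
perceptual-disfluency experiments.

When words are blurred (or otherwise made harder to read) during study,
later memory for them sometimes improves. Whether that happens seems to
depend on *which processing stages* the degradation reaches — and mean
RTs cannot tell a shift of the whole RT distribution apart from a
stretched slow tail. `rtfluency` is for researchers in word recognition
and memory who want to localise such effects with the standard
distributional toolkit:

* **Ex-Gaussian decomposition** of encoding RTs — Gaussian(μ, σ) ⊛
  Exponential(τ), so mean = μ + τ and SD = √(σ² + τ²) — with
  contrast-coded condition effects on the identity (μ) and log (σ, τ/β)
  scales, estimated two-stage (per-subject ML + subject bootstrap) or
  pooled.
* **Wiener diffusion decomposition** — first-passage densities via the
  standard small/large-time series, per-condition ML fits of drift
  rate *v*, boundary *a*, and non-decision time *Ter* (z = 0.5),
  EZ-diffusion closed-form starts.
* **Vincentile quantile and delta plots** — per-subject quantiles
  averaged across subjects, quantile-wise condition differences, and a
  four-way qualitative pattern classifier (`no_difference`,
  `complete_shift`, `late_differences`, `early_differences`).
* **Signal detection analysis** of old/new recognition — d′ = z(H) −
  z(F), criterion c = −(z(H)+z(F))/2, and the equivalent probit
  regression in which status × condition interactions are d′
  differences and main effects carry −c.
* **Inference summaries** — bootstrap credible intervals (90%
  directional / 95% two-sided), directional posterior probabilities,
  evidence ratios ER = p/(1−p), and the conjunction decision rule
  (zero excluded ∧ p ≥ 0.95 ∧ ER > 3).
* **A synthetic-experiment generator** emulating counterbalanced
  blur × frequency designs (6 lists, old/new yoking, 2:1
  target:filler ratios) with known ground truth, for recovery and
  calibration studies.

Everything takes a data frame of trials first and returns tibbles, so
the pieces chain with the pipe; fitted objects have `tidy()`/`glance()`
methods and result types have `autoplot()` methods.

## Worked example

Simulate a full 216-subject lexical-decision experiment under the
stage-specific scenario (high blur raises both μ and τ; low blur a small
μ shift only), then run the whole pipeline:

```r
library(rtfluency)

sim <- simulate_full_experiment("1A", scenario = "stage_specific", seed = 1)
report <- run_pipeline(trials = sim$trials, seed = 1)
report
```

```
rtfluency pipeline report (seed 1)

Ex-Gaussian contrast effects:
  parameter contrast    mean      se cri_lower cri_upper posterior_prob evidence_ratio supported
1 log_beta  blur1     0.5762 0.05977  0.479752    0.6781          1.000 Inf            TRUE
2 log_beta  blur2     0.0767 0.09100 -0.073632    0.2271          0.798 3.96           FALSE
3 log_sigma blur1    -0.0116 0.08243 -0.146357    0.1233          0.446 0.81           FALSE
4 log_sigma blur2     0.1059 0.09224 -0.047414    0.2583          0.876 7.10           FALSE
5 mu        blur1     0.1044 0.00612  0.094379    0.1146          1.000 Inf            TRUE
6 mu        blur2     0.0115 0.00634  0.000776    0.0218          0.963 25.67          TRUE

Delta-plot patterns:
  contrast label                pattern
1 blur1    high - (clear+low)/2 late_differences
2 blur2    low - clear          complete_shift

Recognition (SDT) estimates:
  blur  hit_rate fa_rate dprime criterion c_model
1 clear    0.628   0.275  0.926    0.136  -0.136
2 high     0.651   0.274  0.988    0.106  -0.106
3 low      0.653   0.319  0.863    0.0382 -0.0382
```

Reading the output: the high-blur contrast (`blur1`) shows a supported
positive effect on both μ (a ~0.10 s shift of the whole distribution,
generative truth 0.107) and log β/τ (a stretched slow tail) — the
injected stage-specific pattern — while the low-vs-clear contrast
(`blur2`) shows only the small μ shift (truth 0.016 s), with an
interval spanning zero on the tail. The σ effects are the least
identifiable at 28 trials per cell and are not reliably detected here.
The delta plots tell the same story graphically (growing quantile
differences for high blur, a flat shift for low blur), and the
recognition test recovers the generative d′ advantage for high-blur
items (truth: 0.90/0.90/1.03 for clear/low/high).

`autoplot(report$quantile_profile)`,
`autoplot(report$delta_profiles$profile[[1]])` and
`autoplot(report$sdt_estimates)` draw the standard quantile, delta, and
SDT panels.

See the vignette (`vignettes/distributional-disfluency.Rmd`) for the
models, the generator's reference conditions, and numerical choices.

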