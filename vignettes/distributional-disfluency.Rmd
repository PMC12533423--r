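---
title: "Distributional RT and recognition-memory analysis of perceptual disfluency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributional RT and recognition-memory analysis of perceptual disfluency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtfluency)
library(dplyr)
```

## The problem

Degrading the legibility of study material — for example by blurring words —
sometimes improves later memory (the *perceptual disfluency* effect), and
sometimes does nothing. Mean response times are a blunt instrument for
finding out *where* in the processing stream a blur manipulation acts:
RT distributions are right-skewed, and a manipulation can shift the whole
distribution, stretch only its slow tail, or both, while leaving the mean
pattern ambiguous. `rtfluency` implements the distributional toolkit used
to localise such effects: ex-Gaussian decomposition, Wiener diffusion
decomposition, Vincentile quantile/delta profiling, and an equal-variance
signal-detection analysis of the subsequent old/new recognition test —
driven by a synthetic-experiment generator with known ground truth.

## The models

### Ex-Gaussian decomposition

Encoding RTs are modelled as the convolution of a Gaussian
$\mathcal N(\mu, \sigma^2)$ and an exponential with mean $\tau$.
The mean of the composite is $\mu + \tau$ and its SD is
$\sqrt{\sigma^2 + \tau^2}$; $\mu$ indexes a shift of the whole
distribution, $\tau$ the slow tail. Condition effects are decomposed with
an identity link on $\mu$ and log links on $\sigma$ and $\tau$ (reported
as *beta* in the distributional-regression tradition), using two
orthogonal planned contrasts on the three-level blur factor:

* **blur1**: high blur (+0.5) against clear and low blur (both −0.5);
* **blur2**: low blur (+0.5) against clear (−0.5), high blur 0.

The blur1 weights are used exactly as printed in this literature even
though they do not sum to zero; with a saturated cell-means solve this
makes the blur1 coefficient exactly "high minus the mean of clear and
low" on each link scale, while the intercept is the midpoint of the high
cell and the clear/low mean rather than the grand mean. A `centered`
option (−0.25/−0.25/+0.5) is available and labelled non-default.

The default estimator is **two-stage**: an ex-Gaussian maximum-likelihood
fit per subject × condition cell, the cell parameters mapped through the
contrast design per subject, and coefficients averaged over subjects.
Uncertainty comes from a case-resampling bootstrap over subjects
(default 16,000 draws, mirroring the posterior sample sizes of the
hierarchical Bayesian counterpart this workflow emulates at desk scale).
A `pooled` mode fits each condition cell over all subjects instead.

### Wiener diffusion decomposition

The four-parameter Wiener first-passage model (drift $v$, boundary
separation $a$, relative start $z$, non-decision time $T_{er}$; unit
diffusion) is fit per condition by maximum likelihood with accuracy
coding (correct = upper boundary) and $z = 0.5$ unless configured. The
defective first-passage densities use the standard small-time and
large-time series expansions with term counts chosen for an absolute
tolerance of $10^{-8}$, switching to whichever expansion needs fewer
terms. EZ-diffusion closed-form moments provide starting values; at its
own forward moments that inversion is exact, which the tests assert.
$v$ indexes evidence-accumulation efficiency (a late, analytic
component); $T_{er}$ indexes encoding and motor time (an early
component). No inter-trial variability parameters are included: the body
of evidence this package operationalises discusses only $v$ and $T_{er}$,
and the four-parameter model keeps recovery identifiable at per-condition
trial counts.

### Vincentile quantile and delta profiles

Correct-trial RTs are summarised per subject and condition at the
$.1, .3, .5, .7, .9$ quantiles (type-7 interpolation; the estimator is
recorded in the profile's metadata), averaged over subjects
(Vincentization), and differenced between conditions — composite
references (e.g. high vs the mean of clear and low) average the
reference conditions with equal weight, mirroring the model contrasts.
The resulting delta profile is classified into one of four qualitative
patterns — `no_difference`, `complete_shift`, `late_differences`,
`early_differences` — with two thresholds: a magnitude floor
`eps` (default 10 ms) and a fitted-slope tolerance (default 5 ms per
quantile step). The patterns in this literature are qualitative; the
defaults are documented, configurable, and expressed in the unit of the
deltas, so rescaling data and thresholds together leaves the label
unchanged.

### Recognition memory (SDT)

Old/new responses follow the equal-variance Gaussian model. From
hit/false-alarm counts, $d' = z(H) - z(F)$ and
$c = -\tfrac12\,(z(H) + z(F))$; extreme rates receive the log-linear
0.5/1 correction (recorded in the output). The same model is expressed
as a probit regression of P("old") on item status (coded ±0.5),
condition contrasts, and their interactions: the status coefficient is
the grand $d'$, status × contrast interactions are $d'$ differences, and
the non-status terms carry criterion differences on the reversed-sign
($-c$) parameterisation; plots always use the conventional sign. On
aggregated counts without random effects the two routes coincide
exactly, which the tests assert to $10^{-8}$. The default likelihood is
binomial on condition × status aggregates (the simplification this
design family itself adopts for its factorial experiment); a Bernoulli
trial-level mode gives identical point estimates.

### Inference summaries

Bootstrap draws of each contrast coefficient are condensed into the
standard reporting row: mean, SE, an equal-tailed interval — 90% for
directional hypotheses, 95% for two-sided — the directional posterior
probability $p$, and the evidence ratio $\mathrm{ER} = p/(1-p)$,
rendered `Inf` when every draw is on the hypothesised side. A
directional hypothesis is *supported* only when zero is excluded from
the interval, $p \ge 0.95$, and $\mathrm{ER} > 3$; $\mathrm{ER} < 0.3$
supports the alternative and the band between is inconclusive.
Point-null evidence ratios (Savage–Dickey style) require a prior that a
bootstrap cannot supply and are deliberately out of scope. No
multiplicity correction is applied; hypotheses are evaluated
individually, as is conventional for this reporting style.

## The synthetic experiment generator

`simulate_full_experiment()` reproduces the structure of the three study
layouts: a lexical-decision experiment with 168 words rotated through
six counterbalanced lists (84 study + 84 new per list, 28 per blur
level; 84 nonword fillers), 216 subjects at 36 per list, with blur
either reinstated at test (`"1A"`) or rendered clear with yoked
false-alarm sets (`"1B"`); and a semantic-categorisation experiment
(`"2"`) crossing blur with word frequency, 90 non-animal study words
plus 45 animal fillers per list (a 2:1 ratio), 90 non-animal new words,
and 432 subjects.

Encoding RTs come from condition-specific ex-Gaussian cells (or a
diffusion process) with Gaussian subject and item intercepts on the link
scales. The scenario presets encode the three competing theoretical
accounts as generative patterns: `stage_specific` (high blur raises both
$\mu$ and $\tau$; low blur a small $\mu$ shift), `compensatory` ($\mu$
only), `metacognitive` ($\tau$ only, for both blur levels), plus a
`null`. Magnitudes echo the scale reported for blur manipulations in
lexical decision — baseline clear cell $\mu = 0.55$ s, $\sigma = 0.08$ s,
$\tau = 0.20$ s; a 0.107 s high-blur $\mu$ shift; 0.427 on $\log\tau$;
a 0.016 s low-blur shift — with subject SDs of 0.05 s on $\mu$ and
0.2/0.3 on $\log\sigma$/$\log\tau$, and smaller item SDs (0.02 s,
0.1, 0.1). These are stated once here as the package's reference
conditions. Recognition responses follow the SDT rule
$P(\text{"old"}) = \Phi(d'\,s_c - c)$ with status $s_c = \pm\tfrac12$,
baseline $d' = 0.9$ and a 0.13 high-blur advantage.

What the generator deliberately does **not** emulate: real lexical
properties of items (items are abstract identifiers), random slopes (the
random-effects structure is intercepts-only by default, chosen so
recovery at the default sizes is identifiable), contaminant/lapse RT
processes beyond a condition-level error rate, and any particular
relation between encoding difficulty and memory beyond the preset
$d'$ tables. Passing recovery tests therefore shows the estimators are
correct and well calibrated under the assumed data-generating family —
not that real data satisfy those assumptions.

## Numerical choices

* The ex-Gaussian density is evaluated through the scaled complementary
  error function in the bulk and left tail and a log-space form in the
  right tail, so it is finite and proper for extreme $\sigma/\tau$
  ratios (asserted by quadrature in the tests).
* Ex-Gaussian ML fits run on $(\mu, \log\sigma, \log\tau)$ from
  method-of-moments starts, under box constraints that keep $\sigma$ and
  $\tau$ above 2% of the sample SD. Small cells (a few dozen trials)
  otherwise collapse $\sigma \to 0$ on a likelihood ridge a few percent
  of the time; a fit pinned at a bound is the boundary member of the
  family (Gaussian or shifted exponential), flagged, not an error. At
  28 trials per cell the cell MLEs trade a little $\tau$ for $\mu$
  (small upward $\mu$ bias, downward $\tau$ bias); contrast coefficients
  are unaffected because the bias is shared across cells, and the
  remaining subject-level noise is heavy-tailed, which makes the
  bootstrap intervals conservative.
* The diffusion simulator is Euler–Maruyama with a Brownian-bridge
  crossing correction, which removes most discretisation bias at the
  default 1 ms step; simulated first passages match the analytic
  densities to KS distance < 0.02 at $n = 10^5$.
* Trim bounds are inclusive (`[0.2, 2.5]` s retained): removal language
  in this literature is phrased as strict inequalities, so boundary
  values stay. Accuracy-based participant exclusion (strictly below
  80%) is applied before RT trimming.
* Ties and degenerate inputs: empty trial sets propagate as empty
  results with zeroed reports; subjects below per-cell floors are
  dropped with a message and recorded in the fit object; recognition
  cells with all-"old"/all-"new" responding receive the log-linear
  correction and a flag.

## Problem sizes used in the shipped checks

The shipped test-suite and acceptance script run the estimators at the
design's own scale where that is what is being claimed (216 subjects ×
28 trials per cell for distributional recovery; 6,048 trials per
condition for diffusion recovery; $10^5$–$10^6$ draws for density and
moment identities) and at reduced sizes for properties that do not
depend on scale (toy Vincentile oracles, contrast algebra, decision-rule
arithmetic). Interval calibration is checked over 200 null simulations
of 200 subjects each.

## A worked run

```{r, eval = FALSE}
sim <- simulate_full_experiment("1A", seed = 1)
report <- run_pipeline(trials = sim$trials, seed = 1)
report            # contrast table, delta patterns, SDT estimates
autoplot(report$quantile_profile)
autoplot(report$delta_profiles$profile[[1]])
autoplot(report$sdt_estimates)
```

## Known limitations

* The two-stage + bootstrap inference path is a frequentist stand-in
  for the hierarchical Bayesian models this workflow emulates; it
  matches their signs and approximate magnitudes on well-powered
  synthetic data but is not numerically identical to a maximal
  random-effects posterior.
* The diffusion fit is per-condition and non-hierarchical; with fewer
  than ~40 trials per condition it warns and should be trusted for
  orderings, not point values.
* The delta-pattern classifier is a qualitative instrument; its two
  thresholds matter near boundaries between patterns and should be
  reported alongside any label.
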