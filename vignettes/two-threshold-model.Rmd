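---
title: "The two-threshold model of acidic pH avoidance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The two-threshold model of acidic pH avoidance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acidnav)
```

## The behavioral question

*Caenorhabditis elegans* avoids acidic pH (below about 4.0) using two of its
stock locomotory maneuvers: **reversal avoidance** (an abrupt backward run
followed by a large, essentially random reorientation — klinokinesis) and
**curve avoidance** (a gradual steering turn toward the less acidic side —
klinotaxis). On a plate carrying a straight acidic border, the choice
between the two depends strongly on the **angle of encounter**: worms
hitting the acid head-on (near 90° to the border) mostly reverse, worms
grazing it at a shallow angle mostly curve.

The two-distinct-threshold model explains this angle dependence without any
angle sensing. Each maneuver is triggered stochastically by the *absolute*
sensed pH, with its own threshold: curves begin at a relatively mild
threshold pH, reversals only at a more acidic one. A worm entering at a
shallow angle completes its escape by curving before it ever reaches the
reversal zone; a head-on worm overshoots the curve zone while it is still
rotating and reaches the deeper reversal threshold. The angle dependence is
an emergent property of the geometry plus the threshold gap.

## The model worm

The worm is a point moving at constant speed $v = 0.15$ mm/s, updating
position and heading every $\Delta t = 0.8$ s. A pH sensor is held 0.51 mm
ahead of the positional point and swung alternately to the left and right
of the heading each step (swing amplitude is a configuration knob, default
30°; the published description specifies the alternation but not the
amplitude). At each step the sensed pH $C$ feeds two sigmoid per-step
probabilities

$$p_c(C) = \frac{1}{1 + \exp\!\big((C - \beta_c)/\alpha_c\big)}, \qquad
  p_r(C) = \frac{1}{1 + \exp\!\big((C - \beta_r)/\alpha_r\big)},$$

where $\beta_c$, $\beta_r$ are the curve and reversal threshold pHs and
$\alpha_c$, $\alpha_r$ their spreads (all in pH units). Two independent
Bernoulli draws decide the step; if both fire at once, reversal wins, so
$P(\text{reversal}) = p_r$ and $P(\text{curve}) = p_c (1 - p_r)$.
Independence is the minimal assumption consistent with the stated
tie-break. The exponent saturates to 0/1 instead of overflowing.

Reorientations are instantaneous, in-place heading changes (the model
describes direction changes only; backward displacement during a real
reversal is out of scope):

* **reversal**: magnitude $\sim \mathcal N(137°, 8°)$, side uniformly
  random;
* **curve**: magnitude $\sim \mathcal N(\varphi_c, \Delta\varphi_c)$,
  turned toward the side whose pH sample among the current and previous
  step was less acidic (lateral information comes from the alternating
  sensor swing). Ties, and a curve on the very first step, pick a side
  uniformly at random.

A trial starts at a uniform random position in a 1-mm band on the less
acidic side (default below $-2$ mm; the border is $x = 0$, positive $x$
into the acid) with initial heading $\theta_0 \in (-90°, 90°]$ drawn from
the flux-weighted density $\propto 1 - |\sin\theta_0|$, measured from the
border normal. This convention makes the density maximal for head-on
approach and zero for border-parallel headings, which would never encounter
the acid; it is implemented by rejection sampling against the uniform
envelope. The trial ends when a reorientation leaves the heading with a
negative component along the border normal ($\cos\theta < 0$; exact
parallels continue). The maneuver that achieved the escape, plus the
heading and signed distance immediately before it, is the recorded
avoidance event; the encounter angle is the acute angle to the border line,
$90° - |\theta|$. Trials are capped at 10,000 steps (2.2 simulated hours);
capped trials are flagged and excluded from statistics by default. Cohorts
derive one seed per trial from the master seed, so they are reproducible
and order-independent.

```{r cohort}
field <- make_parametric_gradient(
  border_ph = 4, slope = 0.5, span = 6, far_ph = 6, near_ph = 3
)
events <- run_cohort(500, field, optimal_params(), sim_config(), seed = 1)
head(events, 3)
```

## Gradient fields

The assay-plate gradient is represented as a 1-D piecewise-linear monotone
(non-increasing) map from signed border distance to pH, clamped to its end
values outside the measured span, so it is defined everywhere the worm can
wander. Linear interpolation between measured strip values is the least
assumptive monotone choice; measurements come as six 1-mm strips spanning
$-3$ to $+3$ mm, attributed to the strip centres. Parametric fields anchor
pH 4.0 at the border (the bromophenol-blue color transition) with a
configurable slope. Temporal drift of the border over the assay is ignored:
the distance and angle relationships it would perturb are stable in the
data the model emulates.

## The statistics pipeline

Real-worm-style tables first collapse the four observed maneuver classes
(long/short reversal, gradual/deep curve) into the two model classes and
keep only the first event of each serial avoidance run. Then:

* **choice ratio**: events binned every 10° of encounter angle (half-open
  bins, last bin closed), per-bin reversal fraction, and the Pearson
  correlation between bin midpoints and reversal fraction. Bins with fewer
  than 15 events are flagged and excluded from the correlation (but still
  reported); the p-value is the usual t transform with $k - 2$ df. Fewer
  than 3 usable bins leaves the correlation undefined, with a warning.
* **distance summaries**: per-maneuver histograms binned every 0.2 mm
  (aligned to multiples of the width), mean, SD ($n-1$), quartiles.
* **inference**: variance comparisons use the two-sided F test (larger
  variance over smaller, $(n-1, n-1)$ df); mean comparisons use the
  classical pooled-variance Student's t test, matching the tests named in
  the source analyses.

```{r stats}
cs <- bin_choice_ratio(events, min_count = 15)
cs$pearson_r
distance_summary(events)
```

## Parameter search

`grid_search()` re-runs the selection of the published parameter set:
enumerate the full Cartesian product of candidate values (deterministic
lexicographic order), simulate a cohort per combination, and score each
against reference summary statistics. The published value lists multiply
to 3888 combinations; the original report states 2916 without describing
any exclusion, so the full product is enumerated and the count reported —
the discrepancy is documented rather than silently resolved.

The selection criterion behind "parameters matching the experimental data"
is not stated in the original work, so the score is an explicit weighted
sum, with weights exposed in the configuration:
RMSE of the binned reversal ratios (over bins unflagged in both summaries)
plus absolute differences of the per-maneuver mean distances and of the
overall reversal fraction, all with default weight 1. The score is zero
only for a perfect statistical match. Self-recovery — statistics generated
at a grid point are best matched by that point — is part of the test suite,
run on a 32-combination subgrid at 1000 trials per combination; full-grid
runs at 3000 trials per combination remain available through the same
interface.

## Synthetic data

The raw videos behind the real-worm tables were never deposited, so the
package generates statistical stand-ins:

* `generate_gradient_profile()` emulates the strip measurement: six strip
  centres, a linear profile of chosen steepness anchored at pH 4.0, and a
  small uniform measurement jitter (default ±0.05 pH, re-sorted so
  monotonicity always holds; no measurement-error model is given for the
  original assay, so the jitter is a deliberate, conservative choice).
* `generate_event_table()` draws encounter angles from the flux-weighted
  density, assigns maneuvers by a logistic model in the angle, draws
  distances from per-maneuver normals truncated to the plate span, and
  groups events into serial runs of geometric length. Defaults were chosen
  once to mirror the wild-type pattern: reversal probability rising from
  about 0.05 (parallel) to about 0.9 (head-on), curve events centred 1 mm
  less acidic than reversal events, SD 0.3 mm.

Passing tests on these generators show that the pipeline recovers known
generative structure (slope sign, distance ordering, $\sigma$) — they do
not certify the segmentation of real videos into maneuvers, which is
outside the package's scope.

## Numerical and design notes

* Headings are normalized to $(-180°, 180°]$; the termination test is a
  strict $\cos < 0$.
* Per-trial seeds are `master + trial index` (mod $2^{31}-1$);
  per-combination seeds in the grid search are drawn once from the master
  seed.
* Distance histogram bin assignment adds a $10^{-9}$ guard so values on a
  bin edge through floating-point noise land in the intended half-open bin.
* Event CSVs are written with 6 significant digits so identical seeds give
  byte-identical files.
* The `n_trials` configuration key is deliberately not called `n`: bare
  `n` is boolean shorthand in YAML.

## Problem sizes

The shipped tests use 3000-trial cohorts for cohort-level checks (matching
the published cohort size), $10^5$ draws for sampler calibration, and a
32-combination × 1000-trial subgrid for search self-recovery; these sizes
keep the full suite in the tens of seconds on one core while leaving
sampling error well inside the asserted bounds.

## Known limitations

* **Mean-distance ordering on shallow gradients.** The threshold gap
  ($\beta_c - \beta_r = 1.6$ pH with the published set) places curve events
  in less acidic territory than reversal events only when the field
  traverses both threshold zones within the worms' penetration range
  (roughly, slopes of 2.5 pH/mm and above for fields spanning both
  centers). On shallower fields the sigmoids' tails dominate: a small
  fraction of reversals fires far out in mild pH (where $p_r$ is small but
  never zero) and drags the reversal mean below the curve mean, even
  though every upper quantile stays ordered. This is a property of the
  sigmoid equations themselves, and the original simulation acknowledged
  that its mean distances did not exactly replicate the real worm's.
* The real-worm distance observable (furthest entry into the acid during
  the whole maneuver) differs from the model's (positional point
  immediately before the terminal reorientation); the two are compared
  qualitatively, never reconciled numerically.
* The sensor swing amplitude and geometry are unspecified in the source
  description; both are configuration knobs, not fixed truths.
* No body posture, no slowing response (orthotaxis), no distinction
  between long/short reversal or gradual/deep curve inside the model worm,
  and no 2-D radial gradients.
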