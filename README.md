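# acidnav

Simulation and statistics of acidic-pH avoidance navigation in
*Caenorhabditis elegans* under the **two-distinct-threshold model**.

On a plate carrying a spatial acid gradient, *C. elegans* escapes the
acidic region (below about pH 4.0) with two maneuvers: **reversal
avoidance** — an abrupt backward run followed by a large random
reorientation (klinokinesis) — and **curve avoidance** — a gradual steering
turn toward the less acidic side (klinotaxis). The choice between the two
depends on the angle at which the worm encounters the acid: head-on
encounters end in reversal, grazing ones in curve. The two-threshold model
attributes this to nothing but two absolute-pH thresholds, one per
maneuver. Each time step, at sensed pH $C$, the maneuvers fire with
probabilities

$$p_c(C) = \frac{1}{1 + e^{(C-\beta_c)/\alpha_c}}, \qquad
  p_r(C) = \frac{1}{1 + e^{(C-\beta_r)/\alpha_r}},$$

with the curve center $\beta_c$ at milder pH than the reversal center
$\beta_r$ (reversal wins simultaneous draws). The angle dependence of the
choice then emerges from the geometry of gradient crossing alone.

The package provides, for behavioral and computational ethologists:

* `gradient_field` — monotone piecewise-linear pH fields fitted from strip
  measurements (`fit_gradient()`) or built parametrically
  (`make_parametric_gradient()`);
* `simulator` — the stochastic model worm (`run_trial()`, `run_cohort()`):
  constant speed 0.15 mm/s, 0.8-s steps, a pH sensor 0.51 mm ahead swung
  alternately left/right, flux-weighted initial headings
  ($\propto 1-|\sin\theta|$), Normal(137°, 8°) reversal turns, and curve
  turns toward the less acidic side;
* `behavior_stats` — maneuver collapsing, serial-run filtering, 10°-binned
  choice ratios with Pearson correlation, 0.2-mm distance histograms, F and
  Student's t comparisons;
* `param_search` — the exhaustive grid search that selected the published
  parameter set, scored against reference summary statistics;
* `synthetic_data` — seeded generators for strip profiles and
  real-worm-style event tables;
* a thin command-line front end (`inst/cli/acidnav.R`) with `simulate`,
  `analyze`, `synth-gradient`, `synth-events` and `grid-search`
  subcommands driven by JSON/YAML configs.

## Worked example

Simulate 3000 model worms with the published optimal parameters
(α_c = 0.5, β_c = 4.3, α_r = 0.5, β_r = 2.7, φ_c = 30°, Δφ_c = 10°,
start below −2 mm) on a gradient running from pH 6 on the far side through
pH 4.0 at the color border down to pH 3 in the acid:

```r
library(acidnav)
field  <- make_parametric_gradient(border_ph = 4, slope = 0.5, span = 6,
                                   far_ph = 6, near_ph = 3)
events <- run_cohort(3000, field, optimal_params(), sim_config(), seed = 1)
bin_choice_ratio(events, width = 10, min_count = 15)
#> <choice_summary> 3000 events
#>  lo hi mid n_reversal n_curve   n reversal_ratio flagged
#>   0 10   5         32     839 871     0.03673938   FALSE
#>  10 20  15         28     840 868     0.03225806   FALSE
#>  20 30  25         23     591 614     0.03745928   FALSE
#>  30 40  35         22     295 317     0.06940063   FALSE
#>  40 50  45         52      58 110     0.47272727   FALSE
#>  50 60  55         38       8  46     0.82608696   FALSE
#>  60 70  65         51       0  51     1.00000000   FALSE
#>  70 80  75         69       0  69     1.00000000   FALSE
#>  80 90  85         54       0  54     1.00000000   FALSE
#> Pearson r = 0.937, p = 0.000191 (bins with < 15 events excluded)
```

The reversal fraction climbs from ~3% at grazing encounter angles to 100%
for head-on encounters, and correlates with the bin midpoint at r = 0.94 —
the model's signature angle-dependent choice, produced without any angle
sensing. `distance_summary(events)` adds the per-maneuver positions of the
recorded events relative to the border:

```r
distance_summary(events)
#> reversal: n = 369, mean = -1.845 mm, SD = 0.487 mm
#> curve: n = 2631, mean = -1.687 mm, SD = 0.441 mm
```

See the vignette (`vignettes/two-threshold-model.Rmd`) for the full model
description, the design decisions, and known limitations.

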