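# neurocascade

Quantitative analysis of adult hippocampal neurogenesis and astrogenesis
from BrdU pulse-and-chase cell counts.

## The problem

Proliferating neuroprogenitors in the dentate gyrus produce both newborn
neurons and newborn astrocytes, and both outputs change with age. The
experiment behind this package labels S-phase progenitors with BrdU and
counts BrdU⁺ cells per hippocampus in independent animal groups at 2 h,
2 d, 4 d, 10 d and 30 d after labelling (the *longitudinal* axis, over
cell life) in mice of 1, 2, 6 and 12 months (the *transversal* axis,
across adulthood). At 30 d, NeuN/GFAP co-labelling splits survivors into
neurons and astrocytes. Because the design is cross-sectional — no cell
is ever observed twice — connecting the 2 h progenitor pool to its 30 d
progeny needs a model. `neurocascade` provides an *end-point* model: all
progenitor subtypes are pooled, and proliferation, apoptosis and
differentiation are collapsed into net survival between timepoints.

## What the package computes

* **Marsaglia polar sampler** (`cascade_rng()`, `polar_pair()`,
  `rng_normal()`, `rng_truncnorm()`): a from-first-principles, seedable
  normal deviate stream (MRG32k3a uniforms, polar transform with
  spare-deviate cache, rejection-sampled truncation).
* **Synthetic data with known truth** (`default_truths()`,
  `generate_dataset()`, `summarize_counts()`): per-animal count tables
  emulating the experimental design, so every downstream stage is
  testable against a planted ground truth.
* **Constrained cohort simulation** (`simulate_cohort()`): nested
  pseudo-animals per age drawn from group means/SDs under the biological
  restrictions `2h ≤ 2d ≥ 4d ≥ 10d ≥ 30d ≥ (GFAP + NeuN)`, with the 30 d
  marker split *locked* (GFAP drawn, NeuN the exact remainder, or vice
  versa); `deviation_from_experiment()` scores the simulation.
* **Decay models** (`fit_plateau_decay()`, `fit_exponential_decay()`,
  `compare_aicc()`): longitudinal decay as
  `Y(t) = P + (Y0 − P)·exp(−K(t − 2))` (half-life `ln 2 / K`, plateau as
  % of the 2 d peak), transversal decay as `Y(x) = Y0·exp(−Kx)`, ranked
  by small-sample-corrected AICc; plus `linear_regression()`,
  `validate_against_curve()` and `split_age_fit()`.
* **Cascade metrics** (`normalize_to_2h()`, `interval_losses()`,
  `yields()`): interval cell loss and the neurogenic/astrogenic yield —
  30 d newborn neurons (astrocytes) per 2 h proliferating progenitor —
  whose quotient is the neuron-to-astrocyte ratio.
* **Extra-survival scenarios** (`decompose_survival()`,
  `find_allocation()`): mature-age 30 d survival decomposed into the
  young-pattern baseline plus an extra component; a midpoint (bisection)
  search finds the neuron share `p` of the extra that reproduces a target
  ratio, cross-checked against the closed form
  `p* = (R(A_b + E) − N_b) / (E(1 + R))`.

Everything is a data-frame-in / tibble-out function; fitted objects have
`tidy()`, `glance()`, `augment()` and `autoplot()` methods, and
`run_full_pipeline()` chains the whole analysis with one seed.

## Worked example

```r
library(neurocascade)

dataset <- generate_dataset(default_truths(), n_per_group = 10, seed = 1)
config  <- pipeline_config(dataset = dataset, n_replicates = 1000, seed = 1)
report  <- run_full_pipeline(config)

report$longitudinal[c("age_months", "half_life", "plateau_pct", "r_squared")]
#> # A tibble: 4 × 4
#>   age_months half_life plateau_pct r_squared
#>        <dbl>     <dbl>       <dbl>     <dbl>
#> 1          1     2.55         10.1      0.998
#> 2          2     1.99         13.8      0.996
#> 3          6     1.07         20.5      1.000
#> 4         12     0.975        28.6      0.999
```

Each row is one age's longitudinal fit: in young mice the labelled
cohort halves roughly every 2–2.5 d and plateaus near 10–14 % of its 2 d
peak; in mature mice the decay is faster (half-life ≈ 1 d) but a larger
fraction (≈ 21–29 %) survives.

```r
report$yields$experimental[c("age_months", "neuronal_yield",
                             "astrocytic_yield", "ratio")]
#> # A tibble: 4 × 4
#>   age_months neuronal_yield astrocytic_yield ratio
#>        <dbl>          <dbl>            <dbl> <dbl>
#> 1          1          0.148           0.0312  4.74
#> 2          2          0.193           0.0430  4.49
#> 3          6          0.210           0.163   1.28
#> 4         12          0.286           0.261   1.10

report$simulation$deviations
#> # A tibble: 2 × 2
#>   strategy    deviation_pct
#>   <chr>               <dbl>
#> 1 gfap-locked          4.36
#> 2 neun-locked          5.05
```

The neuron-to-astrocyte ratio falls from ≈ 4.7 at 1 month to ≈ 1.1 at
12 months — the niche shifts from neurogenic to neuro/astrogenic — and
the GFAP-locked simulation strategy tracks the experimental summaries
more closely than NeuN-locked (4.36 % vs 5.05 % mean deviation), so the
pipeline carries it forward. The `report$scenarios` table then
attributes the mature-age extra survival mostly to astrocytes: at 6 and
12 months the neuron share of the extra survival is ≈ 0.36–0.42, i.e. a
36N:64A to 42N:58A split, under both the experimental and the simulated
target ratios.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full analysis from scratch against the installed package:
it generates the default four-age synthetic world from the given seed,
runs summaries, longitudinal and transversal decay fits, the direct and
constrained Marsaglia simulations under both locked strategies, yield
tables and the extra-survival allocation search, logs the headline
numbers to stderr, and writes the acceptance JSON to `--out`.
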