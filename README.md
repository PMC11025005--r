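# respsel

Trait-based extinction selectivity for fossil occurrence data, built around
the physiology of oxygen transport.

Mass extinctions do not remove taxa at random. During the end-Permian crisis,
marine clades that carry high-capacity respiratory proteins (hemoglobin,
hemocyanin) fared far better — in both survival and post-crisis body size —
than clades that rely on hemerythrin or on simple diffusion of dissolved O₂.
`respsel` packages the statistical machinery needed to quantify that kind of
selectivity from standard paleontological data: delimited occurrence tables
(genus × stage × locality), body-size tables (species maximum lengths), and a
clade-level trait table. It is aimed at paleobiologists and macroevolution
researchers who want a tested, reproducible pipeline rather than one-off
scripts.

## What it computes

**Extinction magnitude and rates.** For the cohort of genera sampled in the
boundary interval, proportional extinction per group with exact
(Clopper–Pearson) or Wilson binomial confidence intervals. On sequences of
four or more stages it also computes the standard sampling-aware rate
estimators from sliding-window occurrence counts (two-timers 2tᵢ,
three-timers 3t, part-timers pt, gap-fillers gf, boundary crossers N_bt,
N_bL):

- per-capita rate: `q = −ln(N_bt / (N_bt + N_bL))`
- three-timer rate: `μ = ln(2tᵢ / 3t) + ln(p_s)` with pooled sampling
  completeness `p_s = Σ3t / (Σ3t + Σpt)`
- gap-filler rate: `μ = ln((2tᵢ + pt) / (3t + pt + gf))`

**Body-size reduction.** Per group, the percent reduction of the median
maximum length across the boundary, `(1 − median_post/median_pre) · 100`,
with a standard deviation from 1,000 bootstrap replicates and a two-sided
Mann–Whitney U test (exact for small untied samples).

**Selectivity regressions.** Group-level OLS of extinction (or size
reduction) on O₂-carrying capacity, and genus-level multiple logistic
regression of extinction status on capacity (continuous rank or 4-level
categorical), log₁₀ geographic range, motility, physiological buffering, a
carbonate-shell flag and log₁₀ occurrence count — with broom-style `tidy()` /
`glance()` methods and `autoplot()` forest plots.

**Synthetic data with known truth.** A generator that simulates clade-
structured genus ranges with group-specific boundary extinction
probabilities, Bernoulli sampling incompleteness, localities with
paleocoordinates, and log-normal size distributions with group-specific
post-boundary median shifts — so every stage of the pipeline can be validated
against ground truth.

## Worked example

```r
library(respsel)
library(dplyr)

# a study-scale synthetic dataset: 13 clades, ~1,100 genera, 6 stages
cfg <- scenario_study_scale(seed = 7)
sim <- generate_occurrences(cfg)

ann <- sim$occurrences |>
  build_genus_summaries(cfg$stages) |>
  assign_traits()

proportional_extinction(ann, group_by = "protein_group")
#> # A tibble: 4 × 7
#>   group       estimator    value ci_low ci_high n_extinct n_total
#> 1 diffusion   proportional 0.945  0.904   0.972       190     201
#> 2 hemerythrin proportional 0.889  0.832   0.932       152     171
#> 3 hemocyanin  proportional 0.795  0.730   0.850       151     190
#> 4 hemoglobin  proportional 0.621  0.529   0.707        77     124
```

Extinction falls monotonically from the diffusion group (94.5%, CI
90.4–97.2%) to the hemoglobin group (62.1%), recovering the generator's true
probabilities (0.93 / 0.90 / 0.80 / 0.65). The group-level regression against
ordinal O₂ capacity:

```r
est <- proportional_extinction(ann, "protein_group") |>
  mutate(o2_capacity = capacity_values()[group])
ols_fit(est, "o2_capacity", "value")
#> <ols_fit> n = 4 | slope = -0.1067, intercept = 0.9725 | R^2 = 0.942, p = 0.02965
```

a negative capacity–extinction slope, as imposed. The genus-level logistic
regression gives per-genus selectivity coefficients on the log-odds scale:

```r
logistic_fit(encode_design(ann, covariates = c("o2_capacity", "n_occurrences"))) |>
  tidy()
#> # A tibble: 3 × 5
#>   term              estimate std.error statistic  p.value
#> 1 (Intercept)          2.42      0.178     13.6  2.42e-42
#> 2 o2_capacity         -0.862     0.129     -6.69 2.26e-11
#> 3 log10_occurrences   -1.50      0.168     -8.93 4.15e-19
```

(one z-scored unit of O₂ capacity cuts the log-odds of extinction by 0.86).
Body size, with species as the sampling unit:

```r
sz <- generate_sizes(cfg)
size_selectivity_table(sz$sizes, cfg$stages, group_by = "protein_group", seed = 1)
#>   group       reduction_pct boot_sd  mwu_p
#> 1 diffusion           39.1     6.80  1.27e-13
#> 2 hemerythrin         43.0     4.28  3.53e-13
#> 3 hemocyanin          -6.14   18.9   7.81e- 1
#> 4 hemoglobin           7.35    9.72  7.64e- 1
```

The low-capacity groups show strong, significant median size reductions; the
high-capacity groups do not (negative values are size increases). Real data
enter through `read_occurrences()`, `read_sizes()` and `read_trait_table()`
(CSV/TSV, configurable column maps, strict or permissive validation), and
`run_pipeline()` drives the whole analysis from one YAML config. A thin
command-line front end with `simulate | extinction | sizes | regress |
report` subcommands lives at `inst/cli/respsel.R`.

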