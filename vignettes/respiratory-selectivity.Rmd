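---
title: "Methods: respiratory-protein extinction selectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respiratory-protein extinction selectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respsel)
library(dplyr)
```

## The scientific question

Across the Permian–Triassic boundary, marine clades differ enormously in how
much diversity and body size they lost. One physiological axis organizes much
of that variation: the oxygen-carrying capacity of a clade's respiratory
system. Animals without any carrier protein (protozoans, sponges, corals)
depend on diffusion of dissolved O₂; brachiopods and bryozoans carry
hemerythrin, a low-capacity pigment; arthropods and most mollusks carry
hemocyanin; and non-protobranch bivalves, echinoderms, conodonts and fish
carry hemoglobin, the highest-capacity carrier. Under the hypoxia and
acidification that accompany a boundary crisis, the capacity to bind and
transport O₂ plausibly decides who starves and who survives — and, among
survivors, who shrinks.

`respsel` operationalizes that hypothesis as a set of estimable quantities:
group-level extinction magnitudes and rates, group-level body-size
reductions, and regressions of both on O₂-carrying capacity and on
confounding covariates (geographic range, motility, physiological buffering,
shell mineralogy, sampling intensity).

The trait assignment rests on phylogenetic bracketing: extinct members of a
clade are assumed to carry the same dominant respiratory protein as its
modern members. The package takes that assumption as given; it ships the
clade→trait mapping as an editable table (`default_trait_table()`,
`inst/extdata/default_traits.csv`) rather than hard-coding it, because some
codings (echinoderm coelomocyte pigments, conodont physiology) are genuinely
debatable.

## Extinction estimators

**Cohort and status.** A genus is *extinct at the boundary* if it occurs at
or before the boundary interval and never after; a *survivor* if it occurs on
both sides; *undefined* if it first appears after the boundary (such genera
are excluded from every extinction tally). The denominator cohort defaults to
the genera actually sampled in the boundary interval — the natural reading of
"extinction of interval-X genera" — with a range-through alternative
(`cohort = "range_through"`) that admits genera whose sampled range spans the
boundary interval without an occurrence inside it. The two differ in how they
treat gappy sampling; both are standard, and the choice is exposed rather
than asserted.

**Proportional extinction** is the cohort fraction extinct, with a binomial
confidence interval. The default method is Clopper–Pearson — exact
Beta-quantile bounds, conservative by construction, matching the usual error
bars in this literature — with the Wilson score interval as an option. Means
over several groups can be unweighted (the average of group proportions,
which is how multi-clade summary percentages are conventionally quoted) or
pooled over genera (`group_mean_extinction()`).

**Sampling-standardized rates.** Proportional extinction conflates true
extinction with failure to sample survivors. On sequences of ≥ 4 intervals
the package computes the three classical counts-based estimators from the
per-interval occurrence-pattern tallies (`tabulate_interval_counts()`):
Foote's per-capita boundary-crosser rate, the completeness-corrected
three-timer rate, and the gap-filler rate (formulas in
`?per_capita_extinction` etc.). These are the canonical literature forms; the
correction factor ln(p_s) uses completeness pooled over all usable intervals.
Sampling noise can push the three-timer and gap-filler estimates below zero;
such values are floored at 0 and *flagged* (attribute `floored`) rather than
dropped, so downstream summaries can see how often the floor binds. With only
two intervals (the minimal boundary design) the rate estimators are
unavailable and the pipeline says so explicitly instead of failing.

## Body-size reduction

The sampling unit is the species' maximum length in mm — maxima avoid
contamination by juveniles — with an optional collapse to genus maxima. Per
group the package reports the percent reduction of the median,
`(1 − median_post/median_pre)·100`, computed on the raw mm scale (log₁₀
medians are reported alongside for audit; a monotone transform does not
change which species is the median, but the percent reduction is defined on
raw lengths). Uncertainty comes from 1,000 bootstrap replicates, resampling
the pre- and post-boundary cohorts *independently* (they are distinct faunas,
so pairing would be artificial) at their own sizes; the reported `boot_sd` is
the SD of the replicate reductions. Significance uses the two-sided
Mann–Whitney U test: exact by full enumeration of the U distribution when
`n_pre · n_post ≤ 400` and there are no ties, otherwise the normal
approximation with midranks, tie correction and continuity correction.

Seeding is hierarchical: one pipeline seed deterministically spawns an
independent substream per group (keyed by the group label), so adding or
removing a group never changes any other group's bootstrap SD.

## Selectivity regressions

Two complementary fits:

1. **Group-level OLS** of a group outcome (extinction proportion, size
   reduction) on the groups' O₂ capacities. Unweighted by default — each
   group is one point, mirroring how such scatter regressions are drawn —
   with group-size weights as an option. `ols_fit()` reports slope, R², and
   the two-sided t-test p for the slope (n − 2 df).
2. **Genus-level multiple logistic regression** of extinction status (0/1)
   on covariates, fitted by IRLS (Newton-type ascent of the binomial
   log-likelihood) with Wald standard errors from the inverse observed
   information. Capacity enters either as a continuous (ordinal by default)
   value or as a 4-level categorical with the diffusion group as reference —
   both first-class, since they answer slightly different questions (trend
   vs. group contrasts).

Design encoding (`encode_design()`): continuous covariates are z-scored so
coefficients are comparable effect sizes; geographic range enters as log₁₀
(range distributions are right-skewed); occurrence counts as log₁₀(n + 1) for
the same reason (the +1 guards single-occurrence genera); motility, buffering
and the carbonate-shell flag are 0/1. Genera with undefined extinction status
are excluded. Reported p-values are per-coefficient Wald tests with no
multiple-testing correction, which is the convention for this kind of
selectivity table; the report footer of `selectivity_report()` uses the usual
marks (*** p < 0.001, ** p < 0.01, NS).

Numerical care: complete or quasi-complete separation is detected (degenerate
fitted probabilities or runaway coefficients) and sets `converged = FALSE`;
`tidy()` then refuses to print estimates unless explicitly overridden.
Covariates that are constant in the data are dropped with a warning, and
perfectly collinear (aliased) columns are dropped with a warning and the
model refitted — this happens naturally when trait codings coincide at clade
level (e.g. motility and buffering over a clade set where the two agree),
and silently reporting NA coefficients would be worse. Genera are treated as
exchangeable; there is no phylogenetic or clade-random-effect correction,
which is a known limitation (clade-level traits are pseudo-replicated across
their genera, so logistic p-values are anticonservative for clade-level
hypotheses).

**O₂-capacity values.** The only property of capacity that is safely
portable across datasets is the ranking diffusion < hemerythrin < hemocyanin
< hemoglobin (carrier concentrations and Hill coefficients vary within
groups). The default is therefore the ordinal coding 0–3; quantitative values
can be supplied via `capacity_values("custom", ...)`, which rejects any
mapping that violates the ranking.

**Geographic range** defaults to the count of distinct localities (usable
without coordinates, log₁₀-transformed in regressions); the maximum pairwise
great-circle distance (spherical Earth, R = 6371 km) is available when
paleocoordinates exist. Which operationalization best matches published
range covariates is usually unknowable from a methods section, so both are
exposed and neither is privileged.

## The synthetic-data generator

`sim_config()` / `generate_occurrences()` / `generate_sizes()` provide the
ground truth that validates everything else. The model:

- **Ranges.** Each genus originates uniformly among the pre-boundary
  intervals (a configurable fraction originates after the boundary, to
  exercise cohort exclusion), survives each background interval boundary
  with probability 1 − `bg_extinction` (default 0.1), and survives the focal
  boundary with probability 1 − π_g, where π_g is its protein group's
  extinction probability.
- **Sampling.** True presences are thinned by i.i.d. Bernoulli(r) per
  (genus, interval) — `sampling_prob`, default 0.8, a realistic
  per-stage sampling rate for well-studied boundary sections. The sampling
  uniforms are drawn on the full true-presence grid before thinning, so
  lowering r under a fixed seed removes occurrences monotonically.
- **Localities.** Sampled presences receive 1–3 localities from a shared
  pool with uniform paleocoordinates.
- **Sizes.** Species maxima are log-normal per clade; the post-boundary
  cohort's meanlog is shifted by ln(m_g), so the true median reduction is
  (1 − m_g)·100%.

`scenario_study_scale()` bundles a realistic study-scale configuration:
13 clades, ~1,100 genera, ~1,500 size species, extinction probabilities
0.93/0.90/0.80/0.65 ordered against capacity, and size multipliers
0.5/0.55/0.9/0.97. These are illustrative ground truths chosen to resemble
the magnitude ordering reported for the end-Permian crisis — they are inputs
to validation, not estimates of it.

What the generator deliberately does **not** emulate: spatially clustered
sampling (occurrences thin independently per genus-interval, whereas real
sampling fails by locality and by region); correlated trait evolution or
within-clade trait variation; stage-duration differences (all intervals are
exchangeable time bins); facies and taphonomic biases that covary with
mineralogy; and ontogenetic or within-lineage size change. Passing the
recovery tests therefore shows the *estimators* are correct and calibrated
under honest sampling noise — it does not show that real occurrence data
satisfy these estimators' assumptions.

## Validation performed by the test suite and acceptance script

All of the following are computed, not asserted: interval counts and all
three rate estimators agree exactly with exhaustive per-taxon scans of random
presence matrices; with perfect sampling, three-timer and gap-filler rates
collapse onto the per-capita rate; Clopper–Pearson 95% intervals cover a
true proportion of 0.9 (n = 50) in ≥ 95% of 1,000 draws; group extinction
probabilities 0.95/0.90/0.85/0.65 (300 genera/group, sampling 0.8) are
recovered inside their own CIs with a negative capacity slope in ≥ 95% of 50
replicates; imposed median size reductions of 0/20/50% are recovered within
3 percentage points on average over 100 replicates and the bootstrap SD
agrees with an outer Monte-Carlo SD within 25%; the Mann–Whitney test has
5% ± 1.5% type-I error at n = 30 vs 30 and matches full enumeration exactly
for small samples; and the logistic fit reproduces the closed-form 2×2 log
odds ratio to 1e−8, matches an independent coordinate-search likelihood
maximizer to 1e−4 in log-likelihood, and covers true coefficients within
±2 SE in ≥ 93% of recovery simulations. Problem sizes (e.g. 2,000 genera for
the estimator-consistency check, 100 replicates for recovery means) were
chosen as the smallest scales at which the asymptotic statements being tested
are expected to hold with comfortable margin.

## Defaults at a glance

| Parameter | Default | Why |
|---|---|---|
| CI method | Clopper–Pearson, 95% | exact, conservative; field convention |
| Cohort rule | boundary-interval occupancy | matches "interval-X genera" tallies |
| Capacity coding | ordinal 0–3 | ranking is the only portable property |
| Geographic range | n distinct localities | needs no coordinates |
| Bootstrap B | 1,000 | SD of the replicate distribution stabilizes well below this |
| Bootstrap unit | species, unpaired cohorts | distinct faunas; maxima exclude juveniles |
| MWU exact threshold | n₁·n₂ ≤ 400, no ties | exact where cheap, corrected normal otherwise |
| Occurrence transform | log₁₀(n+1), z-scored | right-skewed counts |
| Sampling probability (sim) | 0.8 per interval | realistic completeness for boundary sections |
| Background turnover (sim) | 0.1 per boundary | keeps ranges multi-interval without swamping the focal signal |

## Known limitations

- Extinction status is censored at the edge of the stage sequence: a genus
  surviving past the last interval is indistinguishable from one dying there.
- Clade-level traits pseudo-replicate across genera; logistic inference about
  trait effects is conditional on the exchangeability assumption.
- The rate estimators assume time-homogeneous sampling within the window;
  strong secular sampling trends bias the completeness correction.
- No origination-side statistics, diversity curves, or subsampling
  standardization — the package is deliberately extinction-side only.
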