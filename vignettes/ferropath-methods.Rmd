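---
title: "Statistical methods behind ferropath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind ferropath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ferropath)
```

ferropath implements the cohort-level statistics of a four-cohort,
three-region autopsy study of TDP-43 proteinopathy and its ferritin
(brain-iron) correlate. This vignette explains the statistical model,
the tunable parameters, what the synthetic-data generator does and does
not emulate, and the numerical and design choices that were genuinely
open.

## The study design and data model

Each autopsy case belongs to one of four cohorts — controls under 60,
controls 60 and over, Alzheimer's disease (AD), amyotrophic lateral
sclerosis (ALS) — and contributes three records, one per brain region
(amygdala, hippocampus, frontal cortex). Per record: a pathologist's
binary TDP-43 pathology call, a binary cryptic-exon in-situ
hybridisation readout (a TDP-43 loss-of-function marker), and two
continuous stain burdens, TDP-43 and ferritin, as mean DAB optical
densities in arbitrary units. Intensities may be missing; missingness
is never coerced to zero. Validation (`as_cohort_records()`) enforces
the age/cohort consistency (under-60 means death before 60), the fixed
region vocabulary, and non-negative intensities.

Descriptive summaries use the sample SD (n − 1) and quantiles by linear
interpolation between order statistics at position 1 + (n − 1)q (R's
default type 7). This convention was chosen because it reproduces the
published interquartile ranges for these cohorts exactly at 1 decimal
place; the common type-6 convention does not. With n = 1 the SD is
reported missing rather than zero. With n = 2 a quartile convention is
essentially arbitrary; we report type-7 values and do not attach
significance to them.

## Prevalence inference

Small denominators (10–19 per cohort) and boundary counts (0/19, 9/10,
10/10) make plain Wald intervals useless here. Two pseudo-count methods
carry the prevalence analysis:

* **Agresti–Coull interval.** The sample is inflated by z² pseudo-
  observations (z = 1.959964 at the 95% level, the exact normal
  quantile rather than the rounded 1.96 — both reproduce the published
  bounds at 1 dp, but the exact quantile is the documented constant).
  Interval bounds are clamped to [0, 1] *after* construction; the clamp
  is required to reproduce published upper bounds of 100% at counts
  like 9/10.
* **Agresti–Caffo test.** For a difference of two proportions, one
  success and one failure are added to each group and the Wald z is
  computed from the adjusted proportions. The two-sided p-value is
  normal. This test is implemented from its definition; it has no
  implementation in standard R packages.

Fold changes between cohorts are ratios of the **unadjusted** sample
proportions — using the adjusted proportions would not reproduce the
published 2.7- and 4.5-fold values from their own counts. The adjusted
proportions exist only inside the z statistic. A zero reference
proportion makes the ratio undefined; `fold_change()` returns an `Inf`
marker rather than a number.

Cohort-level positivity is defined as pathology in at least one region;
this is the definition under which the cohort counts and the region
marginals are mutually consistent. Co-pathology is tabulated over all
2³ region patterns; marginal counts are *derived* from the pattern
counts, so the marginal identity is structural rather than re-counted.

One published statistic is not reproducible from its stated counts: the
hippocampus cohort contrast prints z = 3.445 where the formula on
10/14 vs 3/19 gives 3.4487. We compute the formula value and do not
special-case it; the package reports whatever the input counts imply.

## Assumption gating and group comparisons

Continuous comparisons are screened first: Shapiro–Wilk per group and
the median-centred (Brown–Forsythe) Levene test across groups — a
one-way ANOVA on absolute deviations from group medians. If any group
fails normality at the screening level (0.05), *all* cohort comparisons
switch to rank-based tests, a deliberately conservative all-or-nothing
rule that mirrors how such cohort studies keep their reporting
consistent. The gate can also be forced by configuration.

The rank-based track is Kruskal–Wallis (tie-corrected H) followed by
Dunn's post-hoc z from the pooled rank distribution,

$$z_{ij} = \frac{\bar R_i - \bar R_j}
  {\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum_t (t^3-t)}{12(N-1)}\right)
  \left(\frac{1}{n_i}+\frac{1}{n_j}\right)}},$$

Bonferroni-adjusted over all k(k−1)/2 pairs and capped at 1 (displayed
as 1.000, resolving the "p > 0.999" vs "1" display inconsistency in
favour of the cap). Average ranks are used everywhere; tie corrections
enter both the H statistic and the Dunn standard error. A fully
degenerate Kruskal–Wallis input (all values identical) returns H = 0,
p = 1 by convention rather than the 0/0 of the tie correction.

Categorical balance uses Pearson chi-square without continuity
correction at any table size — the correction is togglable but off by
default, because the uncorrected statistic is what the published
sex-balance values (3.189 on 1 df, 2.695 on 3 df) correspond to.
Fisher's exact test covers small expected counts, with p = 1 by
convention for degenerate margins.

## The permutation framework

Where Dunn's test is unsuitable, pairwise comparisons use group-label
permutation. Two genuinely open choices were resolved as follows:

* **The carried statistic.** The framework's statistic is not pinned
  down by convention; we default to the difference in group means (the
  linear two-sample statistic a permutation framework typically
  standardises) and expose a median-difference option.
* **The p-value estimator.** p is the plain proportion of permutations
  with |T*| ≥ |t_obs| among B draws, so p = 0 is possible at extreme
  separations; an add-one smoothed variant is available by flag but off
  by default, keeping the plain proportion as the stated definition.

When the number of distinct label arrangements is at most B, the null
is enumerated exhaustively (`exact = "auto"`), making small-sample
p-values deterministic. The sampled path takes an explicit seed and
leaves the global RNG untouched. Cliff's delta accompanies every
permutation comparison as the effect size: the normalised excess of
between-group pair orderings, with ties contributing zero.

**Engine selection.** The published analyses route some comparisons
(amygdala ferritin) to permutation and keep others (hippocampus,
frontal cortex) with Dunn, without stating a cutoff. We operationalise
"unsuitable due to tied values or nearly identical rank distributions"
as: permutation when the proportion of pooled observations sharing
their value with another observation strictly exceeds a threshold
(default 0.50, configurable since no published cutoff exists), or when
any two groups have exactly equal rank sums; at exactly the threshold
Dunn is kept. This is our formalisation, and it is the one part of the
pipeline that is a reconstruction rather than a re-implementation.

## The regression panel

Per cohort × region cell, TDP-43 burden is regressed on ferritin burden
by simple OLS on pairwise-complete cases. Direction matters: ferritin
is the predictor and TDP-43 the outcome, following the analysis
description and the figure axes (one published table header reverses
the roles; F and R² are direction-invariant in simple OLS, the slope is
not, and we follow the stated modelling direction). Reported per cell:
slope, SE, t, F on (1, n − 2), the F-tail p, R², adjusted R², and the
slope interval. `adjusted_r2_from_f()` inverts a published (F, df) pair
to the adjusted R² a fit would report, which is how the panel's
R²-from-F consistency is tested. Cells with fewer than 3 complete pairs
or a constant predictor are emitted as skipped rows with a reason. No
multiple-testing adjustment is applied across the 12 cells, matching
the original reporting.

## Stain quantification

The burden scores that feed the regressions come, in the original
workflow, from superpixel analysis in a digital-pathology tool. The
package re-implements the measurement contract in simplified form:

1. RGB → optical density, OD = −log₁₀(max(I, 1)/background), base 10,
   white level 255 by default;
2. least-squares projection of each OD pixel onto a two-stain basis
   (default: the standard Ruifrok–Johnston haematoxylin and DAB unit
   vectors), negative DAB concentrations clamped to zero;
3. regular-grid tiles (default 32 px) stand in for superpixels; tiles
   with mean total OD below 0.05 are treated as background; the score
   is the mean over tissue tiles of the tile-mean DAB concentration.

The grid is a deliberate simplification: the original tool's
superpixel segmentation parameters are not restated in the publication
chain, and a regular grid preserves the mean-intensity contract (and
the rotation/traversal invariances) without pretending to reproduce an
uncalibrated segmentation. Scores are in dimensionless OD units; they
are comparable within a study, not across scanners.

## The synthetic cohort generator

No individual-level data are deposited with studies of this kind, so
the generator is the package's test bed. Its defaults *are* the study
conditions: cohort sizes (19, 14, 10, 10) with sex splits (6/13, 5/9,
3/7, 6/4 F/M); age ranges 40–59, 60–74, 69–84, 61–80 (the published
range tables contain two typos — "40–49" for a cohort defined up to 59,
"69–94" against a stated study maximum of 84 — resolved in favour of
the cohort definitions); per-cell pathology prevalences equal to the
published point prevalences; and linkage slopes among pathology-positive
cases equal to the published per-cell regression estimates.

Choices the publication does not determine, fixed once:

* **Age distribution**: uniform on the cohort range, rounded to whole
  years (only ranges and medians are published, not shapes); a
  truncated-normal option would be a sensitivity extension, not a
  default.
* **Ferritin scale**: arbitrary units, means 1.0–1.6 ordered
  qualitatively like the published group comparisons (disease above
  ageing, AD hippocampus highest), common SD 0.35. No attempt is made
  to match unlabeled published axis scales.
* **Residual SDs**: back-calculated per cell so the population R²
  equals the R² implied by the published cell F statistic,
  σ = |β|·s_x·√((1−R²)/R²).
* **Intercepts**: set high enough above 4σ that the non-negativity
  clamp on intensities is essentially never active, keeping the linear
  model exact in practice.
* **Region dependence**: statuses are independent Bernoulli(π) per
  region by default; a `copathology_dependence` knob drives all three
  regions from one shared latent uniform to generate co-pathology
  patterns. Published pattern decompositions for two cohorts conflict
  with their own printed marginals; the default configuration uses the
  printed marginal prevalences.

What the generator does **not** emulate: age–pathology dependence
within cohort (prevalence is constant per cell, not rising in age),
correlation between ferritin level and pathology status, co-occurring
proteinopathies, and any image-level realism beyond the demo tile
builder. Consequently, passing tests demonstrate that the machinery is
correct and calibrated under the declared generating model — not that
the biological conclusions transfer to new tissue.

The deterministic fixture builder `cohort_from_patterns()` complements
the stochastic generator: it lays down exact region-pattern counts so
published prevalence tables and upset decompositions are reproduced
exactly in tests and in the acceptance script.

## Numerical choices and degenerate inputs

* Exact normal quantiles throughout; no rounded critical values.
* Interval clamping after construction; adjusted proportions never
  leak into fold changes.
* Permutation extremeness uses a 1e-12 absolute tolerance on
  |T*| ≥ |t_obs| to keep exhaustive enumeration stable under floating
  point.
* Display rounding (percentages and bounds to 1 dp, z to 4 dp) lives
  in `format_prevalence()` and the report layer only; full precision is
  retained in every returned tibble.
* Degeneracies are conventions, not errors, wherever a convention is
  defensible: H = 0/p = 1 for constant Kruskal–Wallis input, p = 1 for
  empty-margin Fisher tables, skipped-with-reason rows in the
  regression panel, missing SD at n = 1, missing burden score for a
  tissue-free image. Hard errors are reserved for contract violations
  (unknown labels, negative intensities, x > n).

## Problem sizes used in the checks

The simulation-based checks run at sizes chosen to give stable Monte
Carlo estimates while keeping the default suite quick: 2,000 draws for
interval coverage and type-I error (binomial SE ≈ 0.5 pp), 1,000
replicates for slope-interval coverage, 500 for power checks, and 100
random fixtures (B = 50,000) for the sampled-vs-exhaustive permutation
equivalence. Coverage bands in the tests are the corresponding
nominal-rate bands (e.g. 4–6% for a 5% test over 2,000 draws).

## Known limitations

* The tie-proportion engine-selection rule is a formalisation of an
  informally described practice; the original routing criterion is not
  recoverable from the publication.
* The generator's independence assumptions (above) bound what the
  end-to-end tests can certify.
* Grid superpixels are not SLIC superpixels; absolute burden scores
  will differ from the original tool even on identical images, though
  both estimate the same tissue-mean DAB OD.
* One published z statistic (3.445) and one fold/z pair in the AD
  amygdala contrast are not reproducible from their stated counts; the
  package computes from inputs and does not emulate unexplained
  values.
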