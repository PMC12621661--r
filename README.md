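# ferropath

Cohort-level statistical analysis of regional TDP-43 brain pathology and
its association with ferritin (a tissue proxy for brain iron) across
ageing and neurodegenerative disease.

## The problem

TDP-43 proteinopathy is a hallmark of ALS and frontotemporal dementia, is
common in Alzheimer's disease (AD), and occurs in neurologically normal
ageing. A typical autopsy study of this design scores three vulnerable
brain regions — amygdala, hippocampus, frontal cortex — for the binary
presence of pathological TDP-43 in four small cohorts (controls under 60,
controls 60 and over, AD, ALS), and quantifies continuous TDP-43 and
ferritin stain burdens per region. The statistical questions are:

* **Prevalence.** What fraction of each cohort carries pathology per
  region, with intervals that behave sensibly at n = 10–19 and
  boundary counts like 9/10 or 0/19?
* **Cohort contrasts.** Is pathology more frequent in one cohort than
  another, and by how much?
* **Group comparisons.** Do continuous measures (age, ferritin burden)
  differ across cohorts, given small samples and frequent ties?
* **Biomarker value.** How much regional TDP-43 burden does regional
  ferritin explain?

ferropath packages that analysis for reuse: small-sample binomial
inference, assumption-gated group comparisons, a per-cohort, per-region
regression panel, simplified DAB stain quantification, and a synthetic
cohort generator so the whole pipeline is testable without restricted
individual-level autopsy data.

## Methods at the core

* **Agresti–Coull (modified Wald) intervals** for a proportion x/n: with
  z the exact 0.975 normal quantile, ñ = n + z², p̃ = (x + z²/2)/ñ, the
  95% interval is p̃ ± z·√(p̃(1−p̃)/ñ), clamped to [0, 1]
  (`agresti_coull_ci()`).
* **Agresti–Caffo two-proportion z-test**: add one success and one
  failure per group, p̃ᵢ = (xᵢ+1)/(nᵢ+2), then
  z = (p̃₁ − p̃₂)/√(p̃₁(1−p̃₁)/(n₁+2) + p̃₂(1−p̃₂)/(n₂+2)) with a two-sided
  normal p-value and Wald interval for the difference
  (`agresti_caffo_test()`). Implemented from the definition — this test
  has no standard R implementation. Fold changes are ratios of the
  *unadjusted* sample proportions (`fold_change()`).
* **Assumption-gated comparisons**: Shapiro–Wilk per group and
  median-centred (Brown–Forsythe) Levene screening
  (`choose_test_strategy()`); Welch t, Wilcoxon rank-sum,
  Kruskal–Wallis, and Dunn's post-hoc z from the pooled tie-corrected
  rank distribution with Bonferroni correction (`dunn_posthoc()`).
* **Permutation framework**: where Dunn is unsuitable (heavy ties,
  identical rank sums), pairwise group-label permutation tests
  (p = #{|T*| ≥ |t_obs|}/B, exhaustive when the arrangement count fits
  in B) with Cliff's delta effect sizes (`permutation_test()`,
  `cliffs_delta()`, `select_pairwise_engine()`).
* **Regression panel**: per cohort × region, OLS of TDP-43 burden on
  ferritin burden with slope, SE, F on (1, n−2), and adjusted R²
  (`ols_fit()`, `regression_panel()`, `adjusted_r2_from_f()`).
* **Stain quantification**: optical density transform, H-DAB colour
  deconvolution, and grid-superpixel mean DAB burden scoring
  (`rgb_to_od()`, `deconvolve_dab()`, `superpixel_burden()`).

All user-facing functions take data frames first and return tibbles;
fitted objects have `tidy()`/`glance()` methods and result tables have
`autoplot()` methods.

## Worked example

Simulate a study with the default (publication-structured) configuration,
run the full pipeline, and read off the key tables:

```r
library(ferropath)

sim    <- generate_cohort(default_study_config(), seed = 42)
report <- run_analysis(analysis_config(sim$records, seed = 42, B = 2000))

format_prevalence(report$prevalence_by_cohort)[,
  c("cohort", "x", "n", "pct", "pct_lower", "pct_upper")]
#>   cohort      x     n   pct pct_lower pct_upper
#> 1 under60    10    19  52.6      31.7      72.7
#> 2 over60     13    14  92.9      66.5     100
#> 3 AD          9    10  90        57.4     100
#> 4 ALS        10    10 100        67.9     100
```

Each row is the cohort's TDP-43 pathology prevalence (positive in at
least one region) with its Agresti–Coull 95% interval on the percent
scale — note the boundary behaviour at 10/10, where the upper bound
clamps to 100. The age structure behaves like the real design
(`report$age_comparison`: Kruskal–Wallis χ² = 40.8, df = 3, p < 0.001,
with Dunn pairs separating the under-60 cohort from the three older
ones). Comparing pathology incidence between the ageing cohorts with the
published counts:

```r
agresti_caffo_test(12, 14, 6, 19)[, c("z", "p_two_sided", "fold")]
#>       z p_two_sided  fold
#>  3.3795      0.0007 2.714
```

i.e. a 2.7-fold higher incidence in the over-60 cohort, z = 3.3795,
p < 0.001. The regression panel (`report$regression_panel`, 12 rows)
shows the strong ferritin–TDP-43 coupling in the fully affected ALS
cells — e.g. amygdala slope 0.905 (SE 0.102), F(1, 8) = 79.4, adjusted
R² = 0.897 in this draw — and near-null slopes in the sparsely affected
under-60 cells. `autoplot(report$regression_panel)` draws the forest
plot; `autoplot(report$prevalence_by_cohort)` the prevalence intervals.

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/ferropath.R simulate --seed 17 --out study.csv
Rscript inst/scripts/ferropath.R run --input study.csv --out results/
```

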