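Package: ferropath
Title: Regional TDP-43 Pathology Prevalence and Ferritin Association Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cohort-level statistical analysis of regional TDP-43 brain
    pathology across ageing and neurodegenerative disease cohorts. Implements
    small-sample binomial prevalence inference (Agresti-Coull modified Wald
    intervals, Agresti-Caffo two-proportion z-tests, prevalence fold changes),
    assumption-gated group comparisons (Shapiro-Wilk and median-centred Levene
    screening, Welch t, Wilcoxon, Kruskal-Wallis with Dunn-Bonferroni
    post-hocs, label-permutation tests with Cliff's delta), a per-cohort,
    per-region ordinary least-squares panel linking ferritin to TDP-43 stain
    burden, simplified DAB optical-density stain quantification, and a
    synthetic cohort generator so the full pipeline is testable without
    access to individual-level autopsy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    png,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
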