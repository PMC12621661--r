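# Shared fixtures built in code.

# The 18 ages at death of pathology-positive control individuals, as
# enumerated in the cohort description (six under-60 cases, twelve 60+).
positive_control_ages <- c(40, 44, 46, 50, 50, 57,
                           61, 61, 63, 65, 67, 69, 69, 71, 71, 72, 73, 74)

# Upset-pattern decomposition of pathology per cohort: exact region
# combinations so prevalence and co-pathology counts are deterministic.
# Cohort-level positives: under60 6/19, over60 12/14, AD 9/10, ALS 10/10.
study_patterns <- list(
  under60 = list(
    list(regions = "hippocampus", count = 2),
    list(regions = "frontal_cortex", count = 2),
    list(regions = c("amygdala", "frontal_cortex"), count = 1),
    list(regions = c("amygdala", "hippocampus", "frontal_cortex"), count = 1),
    list(regions = character(0), count = 13)
  ),
  over60 = list(
    list(regions = "hippocampus", count = 5),
    list(regions = "amygdala", count = 2),
    list(regions = c("hippocampus", "frontal_cortex"), count = 4),
    list(regions = c("amygdala", "hippocampus", "frontal_cortex"), count = 1),
    list(regions = character(0), count = 2)
  ),
  AD = list(
    list(regions = c("amygdala", "hippocampus", "frontal_cortex"), count = 4),
    list(regions = c("amygdala", "hippocampus"), count = 4),
    list(regions = "hippocampus", count = 1),
    list(regions = character(0), count = 1)
  ),
  ALS = list(
    list(regions = c("amygdala", "hippocampus", "frontal_cortex"), count = 9),
    list(regions = c("amygdala", "hippocampus"), count = 1)
  )
)

study_fixture <- function() cohort_from_patterns(study_patterns)

# A small 3-case long table with one missing intensity, for IO round trips.
tiny_table <- function() {
  tibble::tibble(
    case_id = rep(c("c1", "c2", "c3"), each = 3),
    cohort = rep(c("under60", "over60", "ALS"), each = 3),
    sex = rep(c("F", "M", "M"), each = 3),
    age_at_death = rep(c(45L, 68L, 70L), each = 3),
    region = rep(region_levels(), 3),
    tdp43_status = c(0L, 1L, 0L, 1L, 1L, 0L, 1L, 1L, 1L),
    tdp43_intensity = c(0.1, 0.9, NA, 1.2, 1.4, 0.2, 2.0, 1.8, 1.5),
    ferritin_intensity = c(1.0, 1.1, 0.9, NA, 1.6, 1.2, 1.8, 1.4, 1.7),
    hdgfl2_status = c(0L, 1L, NA, 1L, 1L, 0L, 1L, 1L, 1L)
  )
}
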