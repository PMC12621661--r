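# Data model and CSV ingestion for the four-cohort, three-region design.
#
# The tidy representation is one row per case x region ("long" format):
#   case_id, cohort, sex, age_at_death, region, tdp43_status,
#   tdp43_intensity, ferritin_intensity, hdgfl2_status
# Intensities are mean DAB optical densities (arbitrary units, >= 0) and may
# be missing (NA); missingness is never conflated with zero.

ferro_cols <- c(
  "case_id", "cohort", "sex", "age_at_death", "region",
  "tdp43_status", "tdp43_intensity", "ferritin_intensity", "hdgfl2_status"
)

#' Validate a per-individual, per-region cohort table
#'
#' Enforces the canonical vocabularies and study invariants on a long-format
#' table (one row per case x region): cohort, sex and region tokens must be
#' known; `under60` cases must have died before age 60 and `over60` cases at
#' 60 or later; every case must carry exactly the three canonical regions;
#' pathology and cryptic-exon statuses are 0/1 (the latter may be missing);
#' intensities are non-negative or missing.
#'
#' @param data A data frame in long format.
#' @param strict If `TRUE`, duplicated case x region rows are an error;
#'   otherwise a warning (first occurrence kept).
#' @param label_map Named character vector mapping accepted cohort spellings
#'   to canonical labels; see [default_label_map()].
#' @return A validated tibble with `cohort`, `sex` and `region` as factors on
#'   the canonical levels, ordered by cohort, case and region.
#' @export
as_cohort_records <- function(data, strict = FALSE,
                              label_map = default_label_map()) {
  data <- as_tibble(data)
  missing_cols <- setdiff(ferro_cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  data <- data[ferro_cols]

  bad_row <- function(what, rows) {
    abort(sprintf("%s in row(s): %s", what,
                  paste(head(rows, 5L), collapse = ", ")))
  }

  cohort_raw <- as.character(data$cohort)
  unknown <- which(!cohort_raw %in% names(label_map))
  if (length(unknown) > 0) {
    bad_row(sprintf("unknown cohort token '%s'", cohort_raw[unknown[1]]),
            unknown)
  }
  data$cohort <- factor(unname(label_map[cohort_raw]), levels = ferro_cohorts)

  sex_raw <- as.character(data$sex)
  unknown <- which(!sex_raw %in% c("F", "M"))
  if (length(unknown) > 0) {
    bad_row(sprintf("unknown sex token '%s'", sex_raw[unknown[1]]), unknown)
  }
  data$sex <- factor(sex_raw, levels = c("F", "M"))

  region_raw <- as.character(data$region)
  unknown <- which(!region_raw %in% ferro_regions)
  if (length(unknown) > 0) {
    bad_row(sprintf("unknown region token '%s'", region_raw[unknown[1]]),
            unknown)
  }
  data$region <- factor(region_raw, levels = ferro_regions)

  data$age_at_death <- as.integer(data$age_at_death)
  bad_age <- which(is.na(data$age_at_death) | data$age_at_death < 0)
  if (length(bad_age) > 0) bad_row("missing or negative age_at_death", bad_age)

  young_bad <- which(data$cohort == "under60" & data$age_at_death >= 60)
  if (length(young_bad) > 0) {
    bad_row("cohort 'under60' requires age_at_death < 60", young_bad)
  }
  old_bad <- which(data$cohort == "over60" & data$age_at_death < 60)
  if (length(old_bad) > 0) {
    bad_row("cohort 'over60' requires age_at_death >= 60", old_bad)
  }

  for (col in c("tdp43_status", "hdgfl2_status")) {
    v <- data[[col]]
    bad <- which(!is.na(v) & !v %in% c(0, 1))
    if (length(bad) > 0) bad_row(sprintf("%s must be 0/1", col), bad)
    data[[col]] <- as.integer(v)
  }
  bad <- which(is.na(data$tdp43_status))
  if (length(bad) > 0) bad_row("tdp43_status must not be missing", bad)

  for (col in c("tdp43_intensity", "ferritin_intensity")) {
    v <- as.numeric(data[[col]])
    bad <- which(!is.na(v) & v < 0)
    if (length(bad) > 0) bad_row(sprintf("negative %s", col), bad)
    data[[col]] <- v
  }

  dup <- duplicated(data[c("case_id", "region")])
  if (any(dup)) {
    if (strict) bad_row("duplicate case_id x region", which(dup))
    warn(sprintf("dropping %d duplicate case_id x region row(s)", sum(dup)))
    data <- data[!dup, ]
  }

  # every case carries exactly the three canonical regions
  per_case <- table(data$case_id)
  incomplete <- names(per_case)[per_case != length(ferro_regions)]
  if (length(incomplete) > 0) {
    abort(sprintf("case(s) without exactly one row per region: %s",
                  paste(head(incomplete, 5L), collapse = ", ")))
  }
  # cohort/sex/age constant within case
  const <- dplyr::summarise(
    dplyr::group_by(data, .data$case_id),
    ok = dplyr::n_distinct(.data$cohort) == 1L &
      dplyr::n_distinct(.data$sex) == 1L &
      dplyr::n_distinct(.data$age_at_death) == 1L,
    .groups = "drop"
  )
  if (!all(const$ok)) {
    abort(sprintf("case(s) with inconsistent cohort/sex/age across regions: %s",
                  paste(head(const$case_id[!const$ok], 5L), collapse = ", ")))
  }

  dplyr::arrange(data, .data$cohort, .data$case_id, .data$region)
}

#' Read a cohort table from CSV
#'
#' Reads either the long format (one row per case x region, columns
#' `case_id, cohort, sex, age_at_death, region, tdp43_status, tdp43_intensity,
#' ferritin_intensity, hdgfl2_status`) or a wide format (one row per case with
#' region-suffixed columns such as `tdp43_status_amygdala`), then validates it
#' with [as_cohort_records()]. Empty cells are read as missing values.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict Passed to [as_cohort_records()].
#' @param format `"long"` (default) or `"wide"`.
#' @param label_map Cohort label mapping; see [default_label_map()].
#' @return A validated long-format tibble.
#' @export
load_cohort_table <- function(path, strict = FALSE,
                              format = c("long", "wide"),
                              label_map = default_label_map()) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         na = c("", "NA"), progress = FALSE)
  if (format == "wide") raw <- pivot_cohort_long(raw)
  as_cohort_records(raw, strict = strict, label_map = label_map)
}

pivot_cohort_long <- function(wide) {
  value_cols <- c("tdp43_status", "tdp43_intensity", "ferritin_intensity",
                  "hdgfl2_status")
  tidyr::pivot_longer(
    wide,
    cols = tidyr::matches(paste0(
      "^(", paste(value_cols, collapse = "|"), ")_(",
      paste(ferro_regions, collapse = "|"), ")$"
    )),
    names_pattern = paste0(
      "^(", paste(value_cols, collapse = "|"), ")_(.*)$"
    ),
    names_to = c(".value", "region")
  )
}

#' Write a cohort table to CSV
#'
#' Writes the long format read back by [load_cohort_table()]; missing
#' intensities and statuses become empty cells, so a write/load round trip is
#' lossless.
#'
#' @param records Validated long-format records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(records, path) {
  out <- dplyr::mutate(
    records,
    dplyr::across(c("cohort", "sex", "region"), as.character)
  )
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Descriptive age summary
#'
#' Mean/SD (sample SD, n - 1 denominator) and median with quartiles computed
#' by linear interpolation between order statistics at position
#' `1 + (n - 1) q` (the convention that reproduces published interquartile
#' ranges for these cohorts). With a single observation the SD is reported as
#' missing.
#'
#' @param ages Numeric vector of ages at death (years), length >= 1.
#' @return One-row tibble with `n`, `age_mean`, `age_sd`, `age_median`,
#'   `age_q1`, `age_q3`, `age_min`, `age_max`.
#' @export
#' @examples
#' age_summary(c(40, 44, 46, 50, 50, 57, 61, 61, 63, 65, 67, 69, 69,
#'               71, 71, 72, 73, 74))
age_summary <- function(ages) {
  ages <- as.numeric(ages)
  if (length(ages) < 1 || anyNA(ages)) {
    abort("ages must be non-empty and free of missing values")
  }
  q <- quantile(ages, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble(
    n = length(ages),
    age_mean = mean(ages),
    age_sd = if (length(ages) > 1) sd(ages) else NA_real_,
    age_median = q[2],
    age_q1 = q[1],
    age_q3 = q[3],
    age_min = min(ages),
    age_max = max(ages)
  )
}

#' Per-cohort demographic summaries
#'
#' One row per cohort present in the data: case count, sex split, and the
#' [age_summary()] descriptives. Record order is irrelevant; summaries are
#' computed per distinct case.
#'
#' @param records Validated long-format records.
#' @return Tibble with one row per cohort.
#' @export
summarize_cohorts <- function(records) {
  cases <- dplyr::distinct(
    records, .data$case_id, .data$cohort, .data$sex, .data$age_at_death
  )
  if (nrow(cases) == 0) abort("no cases to summarize")
  dplyr::ungroup(dplyr::group_modify(
    dplyr::group_by(cases, .data$cohort),
    function(grp, key) {
      dplyr::bind_cols(
        tibble(
          n = nrow(grp),
          n_female = sum(grp$sex == "F"),
          n_male = sum(grp$sex == "M")
        ),
        age_summary(grp$age_at_death)[-1]
      )
    }
  ))
}
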