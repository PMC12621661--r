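# Small-sample binomial prevalence inference: Agresti-Coull modified Wald
# intervals, the Agresti-Caffo two-proportion z-test (implemented from the
# add-one-success-and-one-failure definition; no CRAN implementation is
# relied on), prevalence fold changes, and prevalence / co-pathology
# tabulation.

#' Agresti-Coull (modified Wald) binomial confidence interval
#'
#' Inflates the sample by \eqn{z^2} pseudo-observations before applying the
#' Wald formula: with \eqn{\tilde{n} = n + z^2} and
#' \eqn{\tilde{p} = (x + z^2/2)/\tilde{n}}, the interval is
#' \eqn{\tilde{p} \pm z \sqrt{\tilde{p}(1-\tilde{p})/\tilde{n}}},
#' clamped to \[0, 1\]. `z` is the exact standard-normal quantile
#' (1.959964 at `level = 0.95`), not the rounded 1.96.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials, `n >= 1`.
#' @param level Confidence level in (0, 1).
#' @return Tibble with one row per input: `x`, `n`, `p_hat`, `z_crit`,
#'   `n_adj`, `p_adj`, `lower`, `upper`, `level`.
#' @export
#' @examples
#' agresti_coull_ci(18, 33)           # prevalence 54.5%, CI 38.0-70.2%
#' agresti_coull_ci(9, 10)            # upper bound clamps to 1
agresti_coull_ci <- function(x, n, level = 0.95) {
  if (length(level) != 1 || !is.finite(level) || level <= 0 || level >= 1) {
    abort("level must be a single value in (0, 1)")
  }
  k <- max(length(x), length(n))
  x <- rep_len(as.numeric(x), k)
  n <- rep_len(as.numeric(n), k)
  if (any(!is.finite(x) | !is.finite(n) | n < 1 | x < 0 | x > n)) {
    abort("require 0 <= x <= n and n >= 1")
  }
  z <- qnorm(1 - (1 - level) / 2)
  n_adj <- n + z^2
  p_adj <- (x + z^2 / 2) / n_adj
  half <- z * sqrt(p_adj * (1 - p_adj) / n_adj)
  tibble(
    x = x, n = n, p_hat = x / n, z_crit = z, n_adj = n_adj, p_adj = p_adj,
    lower = pmax(0, p_adj - half), upper = pmin(1, p_adj + half),
    level = level
  )
}

#' Two-sided p-value from a standard-normal statistic
#'
#' `2 * (1 - pnorm(|z|))`, the reporting convention used alongside the
#' Agresti-Caffo z statistic.
#'
#' @param z Finite test statistic (vectorised).
#' @return p-values in (0, 1\].
#' @export
#' @examples
#' normal_two_sided_p(2.3962)  # 0.0166
normal_two_sided_p <- function(z) {
  z <- as.numeric(z)
  if (any(!is.finite(z))) abort("z must be finite")
  2 * pnorm(-abs(z))
}

#' Prevalence fold change between two groups
#'
#' Ratio of unadjusted sample proportions `(x1/n1) / (x2/n2)`. When the
#' reference proportion is zero the ratio is undefined and `Inf` is returned
#' as a signalling marker (`NaN` when both are zero); the pseudo-count
#' adjusted proportions are never used here.
#'
#' @param x1,n1 Comparison group successes / trials.
#' @param x2,n2 Reference group successes / trials.
#' @return Fold change (positive real, or `Inf`/`NaN` marker).
#' @export
#' @examples
#' fold_change(12, 14, 6, 19)  # 2.71 -> reported "2.7-fold"
fold_change <- function(x1, n1, x2, n2) {
  if (any(c(n1, n2) < 1) || any(c(x1, x2) < 0) || x1 > n1 || x2 > n2) {
    abort("require 0 <= x <= n and n >= 1 in both groups")
  }
  (x1 / n1) / (x2 / n2)
}

#' Agresti-Caffo two-proportion z-test and confidence interval
#'
#' Adds one success and one failure to each group
#' (\eqn{\tilde{p}_i = (x_i + 1)/(n_i + 2)}) and compares the adjusted
#' proportions on the Wald scale:
#' \deqn{z = (\tilde{p}_1 - \tilde{p}_2) / \sqrt{\tilde{p}_1(1-\tilde{p}_1)/(n_1+2)
#'   + \tilde{p}_2(1-\tilde{p}_2)/(n_2+2)}}
#' with a two-sided normal p-value and the interval
#' `diff +/- z_crit * se`. The reported `fold` uses the unadjusted sample
#' proportions (see [fold_change()]).
#'
#' @param x1,n1 First group successes / trials (`n1 >= 1`).
#' @param x2,n2 Second group successes / trials (`n2 >= 1`).
#' @param level Confidence level for the difference interval.
#' @return One-row tibble: counts, `p_adj1`, `p_adj2`, `se_diff`, `z`,
#'   `p_two_sided`, `diff_lower`, `diff_upper`, `fold`, `level`.
#' @export
#' @examples
#' agresti_caffo_test(12, 14, 6, 19)  # z = 3.3795, p < 0.001
agresti_caffo_test <- function(x1, n1, x2, n2, level = 0.95) {
  counts <- c(x1, n1, x2, n2)
  if (length(counts) != 4 || any(!is.finite(counts))) {
    abort("x1, n1, x2, n2 must be single finite counts")
  }
  if (n1 < 1 || n2 < 1 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    abort("require 0 <= x <= n and n >= 1 in both groups")
  }
  p1 <- (x1 + 1) / (n1 + 2)
  p2 <- (x2 + 1) / (n2 + 2)
  se <- sqrt(p1 * (1 - p1) / (n1 + 2) + p2 * (1 - p2) / (n2 + 2))
  z <- (p1 - p2) / se
  z_crit <- qnorm(1 - (1 - level) / 2)
  fold <- if (x2 > 0) fold_change(x1, n1, x2, n2) else {
    if (x1 > 0) Inf else NaN
  }
  tibble(
    x1 = x1, n1 = n1, x2 = x2, n2 = n2,
    p_adj1 = p1, p_adj2 = p2, se_diff = se, z = z,
    p_two_sided = normal_two_sided_p(z),
    diff_lower = (p1 - p2) - z_crit * se,
    diff_upper = (p1 - p2) + z_crit * se,
    fold = fold, level = level
  )
}

#' Tabulate TDP-43 pathology prevalence with Agresti-Coull intervals
#'
#' At cohort level an individual counts as pathology-positive if positive in
#' at least one brain region; at cohort x region level positivity is the
#' region's own status. Groups with no cases are emitted with `n = 0` and
#' missing interval bounds.
#'
#' @param records Validated long-format records (see [as_cohort_records()]).
#' @param by `"cohort"` or `"cohort_region"`.
#' @param level Confidence level.
#' @return A `ferro_prevalence` tibble with one row per group:
#'   grouping columns, `x`, `n`, `p_hat`, `p_adj`, `lower`, `upper`, `level`.
#' @export
prevalence_table <- function(records, by = c("cohort", "cohort_region"),
                             level = 0.95) {
  by <- match.arg(by)
  if (by == "cohort") {
    cases <- dplyr::summarise(
      dplyr::group_by(records, .data$case_id, .data$cohort),
      positive = as.integer(any(.data$tdp43_status == 1)),
      .groups = "drop"
    )
    counts <- dplyr::summarise(
      dplyr::group_by(cases, .data$cohort, .drop = FALSE),
      x = sum(.data$positive), n = dplyr::n(), .groups = "drop"
    )
  } else {
    counts <- dplyr::summarise(
      dplyr::group_by(records, .data$cohort, .data$region, .drop = FALSE),
      x = sum(.data$tdp43_status == 1), n = dplyr::n(), .groups = "drop"
    )
  }
  ci <- purrr::map2(counts$x, counts$n, function(x, n) {
    if (n == 0) {
      tibble(p_hat = NA_real_, p_adj = NA_real_,
             lower = NA_real_, upper = NA_real_)
    } else {
      agresti_coull_ci(x, n, level)[c("p_hat", "p_adj", "lower", "upper")]
    }
  })
  out <- dplyr::bind_cols(counts, purrr::list_rbind(ci), tibble(level = level))
  class(out) <- c("ferro_prevalence", class(out))
  out
}

#' Region co-pathology pattern counts
#'
#' Counts individuals over the \eqn{2^3} presence/absence patterns of the
#' three regions (the upset-plot decomposition). Region marginal counts are
#' derived from the pattern counts, never re-counted from the raw data, so
#' the marginal identity is structural.
#'
#' @param records Validated long-format records.
#' @param cohort Optional single cohort label to restrict to.
#' @return List of class `ferro_patterns` with elements `patterns` (8-row
#'   tibble: one indicator column per region, `count`), `marginals` (tibble
#'   `region`, `count`), `n_total`, and `n_positive` (individuals positive in
#'   at least one region).
#' @export
copathology_patterns <- function(records, cohort = NULL) {
  if (!is.null(cohort)) {
    cohort <- unname(default_label_map()[match.arg(
      as.character(cohort), names(default_label_map())
    )])
    records <- records[records$cohort == cohort, ]
  }
  wide <- tidyr::pivot_wider(
    records[c("case_id", "region", "tdp43_status")],
    names_from = "region", values_from = "tdp43_status"
  )
  grid <- tidyr::expand_grid(!!!setNames(
    rep(list(c(0L, 1L)), length(ferro_regions)), ferro_regions
  ))
  observed <- dplyr::count(wide, dplyr::across(dplyr::all_of(ferro_regions)),
                           name = "count")
  patterns <- dplyr::left_join(grid, observed, by = ferro_regions)
  patterns$count[is.na(patterns$count)] <- 0L
  marginals <- tibble(
    region = factor(ferro_regions, levels = ferro_regions),
    count = vapply(ferro_regions,
                   function(r) sum(patterns$count[patterns[[r]] == 1L]),
                   integer(1))
  )
  structure(
    list(
      patterns = patterns,
      marginals = marginals,
      n_total = nrow(wide),
      n_positive = sum(patterns$count[rowSums(patterns[ferro_regions]) > 0])
    ),
    class = "ferro_patterns"
  )
}

#' @export
print.ferro_patterns <- function(x, ...) {
  cat(sprintf("Region co-pathology patterns: %d of %d individuals positive\n",
              x$n_positive, x$n_total))
  print(x$patterns)
  cat("Marginals (derived):\n")
  print(x$marginals)
  invisible(x)
}

#' Display-layer rounding for prevalence reports
#'
#' Percentages and interval bounds to 1 decimal place on the percent scale;
#' internal columns keep full precision.
#'
#' @param prevalence A [prevalence_table()] result.
#' @return Tibble with `pct`, `pct_lower`, `pct_upper` display columns.
#' @export
format_prevalence <- function(prevalence) {
  dplyr::mutate(
    as_tibble(prevalence),
    pct = round(100 * .data$p_hat, 1),
    pct_lower = round(100 * .data$lower, 1),
    pct_upper = round(100 * .data$upper, 1)
  )
}
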