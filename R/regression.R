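# Ordinary least-squares panel linking ferritin stain burden (predictor) to
# TDP-43 stain burden (outcome), one fit per cohort x region cell.

#' Simple OLS fit of TDP-43 burden on ferritin burden
#'
#' Fits `y ~ x` by ordinary least squares on pairwise-complete cases and
#' collects the panel quantities: slope with standard error and confidence
#' interval, model F on `(1, n - 2)` degrees of freedom with its p-value,
#' and (adjusted) R-squared. For a single predictor `F = t_slope^2`.
#'
#' @param x Predictor intensities (ferritin).
#' @param y Outcome intensities (TDP-43).
#' @param level Confidence level for the slope interval.
#' @return Object of class `ferro_ols` wrapping the `lm` fit; use
#'   [tidy()]/[glance()] for tibble views, or `$result` for the one-row
#'   summary.
#' @export
#' @examples
#' fit <- ols_fit(1:5, 2 * (1:5) + 1)
#' glance(fit)
ols_fit <- function(x, y, level = 0.95) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3) abort("need >= 3 complete (x, y) pairs")
  if (diff(range(x)) == 0) abort("predictor is constant")
  fit <- lm(y ~ x)
  # an exactly collinear (x, y) pair is a legitimate input here
  sm <- suppressWarnings(summary(fit))
  slope <- unname(coef(fit)[2])
  se_slope <- sm$coefficients[2, 2]
  t_slope <- sm$coefficients[2, 3]
  df2 <- n - 2L
  f_stat <- t_slope^2
  ci <- unname(suppressWarnings(confint(fit, "x", level = level)))
  result <- tibble(
    n = n,
    intercept = unname(coef(fit)[1]),
    estimate = slope, se = se_slope, t = t_slope,
    F = f_stat, df1 = 1L, df2 = df2,
    p = pf(f_stat, 1, df2, lower.tail = FALSE),
    r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
    ci_lower = ci[1], ci_upper = ci[2], level = level
  )
  structure(list(fit = fit, result = result, level = level),
            class = "ferro_ols")
}

#' @export
print.ferro_ols <- function(x, ...) {
  r <- x$result
  cat(sprintf(
    "OLS fit (n = %d): slope %.4g (SE %.4g), F(1, %d) = %.4g, p = %.4g, adj R2 = %.3f\n",
    r$n, r$estimate, r$se, r$df2, r$F, r$p, r$r2_adj
  ))
  invisible(x)
}

#' @export
tidy.ferro_ols <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  tibble(
    term = c("(Intercept)", "ferritin"),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @export
glance.ferro_ols <- function(x, ...) x$result

#' @export
autoplot.ferro_ols <- function(object, ...) {
  d <- tibble(x = object$fit$model$x, y = object$fit$model$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         level = object$level, colour = "steelblue") +
    ggplot2::labs(x = "Ferritin burden (OD units)",
                  y = "TDP-43 burden (OD units)")
}

#' Adjusted R-squared implied by a model F statistic
#'
#' For a model F on `(df1, df2)` degrees of freedom,
#' `r2 = F df1 / (F df1 + df2)` and
#' `r2_adj = 1 - (1 - r2) (df1 + df2) / df2` (for simple regression
#' `df1 + df2 = n - 1`). Lets published (F, df) pairs be converted back to
#' the adjusted R-squared a fit would report.
#'
#' @param f Model F statistic, `>= 0`.
#' @param df1 Numerator degrees of freedom (1 for simple regression).
#' @param df2 Denominator degrees of freedom, `>= 1`.
#' @return Adjusted R-squared.
#' @export
#' @examples
#' adjusted_r2_from_f(59.62, 1, 8)  # 0.867
adjusted_r2_from_f <- function(f, df1 = 1, df2) {
  if (any(f < 0)) abort("F must be >= 0")
  if (any(df2 < 1)) abort("df2 must be >= 1")
  r2 <- f * df1 / (f * df1 + df2)
  1 - (1 - r2) * (df1 + df2) / df2
}

#' Per-cohort, per-region regression panel
#'
#' One [ols_fit()] of TDP-43 burden on ferritin burden per cohort x region
#' cell with at least 3 pairwise-complete cases and a non-constant
#' predictor; other cells are emitted as skipped rows with a reason, never
#' dropped silently.
#'
#' @param records Validated long-format records.
#' @param level Confidence level for slope intervals.
#' @return A `ferro_panel` tibble: `cohort`, `region`, `skipped`, `reason`,
#'   and the [ols_fit()] summary columns.
#' @export
regression_panel <- function(records, level = 0.95) {
  cells <- tidyr::expand_grid(
    cohort = factor(levels(records$cohort), levels(records$cohort)),
    region = factor(levels(records$region), levels(records$region))
  )
  rows <- purrr::pmap(cells, function(cohort, region) {
    cell <- records[records$cohort == cohort & records$region == region, ]
    x <- cell$ferritin_intensity
    y <- cell$tdp43_intensity
    ok <- complete.cases(x, y)
    base <- tibble(cohort = cohort, region = region)
    if (sum(ok) < 3) {
      return(dplyr::bind_cols(base, tibble(
        skipped = TRUE, reason = sprintf("only %d complete pairs", sum(ok)),
        n = sum(ok)
      )))
    }
    if (diff(range(x[ok])) == 0) {
      return(dplyr::bind_cols(base, tibble(
        skipped = TRUE, reason = "constant ferritin predictor", n = sum(ok)
      )))
    }
    dplyr::bind_cols(
      base, tibble(skipped = FALSE, reason = NA_character_),
      glance(ols_fit(x, y, level = level))
    )
  })
  out <- purrr::list_rbind(rows)
  class(out) <- c("ferro_panel", class(out))
  out
}

#' Forest plot of the regression panel
#'
#' Slope estimates with standard-error bars per cohort, faceted by region —
#' the standard way of displaying a ferritin-to-TDP-43 coefficient panel.
#'
#' @param object A [regression_panel()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ferro_panel <- function(object, ...) {
  d <- dplyr::filter(as_tibble(object), !.data$skipped)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$cohort)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - .data$se, xmax = .data$estimate + .data$se
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::labs(x = "Slope: TDP-43 OD per ferritin OD unit (+/- SE)",
                  y = NULL)
}
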