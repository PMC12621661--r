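# Assumption screening that gates the choice between parametric and
# rank-based comparisons: per-group Shapiro-Wilk normality and the
# median-centred (Brown-Forsythe) Levene variance test.

#' Shapiro-Wilk normality test
#'
#' Thin wrapper with the study's preconditions made explicit: sample size
#' between 3 and 5000 and a non-constant sample.
#'
#' @param values Numeric sample.
#' @return One-row tibble: `test`, `statistic` (W), `p`, `n`.
#' @export
shapiro_wilk <- function(values) {
  values <- as.numeric(values[!is.na(values)])
  n <- length(values)
  if (n < 3 || n > 5000) abort("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0) abort("Shapiro-Wilk requires a non-constant sample")
  fit <- shapiro.test(values)
  tibble(test = "shapiro_wilk", statistic = unname(fit$statistic),
         p = fit$p.value, n = n)
}

#' Median-centred Levene (Brown-Forsythe) test for variance homogeneity
#'
#' One-way ANOVA on absolute deviations from the group medians. Degenerate
#' inputs with zero within-group deviation everywhere are flagged rather than
#' producing an infinite F.
#'
#' @param groups List of numeric samples, each with `n >= 2`.
#' @return One-row tibble: `test`, `statistic` (F), `df1`, `df2`, `p`,
#'   `degenerate` flag.
#' @export
#' @examples
#' levene_median(list(c(0, 1, 2), c(0, 2, 4)))  # F = 0.8, df (1, 4)
levene_median <- function(groups) {
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (length(groups) < 2 || any(lengths(groups) < 2)) {
    abort("need >= 2 groups with >= 2 observations each")
  }
  dev <- unlist(lapply(groups, function(g) abs(g - median(g))))
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- length(groups) - 1L
  df2 <- length(dev) - length(groups)
  if (all(dev == 0)) {
    return(tibble(test = "levene_median", statistic = NA_real_,
                  df1 = df1, df2 = df2, p = NA_real_, degenerate = TRUE))
  }
  tab <- anova(aov(dev ~ grp))
  tibble(test = "levene_median", statistic = tab[["F value"]][1],
         df1 = df1, df2 = df2, p = tab[["Pr(>F)"]][1], degenerate = FALSE)
}

#' Choose between parametric and rank-based comparison strategies
#'
#' Runs [shapiro_wilk()] per group and [levene_median()] across groups. The
#' decision is `"nonparametric"` whenever any group's Shapiro p-value is
#' below `alpha` (or when forced by configuration), mirroring the
#' conservative convention of switching all cohort comparisons to
#' rank-based tests once any cohort departs from normality.
#'
#' @param groups Named list of numeric samples.
#' @param force_nonparametric Force the nonparametric branch regardless of
#'   the screen results.
#' @param alpha Screening significance level (default 0.05).
#' @return List of class `ferro_assumptions`: `shapiro` (per-group tibble),
#'   `levene`, `decision`, `rationale`.
#' @export
choose_test_strategy <- function(groups, force_nonparametric = FALSE,
                                 alpha = 0.05) {
  if (is.null(names(groups))) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  shap <- purrr::list_rbind(
    purrr::imap(groups, function(g, nm) {
      dplyr::bind_cols(tibble(group = nm), shapiro_wilk(g))
    })
  )
  lev <- levene_median(groups)
  failing <- shap$group[shap$p < alpha]
  if (force_nonparametric) {
    decision <- "nonparametric"
    rationale <- "forced by configuration"
  } else if (length(failing) > 0) {
    decision <- "nonparametric"
    rationale <- sprintf("Shapiro-Wilk p < %.2g for group(s): %s",
                         alpha, paste(failing, collapse = ", "))
  } else {
    decision <- "parametric"
    rationale <- "no group departed from normality at the screening level"
  }
  structure(
    list(shapiro = shap, levene = lev, decision = decision,
         rationale = rationale),
    class = "ferro_assumptions"
  )
}

#' @export
print.ferro_assumptions <- function(x, ...) {
  cat("Assumption screen ->", x$decision, "\n  ", x$rationale, "\n")
  print(x$shapiro)
  print(x$levene)
  invisible(x)
}
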