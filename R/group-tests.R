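# Parametric, rank-based and categorical comparisons used across the
# cohorts. Standard tests delegate to stats; the Dunn post-hoc is computed
# from the pooled rank distribution directly.

#' Welch's two-sample t-test from summary statistics or raw samples
#'
#' With summary statistics the Welch statistic and Satterthwaite degrees of
#' freedom are computed in closed form; with raw samples the summaries are
#' computed internally first. The sign convention is
#' `t = (mean2 - mean1) / se`.
#'
#' @param a,b Raw samples (optional; supply either both samples or all six
#'   summaries).
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `mean1`, `mean2`,
#'   `n1`, `n2`.
#' @export
#' @examples
#' welch_t(mean1 = 61.3, sd1 = 10.9, n1 = 18,
#'         mean2 = 54.2, sd2 = 7.4, n2 = 15)
welch_t <- function(a = NULL, b = NULL,
                    mean1 = NULL, sd1 = NULL, n1 = NULL,
                    mean2 = NULL, sd2 = NULL, n2 = NULL) {
  if (!is.null(a) || !is.null(b)) {
    a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
    if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per group")
    mean1 <- mean(a); sd1 <- sd(a); n1 <- length(a)
    mean2 <- mean(b); sd2 <- sd(b); n2 <- length(b)
  }
  if (any(vapply(list(mean1, sd1, n1, mean2, sd2, n2), is.null, logical(1)))) {
    abort("supply raw samples or all six summary statistics")
  }
  if (n1 < 2 || n2 < 2) abort("need n >= 2 per group")
  if (sd1 == 0 && sd2 == 0) abort("zero standard deviation in both groups")
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  se <- sqrt(v1 + v2)
  t_stat <- (mean2 - mean1) / se
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  tibble(
    test = "welch_t", statistic = t_stat, df = df,
    p = 2 * stats::pt(-abs(t_stat), df),
    mean1 = mean1, mean2 = mean2, n1 = n1, n2 = n2
  )
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Average ranks for ties; exact p-value for small untied samples, normal
#' approximation with tie correction otherwise (the `stats::wilcox.test`
#' defaults).
#'
#' @param a,b Numeric samples.
#' @return One-row tibble: `test`, `statistic` (W), `p`, `n1`, `n2`,
#'   `exact` flag.
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) < 1 || length(b) < 1) abort("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && length(a) < 50 && length(b) < 50
  fit <- suppressWarnings(wilcox.test(a, b, exact = exact))
  tibble(test = "wilcoxon_rank_sum", statistic = unname(fit$statistic),
         p = fit$p.value, n1 = length(a), n2 = length(b), exact = exact)
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H with `df = k - 1` and a chi-square p-value. A fully
#' degenerate input (all observations identical) returns `H = 0, p = 1` by
#' convention instead of the 0/0 the tie correction would produce.
#'
#' @param groups List of numeric samples (>= 2 groups, total n >= 3).
#' @return One-row tibble: `test`, `statistic` (H), `df`, `p`, `n`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 4.571
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (length(groups) < 2 || any(lengths(groups) == 0)) {
    abort("need >= 2 non-empty groups")
  }
  values <- unlist(groups)
  if (length(values) < 3) abort("need total n >= 3")
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  if (diff(range(values)) == 0) {
    return(tibble(test = "kruskal_wallis", statistic = 0,
                  df = length(groups) - 1L, p = 1, n = length(values)))
  }
  fit <- kruskal.test(values, grp)
  tibble(test = "kruskal_wallis", statistic = unname(fit$statistic),
         df = unname(fit$parameter), p = fit$p.value, n = length(values))
}

#' Dunn's post-hoc pairwise comparisons with Bonferroni correction
#'
#' Pairwise z statistics from the pooled rank distribution:
#' \deqn{z_{ij} = (\bar{R}_i - \bar{R}_j) / \sqrt{\left(\frac{N(N+1)}{12}
#'   - \frac{\sum_t (t^3 - t)}{12(N-1)}\right)\left(\frac{1}{n_i} +
#'   \frac{1}{n_j}\right)}}
#' with the tie correction over tie groups of size t. Raw two-sided normal
#' p-values are Bonferroni-adjusted over all `k(k-1)/2` pairs and capped
#' at 1.
#'
#' @param groups List of numeric samples (>= 3 groups, all non-empty).
#' @param labels Group names (defaults to `names(groups)`).
#' @return Tibble with one row per pair: `group1`, `group2`, `z`, `p_raw`,
#'   `p_adj`, `m`.
#' @export
dunn_posthoc <- function(groups, labels = names(groups)) {
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (length(groups) < 3) abort("Dunn post-hoc needs >= 3 groups")
  if (any(lengths(groups) == 0)) abort("all groups must be non-empty")
  if (is.null(labels)) labels <- paste0("group", seq_along(groups))
  values <- unlist(groups)
  grp <- rep(seq_along(groups), lengths(groups))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, grp, mean)
  tie_sizes <- table(values)
  tie_term <- sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  var_term <- N * (N + 1) / 12 - tie_term
  m <- length(groups) * (length(groups) - 1) / 2
  pairs <- combn(seq_along(groups), 2)
  out <- purrr::map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    se <- sqrt(var_term * (1 / lengths(groups)[i] + 1 / lengths(groups)[j]))
    z <- if (se == 0) 0 else (rbar[[i]] - rbar[[j]]) / se
    p_raw <- normal_two_sided_p(z)
    tibble(group1 = labels[i], group2 = labels[j], z = z,
           p_raw = p_raw, p_adj = min(1, m * p_raw), m = m)
  })
  purrr::list_rbind(out)
}

#' Chi-square goodness-of-fit test
#'
#' Pearson statistic against expected proportions, `df = cells - 1`, no
#' continuity correction.
#'
#' @param observed Vector of observed counts.
#' @param expected_proportions Expected proportions (default uniform);
#'   must be positive and is normalised to sum to 1.
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `n`.
#' @export
#' @examples
#' chi_square_gof(c(33, 20))  # sex balance: 3.189, p = 0.074
chi_square_gof <- function(observed,
                           expected_proportions = rep(1, length(observed))) {
  if (any(expected_proportions <= 0)) abort("expected proportions must be > 0")
  p <- expected_proportions / sum(expected_proportions)
  fit <- chisq.test(observed, p = p)
  tibble(test = "chi_square_gof", statistic = unname(fit$statistic),
         df = as.integer(unname(fit$parameter)), p = fit$p.value,
         n = sum(observed))
}

#' Chi-square test of independence on a two-way table
#'
#' Pearson statistic with `df = (r - 1)(c - 1)`. Continuity correction is
#' off by default (the convention used for the cohort sex-balance tests) and
#' can be enabled for 2x2 tables.
#'
#' @param table Two-way count matrix.
#' @param correct Apply Yates continuity correction (2x2 only).
#' @return One-row tibble: `test`, `statistic`, `df`, `p`, `n`.
#' @export
chi_square_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("table has an empty row or column")
  }
  fit <- suppressWarnings(chisq.test(table, correct = correct))
  tibble(test = "chi_square_independence", statistic = unname(fit$statistic),
         df = as.integer(unname(fit$parameter)), p = fit$p.value,
         n = sum(table))
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by summing hypergeometric probabilities no larger than
#' the observed table's. Degenerate margins (an all-zero row or column)
#' return `p = 1` by convention.
#'
#' @param table 2x2 count matrix.
#' @return One-row tibble: `test`, `p`, `odds_ratio`, `n`.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    abort("need a 2x2 table of non-negative counts")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(tibble(test = "fisher_exact", p = 1, odds_ratio = NA_real_,
                  n = sum(table)))
  }
  fit <- fisher.test(table)
  tibble(test = "fisher_exact", p = fit$p.value,
         odds_ratio = unname(fit$estimate), n = sum(table))
}

#' Spearman rank correlation
#'
#' Average ranks for ties, asymptotic p-value. A constant input has no rank
#' ordering and is signalled as an error.
#'
#' @param x,y Paired numeric samples of equal length, `n >= 3`.
#' @return One-row tibble: `test`, `statistic` (rho), `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  if (length(x) != length(y) || length(x) < 3) {
    abort("need paired samples with n >= 3")
  }
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    abort("rank correlation undefined for a constant sample")
  }
  fit <- suppressWarnings(cor.test(x, y, method = "spearman", exact = FALSE))
  tibble(test = "spearman", statistic = unname(fit$estimate),
         p = fit$p.value, n = length(x))
}
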