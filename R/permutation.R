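# Label-permutation testing with Cliff's delta effect sizes, used where
# rank-based post-hocs are unsuitable (heavy ties, near-identical rank
# distributions).

#' Cliff's delta effect size
#'
#' \eqn{\delta = (\#\{a_i > b_j\} - \#\{a_i < b_j\}) / (n_a n_b)}: the
#' normalised excess of between-group pair orderings, in \[-1, 1\]. Ties
#' contribute zero; identical samples give exactly 0, complete separation
#' gives +/-1.
#'
#' @param a,b Non-empty numeric samples.
#' @return A single value in \[-1, 1\].
#' @export
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))  # -5/9
cliffs_delta <- function(a, b) {
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  cmp <- sign(outer(a, b, "-"))
  sum(cmp) / (length(a) * length(b))
}

perm_stat <- function(values, idx_a, statistic) {
  if (statistic == "mean_diff") {
    mean(values[idx_a]) - mean(values[-idx_a])
  } else {
    median(values[idx_a]) - median(values[-idx_a])
  }
}

#' Two-sample permutation test with Cliff's delta
#'
#' The observed statistic (difference in group means by default, medians as
#' an option) is compared against the null distribution obtained by
#' permuting group labels. The p-value is the plain proportion of
#' permutations whose statistic is at least as extreme as the observed one,
#' `p = #{|T*| >= |t_obs|} / B` (so `p = 0` is possible; an add-one
#' smoothed variant is available but off by default). When the number of
#' distinct label arrangements is at most `B` the null is enumerated
#' exhaustively instead of sampled (`exact = "auto"`).
#'
#' @param a,b Non-empty numeric samples.
#' @param statistic `"mean_diff"` (default) or `"median_diff"`.
#' @param B Number of permutations (default 10000).
#' @param seed Integer seed for the sampled path; the global RNG state is
#'   left untouched.
#' @param exact `"auto"` (enumerate when `choose(n, n_a) <= B`), `"never"`,
#'   or `"always"`.
#' @param smooth Use the add-one estimator `(n_extreme + 1)/(B + 1)`.
#' @return One-row tibble of class `ferro_perm`: `statistic_kind`, `t_obs`,
#'   `B` (arrangements actually evaluated), `n_extreme`, `p`, `exact`,
#'   `seed`, `delta`, `n1`, `n2`.
#' @export
#' @examples
#' permutation_test(c(1, 2, 3), c(4, 5, 6), B = 1000)  # exhaustive, p = 0.1
permutation_test <- function(a, b, statistic = c("mean_diff", "median_diff"),
                             B = 10000, seed = NULL,
                             exact = c("auto", "never", "always"),
                             smooth = FALSE) {
  statistic <- match.arg(statistic)
  exact <- match.arg(exact)
  a <- as.numeric(a[!is.na(a)]); b <- as.numeric(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) abort("both samples must be non-empty")
  if (B < 1) abort("B must be >= 1")
  values <- c(a, b)
  n <- length(values)
  na <- length(a)
  t_obs <- perm_stat(values, seq_len(na), statistic)
  n_arrange <- choose(n, na)
  use_exact <- switch(exact,
    auto = n_arrange <= B,
    never = FALSE,
    always = TRUE
  )
  if (use_exact) {
    if (n_arrange > 5e6) abort("exhaustive enumeration infeasible at this n")
    idx <- combn(n, na)
    t_null <- vapply(seq_len(ncol(idx)),
                     function(k) perm_stat(values, idx[, k], statistic),
                     numeric(1))
    B_used <- ncol(idx)
  } else {
    draw <- function() {
      vapply(seq_len(B), function(i) {
        perm_stat(values, sample.int(n, na), statistic)
      }, numeric(1))
    }
    t_null <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
    B_used <- as.integer(B)
  }
  n_extreme <- sum(abs(t_null) >= abs(t_obs) - 1e-12)
  p <- if (smooth) (n_extreme + 1) / (B_used + 1) else n_extreme / B_used
  out <- tibble(
    statistic_kind = statistic, t_obs = t_obs, B = B_used,
    n_extreme = n_extreme, p = p, exact = use_exact,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    delta = cliffs_delta(a, b), n1 = na, n2 = length(b)
  )
  class(out) <- c("ferro_perm", class(out))
  out
}
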