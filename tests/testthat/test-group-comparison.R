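test_that("Shapiro-Wilk wrapper enforces preconditions and affine invariance", {
  x <- c(2.1, 3.4, 1.7, 5.2, 4.4, 2.9, 3.8)
  w1 <- shapiro_wilk(x)$statistic
  w2 <- shapiro_wilk(3 + 2.5 * x)$statistic
  w3 <- shapiro_wilk(-x)$statistic
  expect_equal(w1, w2, tolerance = 1e-10)
  expect_equal(w1, w3, tolerance = 1e-10)
  expect_gt(w1, 0)
  expect_lte(w1, 1)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
  expect_error(shapiro_wilk(rep(1, 5)), "non-constant")
})

test_that("median-centred Levene matches the hand-computed deviation ANOVA", {
  res <- levene_median(list(c(0, 1, 2), c(0, 2, 4)))
  expect_equal(res$statistic, 0.8, tolerance = 1e-12)
  expect_identical(c(res$df1, res$df2), c(1L, 4L))

  same <- levene_median(list(c(1, 5, 9), c(1, 5, 9)))
  expect_equal(same$statistic, 0)

  degenerate <- levene_median(list(c(2, 2), c(7, 7)))
  expect_true(degenerate$degenerate)
  expect_true(is.na(degenerate$statistic))
})

test_that("median-centred Levene agrees with car's Brown-Forsythe variant", {
  skip_if_not_installed("car")
  groups <- withr::with_seed(5, list(rnorm(12), rnorm(15, sd = 2), rnorm(9)))
  mine <- levene_median(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  ref <- car::leveneTest(unlist(groups), g, center = median)
  expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-10)
  expect_equal(mine$p, ref[["Pr(>F)"]][1], tolerance = 1e-10)
})

test_that("Levene detects a four-fold scale difference with high power", {
  rejections <- withr::with_seed(21, vapply(1:500, function(i) {
    levene_median(list(rnorm(50, sd = 1), rnorm(50, sd = 4)))$p < 0.05
  }, logical(1)))
  expect_gt(mean(rejections), 0.8)
})

test_that("the assumption gate routes per the Shapiro screen", {
  normals <- withr::with_seed(3, replicate(4, rnorm(30), simplify = FALSE))
  names(normals) <- cohort_levels()
  expect_identical(choose_test_strategy(normals)$decision, "parametric")

  skewed <- normals
  skewed$AD <- exp(withr::with_seed(4, rnorm(30, sd = 1.5)))
  gate <- choose_test_strategy(skewed)
  expect_identical(gate$decision, "nonparametric")
  expect_match(gate$rationale, "AD")

  forced <- choose_test_strategy(normals, force_nonparametric = TRUE)
  expect_identical(forced$decision, "nonparametric")
  expect_match(forced$rationale, "forced by configuration")
})

test_that("Welch t from summaries matches the closed form on published summaries", {
  res <- welch_t(mean1 = 61.3, sd1 = 10.9, n1 = 18,
                 mean2 = 54.2, sd2 = 7.4, n2 = 15)
  expect_equal(round(res$statistic, 3), -2.218)
  expect_equal(round(res$df, 1), 29.9)
  expect_lt(res$p, 0.05)
})

test_that("Welch t degenerates and closed forms hold", {
  same <- welch_t(mean1 = 5, sd1 = 2, n1 = 10, mean2 = 5, sd2 = 2, n2 = 10)
  expect_identical(same$statistic, 0)
  expect_identical(same$p, 1)
  # equal n and SD collapses Satterthwaite to the pooled df
  eq <- welch_t(mean1 = 1, sd1 = 3, n1 = 12, mean2 = 2, sd2 = 3, n2 = 12)
  expect_equal(eq$df, 22)
  # raw samples agree with stats::t.test
  a <- c(3.1, 4.5, 2.2, 5.0, 3.3)
  b <- c(6.1, 5.9, 7.2, 4.8, 6.6, 5.5)
  mine <- welch_t(a, b)
  ref <- t.test(b, a)
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_error(welch_t(mean1 = 1, sd1 = 0, n1 = 5, mean2 = 2, sd2 = 0, n2 = 5),
               "zero standard deviation")
})

test_that("Wilcoxon rank-sum: exhaustive small-sample p and tie handling", {
  # C(4,2) = 6 labelings; the observed split is one of two extremes
  res <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p, 2 / 6, tolerance = 1e-12)
  # identical multisets force ties onto the approximation path with p = 1
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_false(same$exact)
  expect_equal(same$p, 1)
})

test_that("Wilcoxon detects a two-sigma shift with high power", {
  rejections <- withr::with_seed(8, vapply(1:500, function(i) {
    wilcoxon_rank_sum(rnorm(30), rnorm(30, mean = 2))$p < 0.05
  }, logical(1)))
  expect_gt(mean(rejections), 0.95)
})

test_that("Kruskal-Wallis H matches hand rank computation and handles ties", {
  res <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(round(res$statistic, 3), 4.571)
  expect_identical(res$df, 2L)

  same <- kruskal_wallis(list(c(3, 3), c(3, 3)))
  expect_identical(res_same <- same$statistic, 0)
  expect_identical(same$p, 1)

  tied <- list(c(1, 1, 2, 2), c(2, 2, 3, 3), c(1, 3, 3, 3))
  mine <- kruskal_wallis(tied)
  ref <- kruskal.test(unlist(tied), factor(rep(1:3, each = 4)))
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-6)
})

test_that("Dunn z uses the pooled rank distribution with Bonferroni capping", {
  res <- dunn_posthoc(list(c(1, 2), c(3, 4), c(5, 6)), c("a", "b", "c"))
  ac <- res[res$group1 == "a" & res$group2 == "c", ]
  # SE = sqrt((N(N+1)/12)(1/n1 + 1/n2)) without ties
  expect_equal(round(ac$z, 3), -2.138)
  expect_true(all(res$m == 3))
  expect_true(all(res$p_adj <= 1))
  expect_equal(res$p_adj, pmin(1, res$m * res$p_raw))

  same <- dunn_posthoc(rep(list(c(1, 2, 3)), 3), c("x", "y", "z"))
  expect_true(all(same$z == 0))
  expect_true(all(same$p_adj == 1))
})

test_that("Dunn on cohort-structured ages recovers the published significance pattern", {
  # ages drawn around the four cohort medians/IQRs; the three under-60
  # contrasts should be the significant ones, the three others not
  sim <- generate_cohort(default_study_config(), seed = 31)
  cases <- dplyr::distinct(sim$records, case_id, cohort, age_at_death)
  groups <- split(cases$age_at_death, cases$cohort)
  res <- dunn_posthoc(groups, names(groups))
  sig <- res$p_adj < 0.05
  with_u60 <- res$group1 == "under60" | res$group2 == "under60"
  expect_true(all(sig[with_u60]))
  expect_false(any(sig[!with_u60]))
})

test_that("chi-square tests reproduce the published sex-balance statistics", {
  overall <- chi_square_gof(c(33, 20))
  expect_equal(round(overall$statistic, 3), 3.189)
  expect_equal(round(overall$p, 3), 0.074)
  expect_identical(overall$df, 1L)

  by_cohort <- chi_square_independence(rbind(F = c(6, 5, 3, 6),
                                             M = c(13, 9, 7, 4)))
  expect_equal(round(by_cohort$statistic, 3), 2.695)
  expect_identical(by_cohort$df, 3L)
  expect_equal(round(by_cohort$p, 3), 0.441)
})

test_that("chi-square degenerate and hand-computed cases", {
  expect_equal(chi_square_gof(c(25, 25))$statistic, 0)
  expect_equal(chi_square_gof(c(25, 25))$p, 1)
  expect_equal(round(chi_square_gof(c(26, 27))$statistic, 4), 0.0189)

  proportional <- rbind(c(10, 20), c(5, 10))
  expect_equal(chi_square_independence(proportional)$statistic, 0)
  expect_equal(chi_square_independence(diag(c(10, 10)))$statistic, 20)
  expect_error(chi_square_independence(rbind(c(0, 0), c(1, 2))), "empty row")
})

test_that("Fisher's exact test: enumeration, degeneracy, transposition symmetry", {
  res <- fisher_exact_2x2(rbind(c(2, 0), c(0, 2)))
  expect_equal(round(res$p, 4), 0.3333)

  zero_row <- fisher_exact_2x2(rbind(c(0, 0), c(3, 4)))
  expect_identical(zero_row$p, 1)

  for (seed in 1:5) {
    tab <- withr::with_seed(seed, matrix(rpois(4, 5), 2))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab)$p, fisher_exact_2x2(t(tab))$p,
                 tolerance = 1e-12)
  }
})

test_that("Spearman rho: hand computation, monotone extremes, antisymmetry", {
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2))$statistic, 0.5)
  x <- c(2, 5, 9, 11, 20)
  expect_equal(spearman_rho(x, x^3)$statistic, 1)
  y <- c(4, 1, 7, 2, 9)
  expect_equal(spearman_rho(x, y)$statistic, -spearman_rho(x, -y)$statistic)
  expect_error(spearman_rho(rep(1, 5), y), "constant")
})

test_that("Kruskal-Wallis holds its type-I error at the study group sizes", {
  alpha_hat <- withr::with_seed(97, mean(vapply(1:2000, function(i) {
    groups <- lapply(c(19, 14, 10, 10), rnorm)
    kruskal_wallis(groups)$p < 0.05
  }, logical(1))))
  expect_gte(alpha_hat, 0.04)
  expect_lte(alpha_hat, 0.06)
})
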