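# End-to-end orchestration: demographics -> age comparisons -> prevalence
# and co-pathology -> ferritin group comparisons (with engine gating) ->
# regression panel, written as stable TSV report tables plus a JSON
# manifest.

#' Analysis configuration
#'
#' @param input Path to a cohort CSV or an in-memory data frame.
#' @param format CSV layout, `"long"` or `"wide"` (see [load_cohort_table()]).
#' @param level Confidence level for all intervals (default 0.95).
#' @param B Permutation count for permutation-routed comparisons
#'   (default 10000).
#' @param seed Integer seed used for every stochastic step.
#' @param tie_threshold Pooled tie proportion above which pairwise
#'   comparisons are routed to the permutation engine (strict inequality;
#'   default 0.5). See [select_pairwise_engine()].
#' @param continuity_correction Apply Yates correction in 2x2 chi-square
#'   tests (off by default).
#' @param force_nonparametric Force the rank-based branch of the
#'   assumption gate.
#' @param label_map Cohort label mapping for ingestion.
#' @param out_dir Optional output directory for TSV tables and the
#'   manifest; `NULL` keeps results in memory only.
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(input, format = "long", level = 0.95, B = 10000,
                            seed = 1, tie_threshold = 0.5,
                            continuity_correction = FALSE,
                            force_nonparametric = FALSE,
                            label_map = default_label_map(),
                            out_dir = NULL) {
  if (level <= 0 || level >= 1) abort("level must be in (0, 1)")
  if (B < 1) abort("B must be >= 1")
  structure(
    list(input = input, format = format, level = level, B = as.integer(B),
         seed = as.integer(seed), tie_threshold = tie_threshold,
         continuity_correction = continuity_correction,
         force_nonparametric = force_nonparametric,
         label_map = label_map, out_dir = out_dir),
    class = "analysis_config"
  )
}

#' Choose the pairwise comparison engine
#'
#' Rank-based Dunn post-hocs are unsuitable when values are heavily tied or
#' rank distributions nearly identical; such comparisons are routed to the
#' label-permutation framework. The rule: route to `"permutation"` when the
#' proportion of pooled observations sharing their value with another
#' observation strictly exceeds `tie_threshold`, or when any two groups have
#' identical rank sums; otherwise `"dunn"`. At exactly the threshold the
#' Dunn engine is kept.
#'
#' @param groups List of numeric samples (>= 2).
#' @param tie_threshold Tie-proportion cutoff in \[0, 1\] (default 0.5).
#' @return `"dunn"` or `"permutation"`.
#' @export
select_pairwise_engine <- function(groups, tie_threshold = 0.5) {
  groups <- lapply(groups, function(g) as.numeric(g[!is.na(g)]))
  if (length(groups) < 2) abort("need >= 2 groups")
  pooled <- unlist(groups)
  counts <- table(pooled)
  prop_tied <- sum(counts[counts > 1]) / length(pooled)
  if (prop_tied > tie_threshold) return("permutation")
  r <- rank(pooled)
  grp <- rep(seq_along(groups), lengths(groups))
  rank_sums <- tapply(r, grp, sum)
  if (anyDuplicated(round(rank_sums, 8)) > 0) return("permutation")
  "dunn"
}

ferro_write <- function(tables, manifest, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables)) {
    readr::write_tsv(as_tibble(tables[[nm]]),
                     file.path(out_dir, paste0(nm, ".tsv")), progress = FALSE)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Run the full cohort analysis
#'
#' Executes the pipeline in report order: demographic summary with
#' sex-balance chi-square tests, age comparison (Kruskal-Wallis omnibus plus
#' Dunn-Bonferroni pairs) gated by the assumption screen, prevalence tables
#' with Agresti-Coull intervals and co-pathology pattern counts, per-region
#' ferritin group comparisons routed to Dunn or permutation-plus-delta by
#' the tie rule, and the ferritin-to-TDP-43 regression panel. Statistical
#' degeneracies (a cohort too small to compare, a constant predictor) are
#' recorded per row, never fatal. With an `out_dir` the tables are written
#' as TSV plus a JSON manifest recording seed, B, package version and a
#' configuration hash; outputs are byte-identical across runs at a fixed
#' seed.
#'
#' @param config An [analysis_config()].
#' @return List of class `ferro_report` with elements `demographics`,
#'   `demographic_tests`, `age_comparison`, `prevalence_by_cohort`,
#'   `prevalence_by_cohort_region`, `pattern_counts`,
#'   `ferritin_comparisons`, `regression_panel`, `manifest`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  records <- if (is.data.frame(config$input)) {
    as_cohort_records(config$input, label_map = config$label_map)
  } else {
    load_cohort_table(config$input, format = config$format,
                      label_map = config$label_map)
  }
  cases <- dplyr::distinct(records, .data$case_id, .data$cohort, .data$sex,
                           .data$age_at_death)

  # 1. demographics ---------------------------------------------------------
  demographics <- summarize_cohorts(records)
  sex_overall <- chi_square_gof(c(sum(cases$sex == "M"),
                                  sum(cases$sex == "F")))
  sex_by_cohort <- table(cases$sex, droplevels(cases$cohort))
  sex_cohort_test <- if (ncol(sex_by_cohort) >= 2) {
    chi_square_independence(sex_by_cohort,
                            correct = config$continuity_correction)
  } else {
    tibble(test = "chi_square_independence", statistic = NA_real_,
           df = NA_real_, p = NA_real_, n = nrow(cases))
  }
  demographic_tests <- dplyr::bind_rows(
    dplyr::mutate(sex_overall, comparison = "sex_balance_overall"),
    dplyr::mutate(sex_cohort_test, comparison = "sex_by_cohort")
  )

  # 2. age comparison -------------------------------------------------------
  age_groups <- split(cases$age_at_death, droplevels(cases$cohort))
  comparable <- lengths(age_groups) >= 2
  age_comparison <- if (sum(lengths(age_groups) > 0) >= 2 &&
                          sum(comparable) >= 2) {
    grp <- age_groups[comparable]
    screen <- tryCatch(
      choose_test_strategy(grp, config$force_nonparametric),
      error = function(e) NULL
    )
    excluded <- names(age_groups)[!comparable]
    gating <- if (is.null(screen)) "assumption screen unavailable" else
      screen$rationale
    if (length(excluded) > 0) {
      gating <- paste0(gating, "; skipped cohort(s) with n < 2: ",
                       paste(excluded, collapse = ", "))
    }
    omnibus <- dplyr::mutate(kruskal_wallis(grp), comparison = "age_omnibus",
                             gating = gating)
    pairs <- if (length(grp) >= 3) {
      dplyr::mutate(dunn_posthoc(grp), comparison = "age_pairwise")
    } else {
      NULL
    }
    dplyr::bind_rows(omnibus, pairs)
  } else {
    tibble(comparison = "age_omnibus", test = "kruskal_wallis",
           statistic = NA_real_, df = NA_real_, p = NA_real_,
           gating = "skipped: fewer than two cohorts with n >= 2")
  }

  # 3. prevalence + patterns ------------------------------------------------
  prevalence_by_cohort <- prevalence_table(records, "cohort", config$level)
  prevalence_by_cohort_region <-
    prevalence_table(records, "cohort_region", config$level)
  pattern_counts <- purrr::list_rbind(purrr::map(
    as.character(unique(records$cohort)), function(co) {
      pats <- copathology_patterns(records, co)
      dplyr::bind_cols(tibble(cohort = co), pats$patterns)
    }
  ))

  # 4. ferritin comparisons -------------------------------------------------
  ferritin_comparisons <- purrr::list_rbind(purrr::map(
    ferro_regions, function(rg) {
      reg <- records[records$region == rg & !is.na(records$ferritin_intensity), ]
      grp <- split(reg$ferritin_intensity, droplevels(reg$cohort))
      grp <- grp[lengths(grp) > 0]
      if (length(grp) < 2 || sum(lengths(grp) >= 2) < 2) {
        return(tibble(region = rg, comparison = "omnibus",
                      engine = NA_character_,
                      note = "skipped: fewer than two comparable cohorts"))
      }
      omni <- dplyr::bind_cols(
        tibble(region = rg, comparison = "omnibus"),
        kruskal_wallis(grp)
      )
      engine <- select_pairwise_engine(grp, config$tie_threshold)
      pairwise <- if (engine == "dunn" && length(grp) >= 3) {
        dplyr::bind_cols(
          tibble(region = rg, comparison = "pairwise", engine = "dunn"),
          dunn_posthoc(grp)
        )
      } else {
        pair_idx <- combn(length(grp), 2)
        purrr::list_rbind(purrr::map(seq_len(ncol(pair_idx)), function(k) {
          i <- pair_idx[1, k]; j <- pair_idx[2, k]
          res <- permutation_test(grp[[i]], grp[[j]], B = config$B,
                                  seed = config$seed + 1000L * k)
          dplyr::bind_cols(
            tibble(region = rg, comparison = "pairwise",
                   engine = "permutation",
                   group1 = names(grp)[i], group2 = names(grp)[j]),
            as_tibble(res)
          )
        }))
      }
      dplyr::bind_rows(dplyr::mutate(omni, engine = engine), pairwise)
    }
  ))

  # 5. regression panel -----------------------------------------------------
  panel <- regression_panel(records, level = config$level)

  manifest <- list(
    package = "ferropath",
    version = as.character(utils::packageVersion("ferropath")),
    seed = config$seed, B = config$B, level = config$level,
    tie_threshold = config$tie_threshold,
    n_cases = nrow(cases), n_rows = nrow(records),
    config_hash = rlang::hash(config[setdiff(names(config),
                                            c("input", "out_dir"))])
  )

  report <- structure(
    list(
      demographics = demographics,
      demographic_tests = demographic_tests,
      age_comparison = age_comparison,
      prevalence_by_cohort = prevalence_by_cohort,
      prevalence_by_cohort_region = prevalence_by_cohort_region,
      pattern_counts = pattern_counts,
      ferritin_comparisons = ferritin_comparisons,
      regression_panel = panel,
      manifest = manifest
    ),
    class = "ferro_report"
  )
  if (!is.null(config$out_dir)) {
    ferro_write(report[setdiff(names(report), "manifest")], manifest,
                config$out_dir)
  }
  report
}

#' @export
print.ferro_report <- function(x, ...) {
  cat("ferropath analysis report\n")
  cat(sprintf("  cases: %d (seed %d, B %d)\n", x$manifest$n_cases,
              x$manifest$seed, x$manifest$B))
  for (nm in setdiff(names(x), "manifest")) {
    cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Prevalence plot with Agresti-Coull intervals
#'
#' Point prevalence per group with its interval, on the percent scale.
#'
#' @param object A [prevalence_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ferro_prevalence <- function(object, ...) {
  d <- format_prevalence(object)
  d$group <- if ("region" %in% names(d)) {
    interaction(d$cohort, d$region, sep = " / ")
  } else {
    d$cohort
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pct, y = .data$group)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$pct_lower,
                                          xmax = .data$pct_upper)) +
    ggplot2::xlim(0, 100) +
    ggplot2::labs(x = "TDP-43 pathology prevalence (%, Agresti-Coull 95% CI)",
                  y = NULL)
}
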