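write_manifest <- function(out_dir, seed, params) {
  manifest <- list(
    package = "dietquality",
    version = as.character(utils::packageVersion("dietquality")),
    r_version = as.character(getRversion()),
    seed = seed,
    params = params,
    written = c("see files in this directory")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Simulate a cohort and write the diary files
#'
#' Generates a synthetic cohort (see [generate_cohort()]) and writes
#' `diary.csv`, `anthro.csv`, `generator_report.csv` and a run manifest to
#' `out_dir`.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [cohort_config()].
#' @param seed Overrides `config$seed` when given.
#' @return The [generate_cohort()] result, invisibly.
#' @export
run_simulate <- function(out_dir, config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- seed
  res <- generate_cohort(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_diary(res$diary, file.path(out_dir, "diary.csv"))
  readr::write_csv(res$anthro, file.path(out_dir, "anthro.csv"))
  readr::write_csv(res$report, file.path(out_dir, "generator_report.csv"))
  write_manifest(out_dir, res$seed, list(n_participants = config$n_participants))
  message("simulated ", length(unique(res$diary$participant_id)),
          " participants (seed ", res$seed, ")")
  invisible(res)
}

#' Score a diary and write the index report tables
#'
#' Reads and validates a diary, aggregates it to participant means, scores
#' all four diet-quality indices, and writes `component_scores.csv` (long),
#' `index_totals.csv`, `adherence_distribution.csv` and `concordance.csv`.
#'
#' @param diary Path of a diary CSV, or a diary tibble.
#' @param out_dir Output directory.
#' @param sodium_deciles Passed to [score_indices()].
#' @param dash_boundary Passed to [index_totals()].
#' @param sweets_kcal_per_g Passed to [day_totals()].
#' @return A list with `means`, `scores`, `totals`, `adherence`,
#'   `concordance`, invisibly.
#' @export
run_score <- function(diary, out_dir, sodium_deciles = c("cohort", "fixed"),
                      dash_boundary = c("ge", "gt"), sweets_kcal_per_g = 3) {
  sodium_deciles <- match.arg(sodium_deciles)
  dash_boundary <- match.arg(dash_boundary)
  if (is.character(diary)) diary <- read_diary(diary)
  else diary <- validate_diary(diary)
  days <- day_totals(diary, sweets_kcal_per_g = sweets_kcal_per_g)
  means <- participant_means(days)
  scores <- score_indices(means, sodium_deciles = sodium_deciles)
  totals <- index_totals(scores, dash_boundary = dash_boundary)
  adherence <- adherence_distribution(totals)
  concordance <- concordance_table(totals)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(scores, file.path(out_dir, "component_scores.csv"))
  readr::write_csv(totals, file.path(out_dir, "index_totals.csv"))
  readr::write_csv(adherence, file.path(out_dir, "adherence_distribution.csv"))
  readr::write_csv(concordance, file.path(out_dir, "concordance.csv"))
  message("scored ", nrow(means), " participants on 4 indices")
  invisible(list(means = means, scores = scores, totals = totals,
                 adherence = adherence, concordance = concordance))
}

# variables compared within each split, in the published table layout
comparison_variables <- function() {
  c(anthro = "age", anthro = "weight_kg", anthro = "bmi",
    anthro = "waist_cm", anthro = "body_fat_pct", anthro = "visceral_fat",
    diet = "processed_meat_g", diet = "added_sugar", diet = "ssb_ml",
    diet = "n_meals", diet = "energy", diet = "breakfast_energy",
    diet = "pe_breakfast", diet = "pe_sweets", diet = "snack_energy",
    diet = "pe_snacking")
}

#' Group comparisons across cutoff-defined splits and shift-day types
#'
#' For each requested split (see [cohort_split_specs()]) the per-participant
#' metrics are partitioned at the split's cutoff and every comparison
#' variable is tested with the normality-gated two-group procedure; a split
#' whose metric is unavailable (e.g. anthropometrics without a sidecar) or
#' degenerate (an empty group) is skipped with a warning.  Shift-day
#' analyses are always run: McNemar tests on the day-type pairs for each
#' dietary habit, and Friedman tests (with Wilcoxon/Bonferroni post hoc)
#' for meal count and snacking energy share.
#'
#' @param diary Path of a diary CSV, or a diary tibble.
#' @param out_dir Output directory; `comparisons.csv`, `habit_mcnemar.csv`
#'   and `shift_friedman.csv` are written.
#' @param anthro Optional path or tibble of the anthropometric sidecar.
#' @param splits Character vector of split names from [cohort_split_specs()].
#' @param alpha Significance level.
#' @param mcnemar_correct Continuity correction for the McNemar tests.
#' @return A list with `comparisons`, `habit_mcnemar`, `shift_friedman`,
#'   invisibly.
#' @export
run_compare <- function(diary, out_dir, anthro = NULL,
                        splits = cohort_split_specs()$split, alpha = 0.05,
                        mcnemar_correct = FALSE) {
  if (is.character(diary)) diary <- read_diary(diary)
  else diary <- validate_diary(diary)
  if (is.character(anthro)) {
    anthro <- readr::read_csv(anthro, show_col_types = FALSE)
  }
  days <- day_totals(diary)
  means <- participant_means(days)
  totals <- index_totals(score_indices(means))
  wide_totals <- tidyr::pivot_wider(totals[c("participant_id", "index", "total")],
                                    names_from = "index", values_from = "total",
                                    names_prefix = "total_")
  metrics <- dplyr::left_join(means, wide_totals, by = "participant_id")
  if (!is.null(anthro)) {
    metrics <- dplyr::left_join(metrics, anthro, by = "participant_id")
  }

  specs <- cohort_split_specs()
  unknown <- setdiff(splits, specs$split)
  if (length(unknown) > 0) {
    rlang::warn(paste0("unknown split(s) skipped: ",
                       paste(unknown, collapse = ", ")))
  }
  vars <- comparison_variables()
  comparisons <- purrr::map_dfr(intersect(splits, specs$split), function(s) {
    sp <- specs[specs$split == s, ]
    if (!sp$metric %in% names(metrics)) {
      rlang::warn(paste0("split ", s, " skipped: metric ", sp$metric,
                         " unavailable"))
      return(tibble::tibble())
    }
    grouped <- split_cohort(metrics, sp$metric, sp$cutoff, sp$equality)
    lo <- grouped[grouped$group == "low", ]
    hi <- grouped[grouped$group == "high", ]
    if (nrow(lo) < 3 || nrow(hi) < 3) {
      rlang::warn(paste0("split ", s, " skipped: group sizes ", nrow(lo),
                         " and ", nrow(hi)))
      return(tibble::tibble())
    }
    purrr::map_dfr(intersect(vars, names(metrics)), function(v) {
      res <- gated_two_group(lo[[v]], hi[[v]], alpha = alpha)
      gs <- res$group_summaries
      tibble::tibble(
        split = s, metric = sp$metric, cutoff = sp$cutoff, variable = v,
        n_low = gs$n[1], n_high = gs$n[2],
        mean_low = gs$mean[1], sd_low = gs$sd[1], median_low = gs$median[1],
        mean_high = gs$mean[2], sd_high = gs$sd[2],
        median_high = gs$median[2],
        test = res$test_used, statistic = res$statistic,
        p_value = res$p_value, significant = res$significant
      )
    })
  })

  flags <- habit_flags(days)
  habit_cols <- c("consumed_processed_meat", "consumed_sweets", "snacked",
                  "sweetened_beverage")
  pairs <- utils::combn(day_types(), 2, simplify = FALSE)
  habit_mcnemar <- purrr::map_dfr(habit_cols, function(h) {
    wide <- tidyr::pivot_wider(flags[c("participant_id", "day_type", h)],
                               names_from = "day_type",
                               values_from = dplyr::all_of(h))
    purrr::map_dfr(pairs, function(p) {
      res <- suppressWarnings(
        mcnemar_test(wide[[p[1]]], wide[[p[2]]], correct = mcnemar_correct)
      )
      tibble::tibble(habit = h, pair = paste(p, collapse = " vs "),
                     b = res$b, c = res$c, statistic = res$statistic,
                     p_value = res$p_value,
                     significant = res$p_value < alpha)
    })
  })

  shift_vars <- c("n_meals", "snack_energy", "processed_meat_g", "sweets_g")
  shift_friedman <- purrr::map_dfr(shift_vars, function(v) {
    res <- friedman_shifts(days, v, alpha = alpha)
    tibble::tibble(variable = v, statistic = res$friedman_statistic,
                   df = res$friedman_df, p_value = res$friedman_p,
                   n = res$n, n_posthoc = nrow(res$posthoc))
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(comparisons, file.path(out_dir, "comparisons.csv"))
  readr::write_csv(habit_mcnemar, file.path(out_dir, "habit_mcnemar.csv"))
  readr::write_csv(shift_friedman, file.path(out_dir, "shift_friedman.csv"))
  invisible(list(comparisons = comparisons, habit_mcnemar = habit_mcnemar,
                 shift_friedman = shift_friedman))
}
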