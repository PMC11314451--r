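#' Adherence classification of index totals
#'
#' Band definitions: HDI-2015 totals of 6-7 are `high`, 4-5 `moderate`, 0-3
#' `low`.  Mellen DASH totals of at least 4.5 are DASH-consistent (returns a
#' logical).  HEI-2015: below 60 `low`, 60-69 `moderate`, 70-79 `good`,
#' 80-89 `high`, 90-100 `extremely_high`.  AHEI-2010 adds `perfect` above
#' 100 points.  Bands partition the full score range; non-integer totals
#' fall in the band of their containing interval.
#'
#' @param total Numeric vector of index totals.
#' @return Character vector of classes (`classify_dash()`: logical).
#' @name adherence-classes
NULL

#' Score a cohort against all four diet-quality indices
#'
#' Runs [score_hdi2015()], [score_dash_mellen()], [score_hei2015()] and
#' [score_ahei2010()] on a mean-intake table and binds the component scores
#' into one long tibble.
#'
#' @inheritParams score_hdi2015
#' @param sodium_deciles `"cohort"` to derive AHEI sodium cutoffs from this
#'   cohort's sodium distribution, `"fixed"` for the published reference
#'   cutoffs.
#' @return A long tibble of component scores for all indices.
#' @export
score_indices <- function(intake, sodium_deciles = c("cohort", "fixed")) {
  sodium_deciles <- match.arg(sodium_deciles)
  cutoffs <- sodium_decile_cutoffs(
    intake$sodium,
    mode = if (sodium_deciles == "cohort") "cohort_empirical" else "fixed_reference"
  )
  dplyr::bind_rows(
    score_hdi2015(intake),
    score_dash_mellen(intake),
    score_hei2015(intake),
    score_ahei2010(intake, cutoffs)
  )
}

#' Index totals and adherence classes from component scores
#'
#' Sums component points per participant and index and attaches the
#' adherence classification.  For the DASH index the class is
#' `"consistent"`/`"not_consistent"`; `above_low` and `good_or_high`
#' logical columns give the cross-index comparable adherence levels used by
#' the concordance summary (for DASH, consistency fills both).
#'
#' @param scores A long component-score tibble (e.g. from [score_indices()]).
#' @param dash_boundary Passed to [classify_dash()].
#' @return A tibble: `participant_id`, `index`, `total`, `adherence`,
#'   `above_low`, `good_or_high`.
#' @export
index_totals <- function(scores, dash_boundary = c("ge", "gt")) {
  dash_boundary <- match.arg(dash_boundary)
  totals <- dplyr::summarise(
    dplyr::group_by(scores, .data$participant_id, .data$index),
    total = sum(.data$points), .groups = "drop"
  )
  classify_one <- function(index, total) {
    switch(index,
      HDI2015 = classify_hdi(total),
      DASH_MELLEN = ifelse(classify_dash(total, dash_boundary),
                           "consistent", "not_consistent"),
      HEI2015 = classify_hei(total),
      AHEI2010 = classify_ahei(total),
      rlang::abort(paste0("unknown index: ", index),
                   class = "dietquality_contract_error")
    )
  }
  totals$adherence <- unlist(Map(classify_one, totals$index, totals$total),
                             use.names = FALSE)
  totals$above_low <- !(totals$adherence %in% c("low", "not_consistent"))
  totals$good_or_high <- totals$adherence %in%
    c("high", "good", "extremely_high", "perfect", "consistent")
  totals
}

#' Cross-index adherence concordance
#'
#' For each listed index subset, the percentage of participants that are
#' simultaneously above low adherence on every index of the subset, the
#' percentage simultaneously at good-or-high adherence, and the complement
#' (low on at least one).  DASH consistency counts as above-low and
#' good-or-high; for the HDI the good-or-high level is the `high` band.
#'
#' @param totals An [index_totals()] tibble covering all four indices for
#'   every participant.
#' @param subsets Named list of index-name character vectors; the default
#'   reproduces the subsets of the published concordance summary.
#' @return A tibble: `subset`, `indices`, `n`, `pct_low_on_any`,
#'   `pct_above_low_all`, `pct_good_or_high_all`.
#' @export
concordance_table <- function(totals, subsets = NULL) {
  if (is.null(subsets)) {
    subsets <- list(
      "4 indices: AHEI-2010, HDI-2015, HEI-2015, DASH" =
        c("AHEI2010", "HDI2015", "HEI2015", "DASH_MELLEN"),
      "3 indices: DASH, HDI-2015, HEI-2015" =
        c("DASH_MELLEN", "HDI2015", "HEI2015"),
      "2 indices: DASH, HDI-2015" = c("DASH_MELLEN", "HDI2015"),
      "2 indices: DASH, HEI-2015" = c("DASH_MELLEN", "HEI2015"),
      "2 indices: HDI-2015, HEI-2015" = c("HDI2015", "HEI2015")
    )
  }
  participants <- unique(totals$participant_id)
  have <- tapply(totals$index, totals$participant_id,
                 function(x) length(unique(x)))
  needed <- unique(unlist(subsets))
  missing <- setdiff(needed, unique(totals$index))
  if (length(missing) > 0 ||
      any(have < length(unique(totals$index)))) {
    rlang::abort("every participant needs a classification for every index",
                 class = "dietquality_contract_error")
  }
  purrr::imap_dfr(subsets, function(indices, label) {
    sub <- totals[totals$index %in% indices, ]
    by_p <- dplyr::summarise(
      dplyr::group_by(sub, .data$participant_id),
      all_above_low = all(.data$above_low),
      all_good_high = all(.data$good_or_high),
      .groups = "drop"
    )
    n <- nrow(by_p)
    tibble::tibble(
      subset = label,
      indices = paste(indices, collapse = "+"),
      n = n,
      pct_low_on_any = 100 * mean(!by_p$all_above_low),
      pct_above_low_all = 100 * mean(by_p$all_above_low),
      pct_good_or_high_all = 100 * mean(by_p$all_good_high)
    )
  })
}

#' Adherence distribution of a scored cohort
#'
#' Percentage of participants in each adherence band, per index — the
#' summary behind the published adherence tables and bar charts.
#'
#' @inheritParams concordance_table
#' @return A tibble: `index`, `adherence`, `n`, `pct`.
#' @export
adherence_distribution <- function(totals) {
  dplyr::mutate(
    dplyr::count(totals, .data$index, .data$adherence),
    pct = 100 * .data$n / length(unique(totals$participant_id))
  )
}
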