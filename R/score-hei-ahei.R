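#' Linear proration between a zero-score and a full-score criterion
#'
#' The HEI-2015 and AHEI-2010 award full component points at or beyond a
#' favorable criterion, zero at or beyond an unfavorable one, and prorate
#' linearly in between.  `prorate()` implements that two-point interpolation
#' for both orientations (`at_zero` may exceed `at_max` for "less is better"
#' components).
#'
#' @param x Observed value(s).
#' @param at_zero Value at/beyond which the component scores 0.
#' @param at_max Value at/beyond which the component scores `max_points`.
#' @param max_points Component maximum.
#' @return Numeric score(s) in `[0, max_points]`.
#' @export
prorate <- function(x, at_zero, at_max, max_points) {
  frac <- (x - at_zero) / (at_max - at_zero)
  max_points * pmin(1, pmax(0, frac))
}

#' Healthy Eating Index 2015 component scores
#'
#' Thirteen components on per-1000 kcal food-group densities and
#' percent-of-energy quantities, each linearly prorated between its printed
#' minimum- and maximum-score criteria: nine adequacy components (total
#' fruits, whole fruits, total vegetables, greens and beans, whole grains,
#' dairy, total protein foods, seafood and plant proteins, fatty-acid ratio)
#' and four moderation components (refined grains, sodium, added sugars,
#' saturated fats).  A diet with zero saturated fat is treated as meeting the
#' fatty-acid-ratio maximum criterion.
#'
#' @inheritParams score_hdi2015
#' @return A long component-score tibble (see [score_hdi2015()]).
#' @export
score_hei2015 <- function(intake) {
  check_energy(intake)
  ratio <- ifelse(is.finite(intake$pufa_mufa_sfa_ratio),
                  intake$pufa_mufa_sfa_ratio, 2.5)
  score_tbl(
    intake, "HEI2015",
    component = c("total_fruits", "whole_fruits", "total_vegetables",
                  "greens_and_beans", "whole_grains", "dairy",
                  "total_protein", "seafood_plant_protein",
                  "fatty_acid_ratio", "refined_grains", "sodium",
                  "added_sugars", "saturated_fats"),
    points = list(
      prorate(intake$dens_fruit_cupeq, 0, 0.8, 5),
      prorate(intake$dens_whole_fruit_cupeq, 0, 0.4, 5),
      prorate(intake$dens_veg_cupeq, 0, 1.1, 5),
      prorate(intake$dens_green_cupeq, 0, 0.2, 5),
      prorate(intake$dens_whole_grain_ozeq, 0, 1.5, 10),
      prorate(intake$dens_lowfat_dairy_cupeq, 0, 1.3, 10),
      prorate(intake$dens_lean_protein_ozeq, 0, 2.5, 5),
      prorate(intake$dens_seafood_plant_cupeq, 0, 0.8, 5),
      prorate(ratio, 1.2, 2.5, 10),
      prorate(intake$dens_refined_grain_ozeq, 4.3, 1.8, 10),
      prorate(intake$dens_na / 1000, 2.0, 1.1, 10),
      prorate(intake$pe_added_sugar, 26, 6.5, 10),
      prorate(intake$pe_sfa, 16, 8, 10)
    ),
    max_points = c(5, 5, 5, 5, 10, 10, 5, 5, 10, 10, 10, 10, 10)
  )
}

#' @rdname adherence-classes
#' @export
classify_hei <- function(total) {
  if (any(total < 0 | total > 100)) {
    rlang::abort("HEI-2015 total out of [0, 100]",
                 class = "dietquality_contract_error")
  }
  dplyr::case_when(total >= 90 ~ "extremely_high",
                   total >= 80 ~ "high",
                   total >= 70 ~ "good",
                   total >= 60 ~ "moderate",
                   TRUE ~ "low")
}

#' Cohort sodium decile cutoffs for the AHEI-2010 sodium component
#'
#' The AHEI-2010 scores sodium against the studied population's lowest and
#' highest deciles.  `cohort_empirical` mode computes the 10th and 90th
#' percentiles (linear-interpolation definition) of the supplied per-
#' participant sodium intakes; `fixed_reference` mode returns the published
#' cutoffs of the shift-midwife cohort, 1279.47 and 2840.26 mg/d.  Fewer than
#' 10 values in empirical mode falls back to the fixed cutoffs with a
#' warning.
#'
#' @param cohort_sodium Numeric vector of per-participant sodium intakes
#'   (mg/d); may be `NULL` in fixed mode.
#' @param mode `"cohort_empirical"` or `"fixed_reference"`.
#' @return A list with `low_cutoff`, `high_cutoff` (mg/d) and `source`.
#' @export
sodium_decile_cutoffs <- function(cohort_sodium = NULL,
                                  mode = c("cohort_empirical",
                                           "fixed_reference")) {
  mode <- match.arg(mode)
  if (mode == "cohort_empirical" && length(cohort_sodium) < 10) {
    rlang::warn(paste0("fewer than 10 sodium values (",
                       length(cohort_sodium),
                       "); falling back to fixed reference deciles"))
    mode <- "fixed_reference"
  }
  if (mode == "fixed_reference") {
    list(low_cutoff = 1279.47, high_cutoff = 2840.26,
         source = "fixed_reference")
  } else {
    q <- stats::quantile(cohort_sodium, c(0.1, 0.9), names = FALSE, type = 7)
    list(low_cutoff = q[1], high_cutoff = q[2], source = "cohort_empirical")
  }
}

# AHEI-2010 alcohol component: 10 points in the moderate band
# 0.5-1.5 drinks/d, 0 at >= 2.5, linear in between on both sides, and a flat
# 2.5 points for non-drinkers.
ahei_alcohol_points <- function(drinks) {
  ifelse(drinks == 0, 2.5,
    ifelse(drinks < 0.5, 2.5 + (10 - 2.5) * drinks / 0.5,
      ifelse(drinks <= 1.5, 10,
        ifelse(drinks < 2.5, 10 * (2.5 - drinks), 0))))
}

#' Alternative Healthy Eating Index 2010 component scores
#'
#' Eleven components, each linearly prorated between its printed criteria:
#' vegetables, fruits, whole grains, nuts and legumes, EPA+DHA and PUFA %E
#' (more is better); sugar-sweetened beverages and juice, red/processed
#' meat, trans fat %E and sodium (less is better, sodium against the cohort
#' decile cutoffs); and alcohol with a moderate-intake optimum and 2.5
#' points for non-drinkers.
#'
#' @inheritParams score_hdi2015
#' @param cutoffs Sodium decile cutoffs from [sodium_decile_cutoffs()].
#' @return A long component-score tibble (see [score_hdi2015()]).
#' @export
score_ahei2010 <- function(intake, cutoffs = sodium_decile_cutoffs(intake$sodium)) {
  check_energy(intake)
  if (cutoffs$low_cutoff == cutoffs$high_cutoff) {
    rlang::warn("degenerate sodium decile cutoffs; sodium component set to 5")
    sodium_points <- rep(5, nrow(intake))
  } else {
    sodium_points <- prorate(intake$sodium, cutoffs$high_cutoff,
                             cutoffs$low_cutoff, 10)
  }
  score_tbl(
    intake, "AHEI2010",
    component = c("vegetables", "fruits", "whole_grains", "ssb_juice",
                  "nuts_legumes", "red_processed_meat", "trans_fat",
                  "epa_dha", "pufa", "sodium", "alcohol"),
    points = list(
      prorate(intake$veg_servings, 0, 5, 10),
      prorate(intake$fruit_servings, 0, 4, 10),
      prorate(intake$whole_grain_g, 0, 75, 10),
      prorate(intake$ssb_servings, 1, 0, 10),
      prorate(intake$nuts_legume_servings, 0, 1, 10),
      prorate(intake$red_processed_meat_servings, 1.5, 0, 10),
      prorate(intake$pe_trans, 4, 0.5, 10),
      prorate(intake$epa_dha, 0, 250, 10),
      prorate(intake$pe_pufa, 2, 10, 10),
      sodium_points,
      ahei_alcohol_points(intake$alcohol_drinks)
    ),
    max_points = rep(10, 11)
  )
}

#' @rdname adherence-classes
#' @export
classify_ahei <- function(total) {
  if (any(total < 0 | total > 110)) {
    rlang::abort("AHEI-2010 total out of [0, 110]",
                 class = "dietquality_contract_error")
  }
  dplyr::case_when(total > 100 ~ "perfect",
                   total >= 90 ~ "extremely_high",
                   total >= 80 ~ "high",
                   total >= 70 ~ "good",
                   total >= 60 ~ "moderate",
                   TRUE ~ "low")
}
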