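#' Conventional energy-conversion (Atwater) factors
#'
#' kcal per gram of protein, carbohydrate and fat, and per gram of ethanol.
#' Free and added sugars use the carbohydrate factor.
#'
#' @return Named numeric vector.
#' @export
atwater_factors <- function() {
  c(protein = 4, carbohydrate = 4, fat = 9, alcohol = 7)
}

#' Collapse meal records to day totals
#'
#' Sums every nutrient and food-group amount over the eating occasions of
#' each participant-day and derives the day-level quantities the analysis
#' uses: the meal count (between-meal snacks excluded by default), breakfast
#' energy, energy eaten as between-meal snacks, and the energy contributed by
#' sweets (derived from sweets mass at `sweets_kcal_per_g`).
#'
#' @param diary A validated diary tibble (see [validate_diary()]).
#' @param count_snacks_as_meals Count between-meal snacks in `n_meals`?
#' @param sweets_kcal_per_g Energy density used to convert sweets mass to
#'   sweets energy; the default 3 kcal/g reconciles typical cake/confectionery
#'   composition with the cohort-level share of energy from sweets.
#' @return A tibble with one row per participant-day: the summed diary
#'   amounts plus `n_meals`, `breakfast_energy`, `snack_energy` and
#'   `sweets_energy`.
#' @export
day_totals <- function(diary, count_snacks_as_meals = FALSE,
                       sweets_kcal_per_g = 3) {
  if (nrow(diary) == 0) {
    rlang::abort("diary has no records", class = "dietquality_contract_error")
  }
  diary <- validate_diary(diary, check_structure = FALSE)
  nums <- diary_numeric_cols()
  out <- dplyr::summarise(
    dplyr::group_by(diary, .data$participant_id, .data$day_type),
    n_meals = if (count_snacks_as_meals) dplyr::n() else sum(!.data$is_snack),
    breakfast_energy = sum(.data$energy[.data$meal_slot == "breakfast"]),
    snack_energy = sum(.data$energy[.data$is_snack]),
    dplyr::across(dplyr::all_of(nums), sum),
    .groups = "drop"
  )
  out$sweets_energy <- sweets_kcal_per_g * out$sweets_g
  out
}

#' Per-participant 3-day mean intake with derived shares and densities
#'
#' Averages the three diary days of each participant (unweighted) and derives
#' the quantities the diet-quality indices and group splits consume:
#' percent-of-energy (%E) shares via Atwater factors, per-1000 kcal nutrient
#' and food-group densities, and the (PUFA+MUFA)/SFA percent-energy ratio.
#'
#' %E shares are computed on the 3-day means, e.g.
#' `pe_fat = 100 * 9 * mean(fat) / mean(energy)`, and densities as
#' `dens_x = 1000 * mean(x) / mean(energy)`.
#'
#' @param days A day-totals tibble from [day_totals()] with exactly one
#'   morning-shift, night-shift and off day per participant.
#' @param atwater Named energy factors, see [atwater_factors()].
#' @param alcohol_g_per_drink Grams of ethanol counted per reported drink
#'   when attributing alcohol energy (default 10 g).
#' @return A tibble with one row per participant: every day-level field
#'   averaged, plus `pe_*` shares, `dens_*` densities and
#'   `pufa_mufa_sfa_ratio`.
#' @export
participant_means <- function(days, atwater = atwater_factors(),
                              alcohol_g_per_drink = 10) {
  counts <- dplyr::count(days, .data$participant_id, .data$day_type)
  per_p <- tapply(counts$n, counts$participant_id, sum)
  n_types <- tapply(counts$day_type, counts$participant_id,
                    function(x) length(unique(x)))
  if (any(per_p != 3) || any(n_types != 3)) {
    rlang::abort(
      "each participant must contribute exactly one day of each day type",
      class = "dietquality_contract_error"
    )
  }
  num_cols <- setdiff(names(days)[vapply(days, is.numeric, logical(1))],
                      "participant_id")
  means <- dplyr::summarise(
    dplyr::group_by(days, .data$participant_id),
    dplyr::across(dplyr::all_of(num_cols), mean),
    .groups = "drop"
  )
  if (any(means$energy <= 0)) {
    rlang::abort("participant with zero mean energy intake",
                 class = "dietquality_degenerate_error")
  }
  e <- means$energy
  pe <- function(grams, factor) 100 * factor * grams / e
  dens <- function(x) 1000 * x / e

  means$pe_protein <- pe(means$protein, atwater[["protein"]])
  means$pe_fat <- pe(means$fat, atwater[["fat"]])
  means$pe_sfa <- pe(means$sfa, atwater[["fat"]])
  means$pe_mufa <- pe(means$mufa, atwater[["fat"]])
  means$pe_pufa <- pe(means$pufa, atwater[["fat"]])
  means$pe_trans <- pe(means$trans_fat, atwater[["fat"]])
  means$pe_carbohydrate <- pe(means$carbohydrate, atwater[["carbohydrate"]])
  means$pe_free_sugar <- pe(means$free_sugar, atwater[["carbohydrate"]])
  means$pe_added_sugar <- pe(means$added_sugar, atwater[["carbohydrate"]])
  means$pe_alcohol <- pe(means$alcohol_drinks * alcohol_g_per_drink,
                         atwater[["alcohol"]])
  means$pe_sweets <- 100 * means$sweets_energy / e
  means$pe_snacking <- 100 * means$snack_energy / e
  means$pe_breakfast <- 100 * means$breakfast_energy / e

  means$dens_fiber <- dens(means$fiber)
  means$dens_na <- dens(means$sodium)
  means$dens_k <- dens(means$potassium)
  means$dens_ca <- dens(means$calcium)
  means$dens_mg <- dens(means$magnesium)
  means$dens_chol <- dens(means$cholesterol)
  means$dens_fruit_cupeq <- dens(means$fruit_cupeq)
  means$dens_whole_fruit_cupeq <- dens(means$whole_fruit_cupeq)
  means$dens_veg_cupeq <- dens(means$veg_cupeq)
  means$dens_green_cupeq <- dens(means$green_veg_legume_cupeq)
  means$dens_lowfat_dairy_cupeq <- dens(means$lowfat_dairy_cupeq)
  means$dens_seafood_plant_cupeq <- dens(means$seafood_plant_protein_cupeq)
  means$dens_whole_grain_ozeq <- dens(means$whole_grain_ozeq)
  means$dens_refined_grain_ozeq <- dens(means$refined_grain_ozeq)
  means$dens_lean_protein_ozeq <- dens(means$lean_protein_ozeq)

  # the Atwater fat factor cancels in the percent-energy ratio
  means$pufa_mufa_sfa_ratio <- ifelse(
    means$sfa > 0, (means$pufa + means$mufa) / means$sfa, Inf
  )
  means
}

#' Per-day dietary habit flags
#'
#' Day-level presence/absence of the habits compared across shift-day types:
#' eating processed meat, eating sweets, snacking between meals, and
#' sweetening beverages (positive added sugar).  A flag is `TRUE` iff the
#' day's amount is positive.
#'
#' @param days A day-totals tibble from [day_totals()].
#' @return A tibble keyed by `participant_id` and `day_type` with logical
#'   columns `consumed_processed_meat`, `consumed_sweets`, `snacked` and
#'   `sweetened_beverage`.
#' @export
habit_flags <- function(days) {
  inconsistent <- days$sweets_g == 0 & days$sweets_energy > 0
  if (any(inconsistent)) {
    rlang::abort(
      paste0("sweets energy recorded without sweets mass (rows ",
             paste(which(inconsistent), collapse = ", "), ")"),
      class = "dietquality_validation_error"
    )
  }
  tibble::tibble(
    participant_id = days$participant_id,
    day_type = days$day_type,
    consumed_processed_meat = days$processed_meat_g > 0,
    consumed_sweets = days$sweets_g > 0,
    snacked = days$snack_energy > 0,
    sweetened_beverage = days$added_sugar > 0
  )
}
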