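#' Serving-size conversion table
#'
#' Gram (or mL) weights of one cup-equivalent, oz-equivalent or serving used
#' to derive the index food-group units from recorded masses, standing in
#' for a full food-equivalents database.  Shipped as
#' `inst/extdata/serving_sizes.csv` and returned here as a named vector.
#'
#' @return Named numeric vector of grams (mL for beverages) per unit.
#' @export
serving_sizes <- function() {
  path <- system.file("extdata", "serving_sizes.csv", package = "dietquality")
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  stats::setNames(tbl$grams_per_unit, tbl$unit)
}

# mean of a normal truncated below at 0
truncnorm0_mean <- function(loc, scale) {
  a <- -loc / scale
  loc + scale * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
}

# location parameter giving a zero-truncated normal the target mean
truncnorm0_location <- function(target_mean, scale) {
  if (scale <= 0) return(target_mean)
  stats::uniroot(function(l) truncnorm0_mean(l, scale) - target_mean,
                 lower = target_mean - 20 * scale, upper = target_mean,
                 extendInt = "upX", tol = 1e-9)$root
}

# inverse-CDF sampler of a truncated normal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(rep(mean, n))
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Synthetic shift-worker cohort configuration
#'
#' The stated world of the generator: a 50-participant cohort keeping a
#' 3-day diary (one morning shift, one night shift, one day off), with the
#' published per-item intake distributions (mean, SD, and a zero-inflation
#' probability equal to one minus the reported consumer fraction where one
#' was reported), a 4.78 +/- 0.94 daily meal count, 70% daily snackers, 56%
#' sweets consumers and 44% beverage sweeteners, and day-type effects
#' defaulting to 1 (habits stable across the shift schedule).  Item amounts
#' are drawn zero-inflated truncated-normal with the positive part's
#' location calibrated so the cohort mean matches the configured mean.
#'
#' @param n_participants Cohort size.
#' @param seed Integer seed; `NULL` draws one at generation time.
#' @param items Data frame overriding the per-item table: columns `item`
#'   (diary column name), `mean`, `sd`, `zero_inflation`, `latent`.
#' @param day_type_effects Optional named list of per-day multiplier vectors,
#'   e.g. `list(night_shift = c(sweets_g = 1.3))`.
#' @param ... Scalar overrides of the remaining defaults (see the returned
#'   list for names).
#' @return A list of class `dietquality_cohort_config`.
#' @export
cohort_config <- function(n_participants = 50, seed = NULL, items = NULL,
                          day_type_effects = list(), ...) {
  if (is.null(items)) {
    items <- tibble::tribble(
      ~item,              ~mean,   ~sd,    ~zero_inflation, ~latent,
      "added_sugar",        9.00,  13.10,  0.56, FALSE,
      "ssb_ml",            41.28, 158.40,  0.80, FALSE,
      "sweets_g",          70.60, 108.83,  0.44, FALSE,
      "caffeine",         147.27, 100.56,  0.10, FALSE,
      "processed_meat_g",  52.96,  59.14,  0.36, FALSE,
      "vegetable_g",      442.50, 234.99,  0.02, FALSE,
      "fruit_g",          250.54, 233.11,  0.10, FALSE,
      "fish_g",            14.88,  42.09,  0.88, FALSE,
      "nuts_seeds_g",       6.88,  21.54,  0.84, FALSE,
      "natural_dairy_g",  185.41, 165.54,  0.18, FALSE,
      "legume_g",           4.49,  18.14,  0.86, FALSE,
      "whole_grain_g",     30.00,  35.00,  0.55, FALSE,
      "salty_snack_g",      4.00,   8.00,  0.50, FALSE,
      "eggs_g",            26.31,  45.61,  0.70, TRUE,
      "red_meat_g",        30.00,  35.00,  0.30, TRUE,
      "lean_meat_g",       50.00,  45.00,  0.25, TRUE,
      "refined_grain_g",  150.00,  60.00,  0.02, TRUE
    )
  }
  cfg <- list(
    n_participants = n_participants,
    seed = seed,
    items = items,
    item_day_prob = 0.9,
    day_type_effects = day_type_effects,
    meal_count_mean = 4.78, meal_count_sd = 0.94, meal_count_min = 1,
    snacker_fraction = 0.70,
    sweets_consumer_fraction = 0.56,
    sweetened_beverage_fraction = 0.44,
    drinker_fraction = 0.08,
    energy_mean = 1870, energy_sd = 470, energy_day_sd = 180,
    energy_min = 900,
    pe_fat_mean = 33, pe_fat_sd = 5,
    pe_protein_mean = 16, pe_protein_sd = 2.5,
    pe_sfa_mean = 12.5, pe_sfa_sd = 2.5,
    pe_pufa_mean = 5, pe_pufa_sd = 1.8,
    pe_trans_mean = 0.6, pe_trans_sd = 0.35,
    snack_share_mean = 0.186, snack_share_sd = 0.09,
    sweets_kcal_per_g = 3,
    alcohol_g_per_drink = 10
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(paste0("unknown config field(s): ",
                        paste(unknown, collapse = ", ")),
                 class = "dietquality_config_error")
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "dietquality_cohort_config")
}

validate_config <- function(cfg) {
  probs <- c(cfg$items$zero_inflation, cfg$item_day_prob,
             cfg$snacker_fraction, cfg$sweets_consumer_fraction,
             cfg$sweetened_beverage_fraction, cfg$drinker_fraction)
  if (any(probs < 0 | probs > 1)) {
    rlang::abort("probabilities must lie in [0, 1]",
                 class = "dietquality_config_error")
  }
  if (any(cfg$items$sd < 0) || any(cfg$items$mean < 0)) {
    rlang::abort("item means and sds must be non-negative",
                 class = "dietquality_config_error")
  }
  if (cfg$n_participants < 1) {
    rlang::abort("n_participants must be at least 1",
                 class = "dietquality_config_error")
  }
  if (cfg$pe_fat_mean + cfg$pe_protein_mean >= 95) {
    rlang::abort("macronutrient energy shares are infeasible",
                 class = "dietquality_config_error")
  }
  invisible(cfg)
}

#' Generate a synthetic shift-worker diary cohort
#'
#' Draws a full meal-level diary for `n_participants` x 3 day types under
#' the configured world (see [cohort_config()]).  Daily item amounts are
#' zero-inflated truncated-normal with consumer status fixed per
#' participant; macronutrient grams are derived from per-participant energy
#' shares so that energy equals the Atwater sum of macronutrients plus
#' alcohol exactly; amounts are allocated across the day's meal slots
#' proportionally to each meal's energy share.  Breakfast is always present;
#' further slots fill in the order lunch, brunch, afternoon snack, supper,
#' so supper is the most commonly missed meal.  Output is deterministic for
#' a fixed seed.
#'
#' @param config A [cohort_config()] object.
#' @return A list with `diary` (validated meal-record tibble), `anthro`
#'   (per-participant anthropometric sidecar: age, BMI, waist, body fat,
#'   visceral fat level, hospital), `report` (a [generator_report()] tibble
#'   computed from the emitted diary) and `seed`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  cfg <- validate_config(config)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  seed <- cfg$seed
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  set.seed(seed)

  n <- cfg$n_participants
  sv <- serving_sizes()
  pid <- sprintf("P%03d", seq_len(n))
  days <- tidyr::expand_grid(participant_id = pid, day_type = day_types())
  nd <- nrow(days)
  p_idx <- match(days$participant_id, pid)

  # --- participant-level latent traits -------------------------------------
  energy_base <- rtruncnorm(n, cfg$energy_mean, cfg$energy_sd,
                            lower = cfg$energy_min)
  pe_fat_p <- rtruncnorm(n, cfg$pe_fat_mean, cfg$pe_fat_sd, 18, 55)
  pe_protein_p <- rtruncnorm(n, cfg$pe_protein_mean, cfg$pe_protein_sd, 10, 28)
  pe_sfa_p <- rtruncnorm(n, cfg$pe_sfa_mean, cfg$pe_sfa_sd, 4, 25)
  pe_pufa_p <- rtruncnorm(n, cfg$pe_pufa_mean, cfg$pe_pufa_sd, 1.5, 14)
  pe_trans_p <- rtruncnorm(n, cfg$pe_trans_mean, cfg$pe_trans_sd, 0, 2.5)
  snacker <- stats::runif(n) < cfg$snacker_fraction
  drinker <- stats::runif(n) < cfg$drinker_fraction
  drink_day <- sample(day_types(), n, replace = TRUE)
  whole_fruit_share <- stats::rbeta(n, 4, 2)
  green_share <- stats::rbeta(n, 1.5, 8)
  lowfat_share <- stats::rbeta(n, 3, 2)

  # --- day-level energy and snack share ------------------------------------
  energy <- rtruncnorm(nd, 0, cfg$energy_day_sd) + energy_base[p_idx]
  energy <- pmax(energy, cfg$energy_min)
  q_snack <- ifelse(snacker[p_idx],
                    rtruncnorm(nd, cfg$snack_share_mean, cfg$snack_share_sd,
                               0.02, 0.55), 0)

  # --- item amounts ---------------------------------------------------------
  items <- cfg$items
  item_amounts <- matrix(0, nd, nrow(items),
                         dimnames = list(NULL, items$item))
  for (j in seq_len(nrow(items))) {
    it <- items[j, ]
    consumer <- stats::runif(n) < (1 - it$zero_inflation)
    eats_today <- consumer[p_idx] & stats::runif(nd) < cfg$item_day_prob
    target <- it$mean / max(1e-12, (1 - it$zero_inflation) * cfg$item_day_prob)
    loc <- truncnorm0_location(target, it$sd)
    amt <- ifelse(eats_today, rtruncnorm(nd, loc, it$sd, lower = 0), 0)
    item_amounts[, j] <- amt
  }
  for (dt in names(cfg$day_type_effects)) {
    eff <- cfg$day_type_effects[[dt]]
    rows <- days$day_type == dt
    for (col in names(eff)) {
      item_amounts[rows, col] <- item_amounts[rows, col] * eff[[col]]
    }
  }
  itm <- function(col) item_amounts[, col]

  # keep sweets energy inside the day's energy budget
  sweets_g <- pmin(itm("sweets_g"), 0.6 * energy / cfg$sweets_kcal_per_g)

  # --- macronutrient bookkeeping (exact Atwater identity) -------------------
  drinks <- ifelse(drinker[p_idx] & days$day_type == drink_day[p_idx],
                   rtruncnorm(nd, 1.2, 0.6, 0.2, 3), 0)
  pe_alcohol <- 100 * 7 * cfg$alcohol_g_per_drink * drinks / energy
  pe_fat <- pmax(15, pe_fat_p[p_idx] + stats::rnorm(nd, 0, 1.2))
  pe_protein <- pmax(8, pe_protein_p[p_idx] + stats::rnorm(nd, 0, 0.8))
  pe_carb <- 100 - pe_fat - pe_protein - pe_alcohol
  pe_sfa <- pe_sfa_p[p_idx]
  pe_pufa <- pe_pufa_p[p_idx]
  pe_trans <- pe_trans_p[p_idx]
  over <- (pe_sfa + pe_pufa + pe_trans) > 0.95 * pe_fat
  shrink <- ifelse(over, 0.95 * pe_fat / (pe_sfa + pe_pufa + pe_trans), 1)
  pe_sfa <- pe_sfa * shrink
  pe_pufa <- pe_pufa * shrink
  pe_trans <- pe_trans * shrink

  fat <- pe_fat * energy / 900
  protein <- pe_protein * energy / 400
  carbohydrate <- pe_carb * energy / 400
  sfa <- pe_sfa * energy / 900
  pufa <- pe_pufa * energy / 900
  trans_fat <- pe_trans * energy / 900
  mufa <- fat - sfa - pufa - trans_fat

  free_sugar <- pmin(itm("added_sugar") + 0.45 * sweets_g + 0.10 * itm("ssb_ml"),
                     0.9 * carbohydrate)
  added_sugar <- pmin(itm("added_sugar"), free_sugar)
  fiber <- 0.02 * itm("vegetable_g") + 0.015 * itm("fruit_g") +
    0.07 * itm("whole_grain_g") + rtruncnorm(nd, 6, 2, 1)

  # --- micronutrients -------------------------------------------------------
  sodium <- rtruncnorm(nd, 1900, 600, 300)
  potassium <- rtruncnorm(nd, 3400, 900, 800)
  calcium <- rtruncnorm(nd, 650, 300, 100)
  magnesium <- rtruncnorm(nd, 330, 100, 80)
  cholesterol <- rtruncnorm(nd, 300, 130, 30)
  epa_dha <- 12 * itm("fish_g") + rtruncnorm(nd, 25, 20, 0)

  # --- derived equivalents and servings ------------------------------------
  whole_fruit_g <- whole_fruit_share[p_idx] * itm("fruit_g")
  green_veg_legume_g <- green_share[p_idx] * itm("vegetable_g") + itm("legume_g")

  day_tbl <- tibble::tibble(
    participant_id = days$participant_id,
    day_type = days$day_type,
    energy = energy,
    protein = protein, fat = fat, sfa = sfa, mufa = mufa, pufa = pufa,
    trans_fat = trans_fat, carbohydrate = carbohydrate,
    free_sugar = free_sugar, added_sugar = added_sugar, fiber = fiber,
    epa_dha = epa_dha, cholesterol = cholesterol, sodium = sodium,
    potassium = potassium, calcium = calcium, magnesium = magnesium,
    caffeine = itm("caffeine"),
    fruit_g = itm("fruit_g"), whole_fruit_g = whole_fruit_g,
    vegetable_g = itm("vegetable_g"),
    green_veg_legume_g = green_veg_legume_g,
    whole_grain_g = itm("whole_grain_g"),
    processed_meat_g = itm("processed_meat_g"), fish_g = itm("fish_g"),
    nuts_seeds_g = itm("nuts_seeds_g"), legume_g = itm("legume_g"),
    natural_dairy_g = itm("natural_dairy_g"), sweets_g = sweets_g,
    salty_snack_g = itm("salty_snack_g"),
    fruit_cupeq = itm("fruit_g") / sv[["fruit_g_per_cupeq"]],
    whole_fruit_cupeq = whole_fruit_g / sv[["fruit_g_per_cupeq"]],
    veg_cupeq = itm("vegetable_g") / sv[["veg_g_per_cupeq"]],
    green_veg_legume_cupeq = green_veg_legume_g / sv[["veg_g_per_cupeq"]],
    lowfat_dairy_cupeq = lowfat_share[p_idx] * itm("natural_dairy_g") /
      sv[["dairy_g_per_cupeq"]],
    seafood_plant_protein_cupeq =
      (itm("fish_g") + itm("nuts_seeds_g") + itm("legume_g")) /
      sv[["seafood_plant_g_per_cupeq"]],
    whole_grain_ozeq = itm("whole_grain_g") / sv[["grain_g_per_ozeq"]],
    refined_grain_ozeq = itm("refined_grain_g") / sv[["grain_g_per_ozeq"]],
    lean_protein_ozeq = (itm("eggs_g") + itm("lean_meat_g")) /
      sv[["lean_protein_g_per_ozeq"]],
    ssb_ml = itm("ssb_ml"),
    ssb_servings = itm("ssb_ml") / sv[["ssb_ml_per_serving"]],
    veg_servings = itm("vegetable_g") / sv[["veg_g_per_serving"]],
    fruit_servings = itm("fruit_g") / sv[["fruit_g_per_serving"]],
    nuts_legume_servings = itm("nuts_seeds_g") / sv[["nuts_g_per_serving"]] +
      itm("legume_g") / sv[["legume_g_per_serving"]],
    red_processed_meat_servings =
      (itm("processed_meat_g") + itm("red_meat_g")) /
      sv[["meat_g_per_serving"]],
    alcohol_drinks = drinks
  )

  # --- spread days over meal slots ------------------------------------------
  n_meals <- pmin(5, pmax(cfg$meal_count_min,
                          round(stats::rnorm(nd, cfg$meal_count_mean,
                                             cfg$meal_count_sd))))
  slot_order <- c("breakfast", "lunch", "brunch", "afternoon_snack", "supper")
  slot_alpha <- c(breakfast = 1.7, lunch = 3.3, brunch = 1.0,
                  afternoon_snack = 1.1, supper = 3.0)

  rows_per_day <- n_meals + as.integer(q_snack > 0)
  row_id <- rep(seq_len(nd), rows_per_day)
  pos <- sequence(rows_per_day)
  is_snack_row <- pos > n_meals[row_id]
  slot <- ifelse(is_snack_row, "between_meal_snack", slot_order[pos])
  w_raw <- ifelse(is_snack_row, 0,
                  stats::rgamma(length(slot),
                                shape = slot_alpha[ifelse(is_snack_row,
                                                          "lunch", slot)]))
  w_tot <- stats::ave(w_raw, row_id, FUN = sum)
  share <- ifelse(is_snack_row, q_snack[row_id],
                  w_raw / w_tot * (1 - q_snack[row_id]))
  scale_cols <- diary_numeric_cols()
  diary <- day_tbl[row_id, ]
  diary[scale_cols] <- diary[scale_cols] * share
  diary$meal_slot <- slot
  diary$is_snack <- is_snack_row
  diary <- validate_diary(diary)

  # --- anthropometric sidecar -----------------------------------------------
  bmi <- rtruncnorm(n, 27.2, 5.5, 17, 45)
  height_cm <- rtruncnorm(n, 164, 6, 148, 185)
  anthro <- tibble::tibble(
    participant_id = pid,
    age = round(rtruncnorm(n, 45, 10.9, 25, 70), 1),
    height_cm = round(height_cm, 1),
    weight_kg = round(bmi * (height_cm / 100)^2, 1),
    bmi = bmi,
    waist_cm = pmax(58, 40 + 1.65 * bmi + stats::rnorm(n, 0, 6)),
    body_fat_pct = pmin(55, pmax(12, 8.5 + 0.92 * bmi + stats::rnorm(n, 0, 3))),
    visceral_fat = round(pmin(14, pmax(1, 0.55 * bmi - 8 +
                                         stats::rnorm(n, 0, 1.5)))),
    hospital = sample(paste0("H", 1:4), n, replace = TRUE)
  )

  list(diary = diary, anthro = anthro,
       report = generator_report(diary, cfg), seed = seed)
}

#' Summarize what a generated cohort actually realized
#'
#' Computes, from an emitted diary (never echoed from the configuration),
#' the cohort mean and SD of each configured non-latent item, the realized
#' fraction of participants snacking on every diary day, and the realized
#' mean daily meal count.
#'
#' @param diary A diary tibble.
#' @param config The [cohort_config()] the diary was generated under (used
#'   only for the item list and sweets energy density).
#' @return A tibble with one row per item plus `snacker_fraction`,
#'   `mean_meal_count` and `mean_energy` attributes columns (`quantity`,
#'   `mean`, `sd`).
#' @export
generator_report <- function(diary, config = cohort_config()) {
  days <- day_totals(diary, sweets_kcal_per_g = config$sweets_kcal_per_g)
  per_p <- dplyr::summarise(
    dplyr::group_by(days, .data$participant_id),
    dplyr::across(dplyr::all_of(setdiff(diary_numeric_cols(),
                                        character(0))), mean),
    n_meals = mean(.data$n_meals),
    snacks_daily = all(.data$snack_energy > 0),
    .groups = "drop"
  )
  items <- config$items[!config$items$latent, ]
  item_stats <- purrr::map_dfr(items$item, function(col) {
    tibble::tibble(quantity = col, mean = mean(per_p[[col]]),
                   sd = stats::sd(per_p[[col]]))
  })
  dplyr::bind_rows(
    item_stats,
    tibble::tibble(quantity = "snacker_fraction",
                   mean = mean(per_p$snacks_daily), sd = NA_real_),
    tibble::tibble(quantity = "mean_meal_count",
                   mean = mean(per_p$n_meals), sd = stats::sd(per_p$n_meals)),
    tibble::tibble(quantity = "mean_energy",
                   mean = mean(per_p$energy), sd = stats::sd(per_p$energy))
  )
}

#' Apply a controlled perturbation to a diary
#'
#' Returns a modified copy of the diary with an additive and/or
#' multiplicative shift applied to one field on the selected rows; all other
#' fields and rows are untouched.  Used for power and recovery studies of
#' the statistical battery.
#'
#' @param diary A diary tibble.
#' @param field Name of the numeric diary column to shift.
#' @param add Additive shift (applied after `mult`), spread over a
#'   participant-day's rows proportionally to their share of the day when
#'   `per_day = TRUE`, else added to every matching row.
#' @param mult Multiplicative shift.
#' @param participants Optional participant-id subset.
#' @param day_types_sel Optional day-type subset.
#' @param per_day Interpret `add` as a per-day amount (default) rather than
#'   per-row.
#' @return The perturbed diary tibble.
#' @export
perturb_cohort <- function(diary, field, add = 0, mult = 1,
                           participants = NULL, day_types_sel = NULL,
                           per_day = TRUE) {
  if (!field %in% diary_numeric_cols()) {
    rlang::abort(paste0("unknown diary field: ", field),
                 class = "dietquality_contract_error")
  }
  rows <- rep(TRUE, nrow(diary))
  if (!is.null(participants)) {
    rows <- rows & diary$participant_id %in% participants
  }
  if (!is.null(day_types_sel)) rows <- rows & diary$day_type %in% day_types_sel
  out <- diary
  out[[field]][rows] <- out[[field]][rows] * mult
  if (add != 0) {
    if (per_day) {
      key <- paste(out$participant_id, out$day_type)
      day_energy <- stats::ave(out$energy, key, FUN = sum)
      out[[field]][rows] <- out[[field]][rows] +
        add * (out$energy[rows] / day_energy[rows])
    } else {
      out[[field]][rows] <- out[[field]][rows] + add
    }
  }
  out
}
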