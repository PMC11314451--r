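check_energy <- function(intake) {
  if (any(intake$energy <= 0)) {
    rlang::abort("mean energy intake must be positive",
                 class = "dietquality_degenerate_error")
  }
}

score_tbl <- function(intake, index, component, points, max_points) {
  tibble::tibble(
    participant_id = rep(intake$participant_id, times = length(component)),
    index = index,
    component = rep(component, each = nrow(intake)),
    points = as.numeric(unlist(points, use.names = FALSE)),
    max_points = rep(max_points, each = nrow(intake))
  )
}

#' Healthy Diet Indicator 2015 component scores
#'
#' Seven binary components on the WHO-based 2015 criteria: one point each for
#' fruit + vegetables above 400 g/d, fat below 30%E, saturated fat below
#' 10%E, polyunsaturated fat within 6-11%E, free sugars below 10%E, fiber
#' above 25 g/d and potassium of at least 3500 mg/d.  Boundary strictness
#' follows the printed criteria exactly (e.g. exactly 400 g scores 0;
#' exactly 3500 mg scores 1).
#'
#' @param intake A mean-intake tibble from [participant_means()].
#' @return A long tibble: `participant_id`, `index`, `component`, `points`,
#'   `max_points`.  Totals via [index_totals()].
#' @export
score_hdi2015 <- function(intake) {
  check_energy(intake)
  score_tbl(
    intake, "HDI2015",
    component = c("fruit_vegetables", "total_fat", "saturated_fat",
                  "polyunsaturated_fat", "free_sugars", "fiber", "potassium"),
    points = list(
      (intake$fruit_g + intake$vegetable_g) > 400,
      intake$pe_fat < 30,
      intake$pe_sfa < 10,
      intake$pe_pufa >= 6 & intake$pe_pufa <= 11,
      intake$pe_free_sugar < 10,
      intake$fiber > 25,
      intake$potassium >= 3500
    ),
    max_points = rep(1, 7)
  )
}

#' @rdname adherence-classes
#' @export
classify_hdi <- function(total) {
  if (any(total < 0 | total > 7)) {
    rlang::abort("HDI-2015 total out of [0, 7]",
                 class = "dietquality_contract_error")
  }
  dplyr::case_when(total >= 6 ~ "high",
                   total >= 4 ~ "moderate",
                   TRUE ~ "low")
}

# 1 / 0.5 / 0 points; `ge` picks at-least thresholds, otherwise at-most.
dash_component <- function(x, full, half, ge = TRUE) {
  if (ge) {
    ifelse(x >= full, 1, ifelse(x >= half, 0.5, 0))
  } else {
    ifelse(x <= full, 1, ifelse(x <= half, 0.5, 0))
  }
}

#' Mellen nutrient-based DASH index component scores
#'
#' Nine components scored 1 / 0.5 / 0 against the nutrient targets of the
#' DASH trial pattern: protein %E, and per-1000 kcal fiber, magnesium,
#' calcium and potassium (more is better); fat %E, saturated fat %E,
#' cholesterol and sodium per 1000 kcal (less is better).  A diet meeting a
#' full target scores 1 on that component, the intermediate band scores 0.5.
#'
#' @inheritParams score_hdi2015
#' @return A long component-score tibble (see [score_hdi2015()]).
#' @export
score_dash_mellen <- function(intake) {
  check_energy(intake)
  score_tbl(
    intake, "DASH_MELLEN",
    component = c("protein", "fiber", "magnesium", "calcium", "potassium",
                  "total_fat", "saturated_fat", "cholesterol", "sodium"),
    points = list(
      dash_component(intake$pe_protein, 18, 16.5),
      dash_component(intake$dens_fiber, 14.8, 9.5),
      dash_component(intake$dens_mg, 238, 158),
      dash_component(intake$dens_ca, 590, 402),
      dash_component(intake$dens_k, 2230, 1534),
      dash_component(intake$pe_fat, 27, 32, ge = FALSE),
      dash_component(intake$pe_sfa, 6, 11, ge = FALSE),
      dash_component(intake$dens_chol, 71.4, 107.1, ge = FALSE),
      dash_component(intake$dens_na, 1143, 1286, ge = FALSE)
    ),
    max_points = rep(1, 9)
  )
}

#' @rdname adherence-classes
#' @param boundary DASH consistency convention: `"ge"` (default; a total of
#'   exactly 4.5 is consistent) or `"gt"` (strictly above 4.5).
#' @export
classify_dash <- function(total, boundary = c("ge", "gt")) {
  boundary <- match.arg(boundary)
  if (any(total < 0 | total > 9)) {
    rlang::abort("DASH total out of [0, 9]",
                 class = "dietquality_contract_error")
  }
  if (boundary == "ge") total >= 4.5 else total > 4.5
}
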