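# Fixtures are built in code: a minimal valid meal record, deterministic
# hand-built diaries, and random-but-valid intake tables for property tests.

meal_record <- function(participant_id = "P1", day_type = "morning_shift",
                        meal_slot = "breakfast", energy = 400, ...) {
  spec <- diary_cols()
  row <- as.list(stats::setNames(rep(0, sum(spec$type == "numeric")),
                                 spec$column[spec$type == "numeric"]))
  row$participant_id <- participant_id
  row$day_type <- day_type
  row$meal_slot <- meal_slot
  row$energy <- energy
  row$is_snack <- meal_slot == "between_meal_snack"
  dots <- list(...)
  stopifnot(all(names(dots) %in% spec$column))
  row[names(dots)] <- dots
  tibble::as_tibble(row)[spec$column]
}

# n participants x 3 day types x `slots` meals, simple consistent nutrients
make_diary <- function(n_participants = 1,
                       slots = c("breakfast", "lunch", "supper",
                                 "afternoon_snack", "between_meal_snack")) {
  rows <- list()
  for (p in seq_len(n_participants)) {
    for (dt in day_types()) {
      for (s in slots) {
        rows[[length(rows) + 1]] <- meal_record(
          participant_id = paste0("P", p), day_type = dt, meal_slot = s,
          energy = 400 + 10 * p, protein = 15, fat = 12, sfa = 4, mufa = 5,
          pufa = 2, trans_fat = 0.1, carbohydrate = 55, free_sugar = 8,
          added_sugar = 3, fiber = 5, sodium = 400, potassium = 700,
          calcium = 150, magnesium = 70, cholesterol = 60,
          fruit_g = 50, whole_fruit_g = 30, vegetable_g = 90,
          sweets_g = 10, processed_meat_g = 12
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

# one intake row with every field the four scorers read; defaults score
# neither best nor worst case
intake_row <- function(participant_id = "P1", ...) {
  row <- tibble::tibble(
    participant_id = participant_id, energy = 2000,
    fruit_g = 200, vegetable_g = 300, fiber = 20, potassium = 3000,
    sodium = 1800,
    pe_fat = 32, pe_sfa = 11, pe_pufa = 5, pe_trans = 1,
    pe_free_sugar = 9, pe_added_sugar = 4, pe_protein = 16,
    dens_fiber = 10, dens_mg = 180, dens_ca = 450, dens_k = 1800,
    dens_chol = 120, dens_na = 900,
    dens_fruit_cupeq = 0.5, dens_whole_fruit_cupeq = 0.25,
    dens_veg_cupeq = 0.8, dens_green_cupeq = 0.1,
    dens_whole_grain_ozeq = 0.6, dens_lowfat_dairy_cupeq = 0.5,
    dens_lean_protein_ozeq = 1.5, dens_seafood_plant_cupeq = 0.3,
    dens_refined_grain_ozeq = 3.0, pufa_mufa_sfa_ratio = 1.6,
    veg_servings = 3, fruit_servings = 2, whole_grain_g = 30,
    ssb_servings = 0.2, nuts_legume_servings = 0.3,
    red_processed_meat_servings = 0.8, epa_dha = 100, alcohol_drinks = 0
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(row)))
  n <- max(1L, vapply(dots, length, integer(1)))
  row <- row[rep(1L, n), ]
  for (nm in names(dots)) row[[nm]] <- dots[[nm]]
  if (n > 1) row$participant_id <- sprintf("P%04d", seq_len(n))
  row
}

# the profile that attains every printed maximum on all four indices
best_case_intake <- function(participant_id = "P1") {
  intake_row(
    participant_id = participant_id,
    fruit_g = 200, vegetable_g = 300, pe_fat = 25, pe_sfa = 5, pe_pufa = 10,
    pe_free_sugar = 5, fiber = 30, potassium = 3600,
    pe_protein = 19, dens_fiber = 15, dens_mg = 240, dens_ca = 600,
    dens_k = 2300, dens_chol = 70, dens_na = 1000,
    dens_fruit_cupeq = 0.8, dens_whole_fruit_cupeq = 0.4,
    dens_veg_cupeq = 1.1, dens_green_cupeq = 0.2,
    dens_whole_grain_ozeq = 1.5, dens_lowfat_dairy_cupeq = 1.3,
    dens_lean_protein_ozeq = 2.5, dens_seafood_plant_cupeq = 0.8,
    dens_refined_grain_ozeq = 1.5, pufa_mufa_sfa_ratio = 2.6,
    pe_added_sugar = 5, veg_servings = 5, fruit_servings = 4,
    whole_grain_g = 75, ssb_servings = 0, nuts_legume_servings = 1,
    red_processed_meat_servings = 0, pe_trans = 0.4, epa_dha = 250,
    sodium = 1000, alcohol_drinks = 1
  )
}

worst_case_intake <- function(participant_id = "P1") {
  intake_row(
    participant_id = participant_id,
    fruit_g = 0, vegetable_g = 0, pe_fat = 40, pe_sfa = 17, pe_pufa = 1,
    pe_free_sugar = 15, fiber = 10, potassium = 2000,
    pe_protein = 12, dens_fiber = 5, dens_mg = 100, dens_ca = 300,
    dens_k = 1200, dens_chol = 150, dens_na = 2500,
    dens_fruit_cupeq = 0, dens_whole_fruit_cupeq = 0, dens_veg_cupeq = 0,
    dens_green_cupeq = 0, dens_whole_grain_ozeq = 0,
    dens_lowfat_dairy_cupeq = 0, dens_lean_protein_ozeq = 0,
    dens_seafood_plant_cupeq = 0, dens_refined_grain_ozeq = 5,
    pufa_mufa_sfa_ratio = 1.0, pe_added_sugar = 30,
    veg_servings = 0, fruit_servings = 0, whole_grain_g = 0,
    ssb_servings = 2, nuts_legume_servings = 0,
    red_processed_meat_servings = 2, pe_trans = 5, epa_dha = 0,
    sodium = 4000, alcohol_drinks = 3
  )
}

# random valid intakes spanning each component's full scoring range
random_intakes <- function(n, seed = 1) {
  set.seed(seed)
  r <- function(lo, hi) stats::runif(n, lo, hi)
  tibble::tibble(
    participant_id = sprintf("R%04d", seq_len(n)), energy = r(1000, 3000),
    fruit_g = r(0, 800), vegetable_g = r(0, 1200), fiber = r(0, 50),
    potassium = r(500, 6000), sodium = r(500, 5000),
    pe_fat = r(10, 50), pe_sfa = r(0, 25), pe_pufa = r(0, 15),
    pe_trans = r(0, 6), pe_free_sugar = r(0, 30), pe_added_sugar = r(0, 35),
    pe_protein = r(8, 30),
    dens_fiber = r(0, 25), dens_mg = r(50, 400), dens_ca = r(100, 900),
    dens_k = r(500, 3500), dens_chol = r(20, 250), dens_na = r(300, 3000),
    dens_fruit_cupeq = r(0, 1.5), dens_whole_fruit_cupeq = r(0, 1),
    dens_veg_cupeq = r(0, 2), dens_green_cupeq = r(0, 0.5),
    dens_whole_grain_ozeq = r(0, 3), dens_lowfat_dairy_cupeq = r(0, 2.5),
    dens_lean_protein_ozeq = r(0, 4), dens_seafood_plant_cupeq = r(0, 1.5),
    dens_refined_grain_ozeq = r(0, 6), pufa_mufa_sfa_ratio = r(0, 4),
    veg_servings = r(0, 8), fruit_servings = r(0, 6),
    whole_grain_g = r(0, 120), ssb_servings = r(0, 3),
    nuts_legume_servings = r(0, 2), red_processed_meat_servings = r(0, 3),
    epa_dha = r(0, 500), alcohol_drinks = r(0, 4)
  )
}
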