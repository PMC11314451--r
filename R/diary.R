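#' Column specification of the diary interchange format
#'
#' The pipeline exchanges food-diary data as a long-format CSV with one row
#' per eating occasion.  `diary_cols()` returns the full column contract:
#' every required column name, its storage type, and its unit.
#'
#' @return A tibble with columns `column`, `type` (`"character"`, `"numeric"`
#'   or `"logical"`) and `unit`.
#' @export
#' @examples
#' diary_cols()
diary_cols <- function() {
  num <- function(cols, unit) tibble::tibble(column = cols, type = "numeric", unit = unit)
  dplyr::bind_rows(
    tibble::tibble(column = "participant_id", type = "character", unit = ""),
    tibble::tibble(column = c("day_type", "meal_slot"), type = "character", unit = ""),
    num("energy", "kcal"),
    num(c("protein", "fat", "sfa", "mufa", "pufa", "trans_fat", "carbohydrate",
          "free_sugar", "added_sugar", "fiber"), "g"),
    num("epa_dha", "mg"),
    num(c("cholesterol", "sodium", "potassium", "calcium", "magnesium",
          "caffeine"), "mg"),
    num(c("fruit_g", "whole_fruit_g", "vegetable_g", "green_veg_legume_g",
          "whole_grain_g", "processed_meat_g", "fish_g", "nuts_seeds_g",
          "legume_g", "natural_dairy_g", "sweets_g", "salty_snack_g"), "g"),
    num(c("fruit_cupeq", "whole_fruit_cupeq", "veg_cupeq",
          "green_veg_legume_cupeq", "lowfat_dairy_cupeq",
          "seafood_plant_protein_cupeq"), "cup-eq"),
    num(c("whole_grain_ozeq", "refined_grain_ozeq", "lean_protein_ozeq"), "oz-eq"),
    num("ssb_ml", "mL"),
    num(c("ssb_servings", "veg_servings", "fruit_servings",
          "nuts_legume_servings", "red_processed_meat_servings"), "servings"),
    num("alcohol_drinks", "drinks"),
    tibble::tibble(column = "is_snack", type = "logical", unit = "")
  )
}

#' Valid values of the categorical diary columns
#' @name diary-levels
#' @return A character vector of levels.
#' @export
day_types <- function() c("morning_shift", "night_shift", "off_day")

#' @rdname diary-levels
#' @export
meal_slots <- function() {
  c("breakfast", "brunch", "lunch", "afternoon_snack", "supper",
    "between_meal_snack")
}

diary_numeric_cols <- function() {
  spec <- diary_cols()
  spec$column[spec$type == "numeric"]
}

#' Validate a diary table
#'
#' Checks the full diary contract: required columns, categorical levels,
#' non-negative finite amounts, within-row nutrient consistency
#' (free sugar within carbohydrate, fatty-acid fractions within total fat,
#' whole fruit within fruit, `is_snack` consistent with `meal_slot`), and the
#' study design of one morning-shift, one night-shift and one off day per
#' participant, each day having at least one eating occasion with positive
#' energy.
#'
#' @param diary A data frame of meal records (see [diary_cols()]).
#' @param check_structure Check the one-day-of-each-type design. Set to
#'   `FALSE` to validate record-level content only.
#' @return `diary`, invisibly, as a tibble with columns in canonical order.
#'   Malformed input aborts with condition class `dietquality_format_error`
#'   (missing columns) or `dietquality_validation_error` (bad values; the
#'   message lists offending row numbers).
#' @export
validate_diary <- function(diary, check_structure = TRUE) {
  spec <- diary_cols()
  missing <- setdiff(spec$column, names(diary))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("diary is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "dietquality_format_error", missing_columns = missing
    )
  }
  extra <- setdiff(names(diary), spec$column)
  if (length(extra) > 0) {
    rlang::warn(paste0("ignoring unknown diary column(s): ",
                       paste(extra, collapse = ", ")))
  }
  diary <- tibble::as_tibble(diary)[spec$column]
  diary$participant_id <- as.character(diary$participant_id)

  problems <- character(0)
  bad_rows <- function(what, idx) {
    idx[is.na(idx)] <- TRUE
    if (any(idx)) {
      problems <<- c(problems, paste0(what, " (rows ",
                                      paste(which(idx), collapse = ", "), ")"))
    }
  }

  bad_rows("unknown day_type", !(diary$day_type %in% day_types()))
  bad_rows("unknown meal_slot", !(diary$meal_slot %in% meal_slots()))

  num <- as.matrix(diary[diary_numeric_cols()])
  storage.mode(num) <- "double"
  nonfinite <- rowSums(!is.finite(num)) > 0
  bad_rows("non-finite amount", nonfinite)
  negative <- rowSums(num < 0, na.rm = TRUE) > 0
  bad_rows("negative amount", negative & !nonfinite)

  ok <- !nonfinite
  tol <- 1e-6
  bad_rows("free_sugar exceeds carbohydrate",
           ok & diary$free_sugar > diary$carbohydrate + tol)
  bad_rows("fatty-acid fractions exceed total fat",
           ok & (diary$sfa + diary$mufa + diary$pufa + diary$trans_fat >
                   diary$fat + tol))
  bad_rows("whole_fruit_g exceeds fruit_g",
           ok & diary$whole_fruit_g > diary$fruit_g + tol)
  bad_rows("is_snack inconsistent with meal_slot",
           xor(as.logical(diary$is_snack),
               diary$meal_slot == "between_meal_snack"))

  if (length(problems) == 0 && check_structure) {
    structure_tbl <- dplyr::summarise(
      dplyr::group_by(diary, .data$participant_id, .data$day_type),
      day_energy = sum(.data$energy), .groups = "drop"
    )
    counts <- tidyr::pivot_wider(
      dplyr::count(structure_tbl, .data$participant_id, .data$day_type),
      names_from = "day_type", values_from = "n", values_fill = 0
    )
    for (dt in setdiff(day_types(), names(counts))) counts[[dt]] <- 0
    bad <- counts$participant_id[
      counts$morning_shift != 1 | counts$night_shift != 1 | counts$off_day != 1
    ]
    if (length(bad) > 0) {
      problems <- c(problems, paste0(
        "participant(s) without exactly one morning_shift, night_shift and ",
        "off_day: ", paste(bad, collapse = ", ")))
    }
    zero_days <- structure_tbl[structure_tbl$day_energy <= 0, ]
    if (nrow(zero_days) > 0) {
      problems <- c(problems, paste0(
        "diary day(s) with no positive-energy record: ",
        paste(zero_days$participant_id, zero_days$day_type,
              sep = "/", collapse = ", ")))
    }
  }

  if (length(problems) > 0) {
    rlang::abort(
      paste0("invalid diary:\n", paste0("- ", problems, collapse = "\n")),
      class = "dietquality_validation_error", problems = problems
    )
  }
  invisible(diary)
}

#' Read and write the diary interchange CSV
#'
#' `read_diary()` reads a UTF-8, comma-separated, header-first diary file and
#' validates it with [validate_diary()]; column order is irrelevant and
#' unknown columns are dropped with a warning.  `write_diary()` writes a
#' validated diary so that a read/write round trip reproduces the cohort
#' field-for-field.
#'
#' @param path Path of the diary CSV.
#' @param diary A valid diary tibble.
#' @param check_structure Passed to [validate_diary()].
#' @return `read_diary()` returns the validated diary tibble;
#'   `write_diary()` returns `path` invisibly.
#' @export
read_diary <- function(path, check_structure = TRUE) {
  spec <- diary_cols()
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  missing <- setdiff(spec$column, names(raw))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("diary file ", path, " is missing required column(s): ",
             paste(missing, collapse = ", ")),
      class = "dietquality_format_error", missing_columns = missing
    )
  }
  for (col in diary_numeric_cols()) raw[[col]] <- as.numeric(raw[[col]])
  raw$is_snack <- as.logical(raw$is_snack)
  out <- validate_diary(raw, check_structure = check_structure)
  out
}

#' @rdname read_diary
#' @export
write_diary <- function(diary, path, check_structure = TRUE) {
  diary <- validate_diary(diary, check_structure = check_structure)
  readr::write_csv(diary, path)
  invisible(path)
}
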