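test_that("generated cohorts have the 3-day design and are deterministic", {
  res <- generate_cohort(cohort_config(n_participants = 50, seed = 42))
  expect_equal(length(unique(res$diary$participant_id)), 50)
  days <- dplyr::distinct(res$diary, participant_id, day_type)
  expect_equal(nrow(days), 150)
  expect_silent(validate_diary(res$diary))

  res2 <- generate_cohort(cohort_config(n_participants = 50, seed = 42))
  expect_identical(res$diary, res2$diary)
  expect_identical(res$anthro, res2$anthro)
  res3 <- generate_cohort(cohort_config(n_participants = 50, seed = 43))
  expect_false(identical(res$diary, res3$diary))
})

test_that("generated diaries survive a write/read round trip validated", {
  res <- generate_cohort(cohort_config(n_participants = 8, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_diary(res$diary, path)
  back <- read_diary(path)
  expect_equal(as.data.frame(back), as.data.frame(res$diary),
               tolerance = 1e-12)
})

test_that("energy equals the Atwater sum of macronutrients and alcohol", {
  res <- generate_cohort(cohort_config(seed = 9))
  days <- day_totals(res$diary)
  atwater_e <- 4 * days$protein + 4 * days$carbohydrate + 9 * days$fat +
    7 * 10 * days$alcohol_drinks
  expect_true(all(abs(atwater_e - days$energy) / days$energy < 0.02))
  m <- participant_means(days)
  pe_sum <- m$pe_protein + m$pe_fat + m$pe_carbohydrate + m$pe_alcohol
  expect_true(all(pe_sum > 95 & pe_sum < 105))
})

test_that("a single seeded cohort lands near the configured item means", {
  res <- generate_cohort(cohort_config(seed = 42))
  report <- res$report
  n <- 50
  for (item in c("vegetable_g", "caffeine")) {
    cfg_row <- cohort_config()$items
    cfg_row <- cfg_row[cfg_row$item == item, ]
    realized <- report$mean[report$quantity == item]
    expect_lt(abs(realized - cfg_row$mean), 3 * cfg_row$sd / sqrt(n))
  }
})

test_that("item means are recovered across seeds within 3 standard errors", {
  n_seeds <- 10  # reduced here; the acceptance suite runs the full sweep
  cfg <- cohort_config()
  items <- cfg$items[!cfg$items$latent, ]
  sums <- setNames(numeric(nrow(items)), items$item)
  for (s in seq_len(n_seeds)) {
    rep_s <- generate_cohort(cohort_config(seed = 100 + s))$report
    sums <- sums + rep_s$mean[match(items$item, rep_s$quantity)]
  }
  realized <- sums / n_seeds
  tol <- 3 * items$sd / sqrt(n_seeds * cfg$n_participants)
  expect_true(all(abs(realized - items$mean) < tol),
              info = paste(items$item[abs(realized - items$mean) >= tol],
                           collapse = ", "))
})

test_that("behavioral fractions and meal structure match the stated world", {
  res <- generate_cohort(cohort_config(seed = 1))
  rep1 <- res$report
  get <- function(q) rep1$mean[rep1$quantity == q]
  expect_gt(get("snacker_fraction"), 0.5)
  expect_lt(get("snacker_fraction"), 0.9)
  expect_gt(get("mean_meal_count"), 4.2)
  expect_lt(get("mean_meal_count"), 5.0)
  # breakfast present every day
  brk <- dplyr::filter(res$diary, meal_slot == "breakfast")
  expect_equal(nrow(dplyr::distinct(brk, participant_id, day_type)), 150)
})

test_that("infeasible configurations fail before sampling", {
  expect_error(generate_cohort(cohort_config(n_participants = 0)),
               class = "dietquality_config_error")
  expect_error(generate_cohort(cohort_config(pe_fat_mean = 70,
                                             pe_protein_mean = 30)),
               class = "dietquality_config_error")
  expect_error(generate_cohort(cohort_config(snacker_fraction = 1.2)),
               class = "dietquality_config_error")
  expect_error(cohort_config(not_a_field = 1),
               class = "dietquality_config_error")
})

test_that("perturbations are local: zero effect is identity", {
  res <- generate_cohort(cohort_config(n_participants = 6, seed = 5))
  same <- perturb_cohort(res$diary, "energy", add = 0, mult = 1)
  expect_identical(same, res$diary)
  expect_error(perturb_cohort(res$diary, "calorie"),
               class = "dietquality_contract_error")
})

test_that("perturbations touch only the selected rows and field", {
  res <- generate_cohort(cohort_config(n_participants = 6, seed = 5))
  shifted <- perturb_cohort(res$diary, "sodium", mult = 2,
                            day_types_sel = "morning_shift")
  off_rows <- res$diary$day_type != "morning_shift"
  expect_identical(shifted[off_rows, ], res$diary[off_rows, ])
  expect_equal(shifted$sodium[!off_rows], 2 * res$diary$sodium[!off_rows])
  other_cols <- setdiff(names(res$diary), "sodium")
  expect_identical(shifted[!off_rows, other_cols],
                   res$diary[!off_rows, other_cols])
  # a per-day additive shift adds the stated daily amount
  plus <- perturb_cohort(res$diary, "energy", add = 500)
  d0 <- day_totals(res$diary); d1 <- day_totals(plus)
  expect_equal(d1$energy, d0$energy + 500, tolerance = 1e-9)
})

test_that("an induced energy shift in snackers is detectable", {
  # +500 kcal/day to snacking participants; the gated two-group test on
  # participant mean energy should reject in the large majority of runs
  n_rep <- 40
  hits <- 0
  for (s in seq_len(n_rep)) {
    res <- generate_cohort(cohort_config(seed = 7000 + s))
    days0 <- day_totals(res$diary)
    snackers <- unique(days0$participant_id[days0$snack_energy > 0])
    if (length(snackers) < 5 ||
        length(snackers) > cohort_config()$n_participants - 5) next
    diary <- perturb_cohort(res$diary, "energy", add = 500,
                            participants = snackers)
    m <- participant_means(day_totals(diary))
    res_t <- gated_two_group(m$energy[m$participant_id %in% snackers],
                             m$energy[!m$participant_id %in% snackers])
    hits <- hits + res_t$significant
  }
  expect_gte(hits / n_rep, 0.8)
})
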