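component_points <- function(scores, comp) {
  scores$points[scores$component == comp]
}

test_that("HEI-2015 prorates adequacy and moderation components linearly", {
  expect_equal(component_points(score_hei2015(
    intake_row(dens_fruit_cupeq = 0.8)), "total_fruits"), 5)
  expect_equal(component_points(score_hei2015(
    intake_row(dens_fruit_cupeq = 0.4)), "total_fruits"), 2.5)
  expect_equal(component_points(score_hei2015(
    intake_row(dens_fruit_cupeq = 1.6)), "total_fruits"), 5)

  expect_equal(component_points(score_hei2015(
    intake_row(pe_added_sugar = 26)), "added_sugars"), 0)
  expect_equal(component_points(score_hei2015(
    intake_row(pe_added_sugar = 6.5)), "added_sugars"), 10)
  expect_equal(component_points(score_hei2015(
    intake_row(pe_added_sugar = 16.25)), "added_sugars"), 5)
})

test_that("a zero-SFA diet caps the fatty-acid ratio at the maximum", {
  sc <- score_hei2015(intake_row(pe_sfa = 0, pufa_mufa_sfa_ratio = Inf))
  expect_equal(component_points(sc, "fatty_acid_ratio"), 10)
})

test_that("HEI and AHEI proration matches an independent interpolation", {
  # independent oracle: stats::approxfun through the two printed criteria
  cases <- list(
    list(q = "dens_fruit_cupeq", comp = "total_fruits", x0 = 0, x1 = 0.8,
         max = 5, idx = "hei"),
    list(q = "dens_whole_fruit_cupeq", comp = "whole_fruits", x0 = 0,
         x1 = 0.4, max = 5, idx = "hei"),
    list(q = "dens_veg_cupeq", comp = "total_vegetables", x0 = 0, x1 = 1.1,
         max = 5, idx = "hei"),
    list(q = "dens_green_cupeq", comp = "greens_and_beans", x0 = 0,
         x1 = 0.2, max = 5, idx = "hei"),
    list(q = "dens_whole_grain_ozeq", comp = "whole_grains", x0 = 0,
         x1 = 1.5, max = 10, idx = "hei"),
    list(q = "dens_lowfat_dairy_cupeq", comp = "dairy", x0 = 0, x1 = 1.3,
         max = 10, idx = "hei"),
    list(q = "dens_lean_protein_ozeq", comp = "total_protein", x0 = 0,
         x1 = 2.5, max = 5, idx = "hei"),
    list(q = "dens_seafood_plant_cupeq", comp = "seafood_plant_protein",
         x0 = 0, x1 = 0.8, max = 5, idx = "hei"),
    list(q = "pufa_mufa_sfa_ratio", comp = "fatty_acid_ratio", x0 = 1.2,
         x1 = 2.5, max = 10, idx = "hei"),
    list(q = "dens_refined_grain_ozeq", comp = "refined_grains", x0 = 4.3,
         x1 = 1.8, max = 10, idx = "hei"),
    list(q = "pe_added_sugar", comp = "added_sugars", x0 = 26, x1 = 6.5,
         max = 10, idx = "hei"),
    list(q = "pe_sfa", comp = "saturated_fats", x0 = 16, x1 = 8, max = 10,
         idx = "hei"),
    list(q = "veg_servings", comp = "vegetables", x0 = 0, x1 = 5, max = 10,
         idx = "ahei"),
    list(q = "fruit_servings", comp = "fruits", x0 = 0, x1 = 4, max = 10,
         idx = "ahei"),
    list(q = "whole_grain_g", comp = "whole_grains", x0 = 0, x1 = 75,
         max = 10, idx = "ahei"),
    list(q = "ssb_servings", comp = "ssb_juice", x0 = 1, x1 = 0, max = 10,
         idx = "ahei"),
    list(q = "nuts_legume_servings", comp = "nuts_legumes", x0 = 0, x1 = 1,
         max = 10, idx = "ahei"),
    list(q = "red_processed_meat_servings", comp = "red_processed_meat",
         x0 = 1.5, x1 = 0, max = 10, idx = "ahei"),
    list(q = "pe_trans", comp = "trans_fat", x0 = 4, x1 = 0.5, max = 10,
         idx = "ahei"),
    list(q = "epa_dha", comp = "epa_dha", x0 = 0, x1 = 250, max = 10,
         idx = "ahei"),
    list(q = "pe_pufa", comp = "pufa", x0 = 2, x1 = 10, max = 10,
         idx = "ahei")
  )
  cutoffs <- sodium_decile_cutoffs(mode = "fixed_reference")
  set.seed(99)
  for (cs in cases) {
    span <- range(c(cs$x0, cs$x1))
    xs <- runif(1000, span[1] - 0.5 * diff(span), span[2] + 0.5 * diff(span))
    xs <- pmax(xs, 0)
    oracle <- stats::approxfun(c(cs$x0, cs$x1), c(0, cs$max), rule = 2)
    args <- setNames(list(xs), cs$q)
    intake <- do.call(intake_row, c(list(participant_id = "P1"), args))
    intake$participant_id <- sprintf("P%04d", seq_along(xs))
    sc <- if (cs$idx == "hei") score_hei2015(intake)
          else score_ahei2010(intake, cutoffs)
    expect_equal(component_points(sc, cs$comp), oracle(xs),
                 tolerance = 1e-9, label = cs$comp)
  }
  # AHEI sodium against the fixed decile cutoffs
  xs <- runif(1000, 500, 4000)
  intake <- intake_row(); intake <- intake[rep(1, 1000), ]
  intake$sodium <- xs
  intake$participant_id <- sprintf("P%04d", seq_along(xs))
  oracle <- stats::approxfun(c(cutoffs$high_cutoff, cutoffs$low_cutoff),
                             c(0, 10), rule = 2)
  expect_equal(component_points(score_ahei2010(intake, cutoffs), "sodium"),
               oracle(xs), tolerance = 1e-9)
  # AHEI alcohol: piecewise-linear through the printed knots, 2.5 at zero
  xs <- c(0, runif(1000, 0, 4))
  intake <- intake_row(); intake <- intake[rep(1, length(xs)), ]
  intake$alcohol_drinks <- xs
  intake$participant_id <- sprintf("P%04d", seq_along(xs))
  oracle <- stats::approxfun(c(0, 0.5, 1.5, 2.5), c(2.5, 10, 10, 0),
                             rule = 2)
  expect_equal(component_points(score_ahei2010(intake, cutoffs), "alcohol"),
               oracle(xs), tolerance = 1e-9)
})

test_that("AHEI worked examples: non-drinker, vegetables, SSB", {
  cutoffs <- sodium_decile_cutoffs(mode = "fixed_reference")
  pts <- function(intake, comp) {
    component_points(score_ahei2010(intake, cutoffs), comp)
  }
  expect_equal(pts(intake_row(alcohol_drinks = 0), "alcohol"), 2.5)
  expect_equal(pts(intake_row(veg_servings = 5), "vegetables"), 10)
  expect_equal(pts(intake_row(veg_servings = 2.5), "vegetables"), 5)
  expect_equal(pts(intake_row(ssb_servings = 0), "ssb_juice"), 10)
  expect_equal(pts(intake_row(ssb_servings = 1), "ssb_juice"), 0)
  expect_equal(pts(intake_row(ssb_servings = 0.5), "ssb_juice"), 5)
})

test_that("sodium decile cutoffs: empirical percentiles and fixed fallback", {
  fixed <- sodium_decile_cutoffs(mode = "fixed_reference")
  expect_equal(fixed$low_cutoff, 1279.47)
  expect_equal(fixed$high_cutoff, 2840.26)

  emp <- sodium_decile_cutoffs(seq(1000, 1900, by = 100))
  expect_equal(emp$low_cutoff, 1090)
  expect_equal(emp$high_cutoff, 1810)

  expect_warning(small <- sodium_decile_cutoffs(c(1500, 1600)),
                 "fewer than 10")
  expect_equal(small$source, "fixed_reference")

  flat <- list(low_cutoff = 2000, high_cutoff = 2000, source = "x")
  expect_warning(sc <- score_ahei2010(intake_row(), flat), "degenerate")
  expect_equal(component_points(sc, "sodium"), 5)
})

test_that("HEI and AHEI adherence bands partition the score range", {
  expect_equal(classify_hei(81.93), "high")    # the cohort maximum
  expect_equal(classify_hei(29.55), "low")     # the cohort minimum
  expect_equal(classify_hei(100), "extremely_high")
  expect_equal(classify_ahei(62), "moderate")  # the cohort maximum
  expect_equal(classify_ahei(38.62), "low")    # the cohort mean
  expect_equal(classify_ahei(110), "perfect")
  expect_equal(classify_ahei(100), "extremely_high")

  # exhaustive scan: every 0.01 step maps to exactly one band, no gaps
  grid_hei <- seq(0, 100, by = 0.01)
  bands <- classify_hei(grid_hei)
  expect_false(any(is.na(bands)))
  expect_equal(sort(unique(bands)),
               sort(c("low", "moderate", "good", "high", "extremely_high")))
  grid_ahei <- seq(0, 110, by = 0.01)
  bands <- classify_ahei(grid_ahei)
  expect_false(any(is.na(bands)))
  changes <- sum(bands[-1] != bands[-length(bands)])
  expect_equal(changes, 5)  # monotone sequence of 6 contiguous bands
})

test_that("totals stay in printed bounds and equal component sums", {
  intakes <- random_intakes(10000, seed = 11)
  scores <- score_indices(intakes, sodium_deciles = "cohort")
  totals <- index_totals(scores)
  rng <- list(HDI2015 = c(0, 7), DASH_MELLEN = c(0, 9),
              HEI2015 = c(0, 100), AHEI2010 = c(0, 110))
  for (idx in names(rng)) {
    tt <- totals$total[totals$index == idx]
    expect_gte(min(tt), rng[[idx]][1])
    expect_lte(max(tt), rng[[idx]][2])
  }
  # per-component bounds
  expect_true(all(scores$points >= 0 & scores$points <= scores$max_points))
})

test_that("component scores are monotone in their driving quantity", {
  xs <- seq(0, 60, length.out = 200)
  fiber_tot <- vapply(xs, function(f) {
    sum(score_hdi2015(intake_row(fiber = f))$points)
  }, numeric(1))
  expect_true(all(diff(fiber_tot) >= 0))

  frt <- vapply(seq(0, 2, length.out = 100), function(v) {
    component_points(score_hei2015(intake_row(dens_fruit_cupeq = v)),
                     "total_fruits")
  }, numeric(1))
  expect_true(all(diff(frt) >= 0))

  sug <- vapply(seq(0, 35, length.out = 100), function(v) {
    component_points(score_hei2015(intake_row(pe_added_sugar = v)),
                     "added_sugars")
  }, numeric(1))
  expect_true(all(diff(sug) <= 0))

  cutoffs <- sodium_decile_cutoffs(mode = "fixed_reference")
  ssb <- vapply(seq(0, 3, length.out = 100), function(v) {
    component_points(score_ahei2010(intake_row(ssb_servings = v), cutoffs),
                     "ssb_juice")
  }, numeric(1))
  expect_true(all(diff(ssb) <= 0))
})
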