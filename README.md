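# dietquality

Diet-quality index scoring and shift-worker food-diary analysis in R.

`dietquality` implements a complete pipeline from per-meal food-diary
records to four diet-quality index scores, adherence classifications,
cross-index concordance, and the group-comparison statistics used in
nutritional-epidemiology studies of shift workers. Because raw diary data
from such studies are rarely deposited, the package also ships a seeded
synthetic cohort generator that emulates a 50-participant, 3-day
(morning-shift / night-shift / off-day) diary study, so every stage of the
pipeline is testable end to end.

## The indices

Scores are computed from 3-day mean intakes, with percent-of-energy (%E)
shares derived via Atwater factors (protein and carbohydrate 4 kcal/g, fat
9 kcal/g, alcohol 7 kcal/g) and nutrient densities expressed per 1000 kcal:

* **HDI-2015** (WHO-based Healthy Diet Indicator, 0–7): seven binary
  criteria — fruit + vegetables > 400 g/d, fat < 30%E, SFA < 10%E,
  PUFA 6–11%E, free sugars < 10%E, fiber > 25 g/d, potassium ≥ 3500 mg/d.
  Bands: 0–3 low, 4–5 moderate, 6–7 high.
* **Mellen's DASH index** (0–9 in half points): nine nutrient targets
  (protein %E; fiber, Mg, Ca, K, cholesterol, Na per 1000 kcal; fat and
  SFA %E) scored 1 / 0.5 / 0 by full / intermediate / missed target.
  Totals ≥ 4.5 are DASH-consistent.
* **HEI-2015** (0–100): thirteen components on food-group densities and
  %E quantities, each linearly prorated between a zero-score and a
  full-score criterion, e.g. total fruits `5 · min(1, density/0.8)`.
* **AHEI-2010** (0–110): eleven prorated components, with sodium scored
  against the cohort's own intake deciles and a flat 2.5 points for
  non-drinkers on the alcohol component.

The statistical battery mirrors standard practice in this literature:
Shapiro–Wilk-gated choice between the pooled t-test and Mann–Whitney,
McNemar tests for paired habit prevalence across day types, Friedman tests
with Bonferroni-corrected Wilcoxon post hocs for repeated measures, and
seeded permutation tests (multivariate dispersion and PERMANOVA, 999
permutations) for sample homogeneity.

## Worked example

```r
library(dietquality)

res   <- generate_cohort(cohort_config(seed = 1))
days  <- day_totals(res$diary)
means <- participant_means(days)
totals <- index_totals(score_indices(means))

adherence_distribution(totals) |>
  dplyr::filter(adherence %in% c("low", "not_consistent"))
#>   index       adherence       n   pct
#>   AHEI2010    low            28    56
#>   DASH_MELLEN not_consistent 48    96
#>   HDI2015     low            35    70
#>   HEI2015     low            26    52
```

More than half of the simulated diets fall in the lowest adherence band of
every index — the generator's stated world is a cohort with genuinely poor
diet quality (high saturated fat and sweets, low legumes, nuts, fish and
green vegetables), and the four indices agree on that verdict while
disagreeing in degree, because they weight different criteria.

Meal frequency does not differ across the shift schedule in this world:

```r
friedman_shifts(days, "n_meals")
#> Friedman shift-day comparison (n = 50)
#>   chi-squared = 4.234, df = 2, p = 0.120
```

Splitting the cohort at the 13%E snacking cutoff and comparing total
energy with the normality-gated two-group test:

```r
sp <- split_cohort(means, "pe_snacking", 13, "lower")
tg <- gated_two_group(means$energy[sp$group == "low"],
                      means$energy[sp$group == "high"])
glance(tg)
#>   test   statistic p.value alpha significant
#>   t_test     -1.89  0.0652  0.05 FALSE
```

Both Shapiro–Wilk gates pass (p = 0.93, 0.94), so the pooled t-test is
used; heavier snackers eat about 230 kcal/d more on average in this
realization (1773 vs 2005 kcal), short of significance at n = 18 + 32.

`run_simulate()`, `run_score()` and `run_compare()` wrap these stages into
file-to-file steps (a thin command-line front end is in `inst/cli/dqi.R`),
and `plot_adherence()` / `plot_meal_counts()` draw the standard summary
figures.

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch against the installed
package, the analytically fixed scoring quantities: the AHEI-2010 alcohol
component awarded to a non-drinker, the smallest DASH total classified as
consistent on the half-point grid, and the smallest integer HDI-2015 total
classified as high adherence.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
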