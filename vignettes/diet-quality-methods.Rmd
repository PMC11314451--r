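---
title: "Scoring diet quality from 3-day food diaries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring diet quality from 3-day food diaries: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietquality)
```

# The pipeline

`dietquality` takes long-format diaries — one row per eating occasion with
already-resolved nutrient and food-group amounts — through three stages:

1. **Aggregation.** Eating occasions are summed to participant-days
   (`day_totals()`), then averaged, unweighted, over each participant's
   three diary days (`participant_means()`). Resolving foods to nutrients
   (food-composition databases, portion estimation) is upstream of this
   package: the diary CSV is the interchange contract, and
   `validate_diary()` enforces it completely — every malformed input is a
   typed error, never a silent drop.
2. **Index scoring.** Four indices are computed from the 3-day means, each
   a pure function of the intake row (and, for the AHEI-2010 sodium
   component, of the cohort sodium distribution).
3. **Cohort statistics.** Cutoff-defined two-group comparisons, paired
   habit-prevalence tests across the three shift-day types, and permutation
   tests of sample homogeneity.

# Derived quantities

Percent-of-energy shares use conventional Atwater factors (protein and
carbohydrate 4 kcal/g, fat 9 kcal/g, alcohol 7 kcal/g); free and added
sugars use the carbohydrate factor, and fatty-acid classes the fat factor.
One alcoholic drink is booked as 10 g ethanol (configurable): "drinks per
day" is reported without a definition often enough that a fixed convention
beats a guess per dataset. Densities are `1000 · mean(x) / mean(energy)`.
All shares and densities are computed on the 3-day means, so multiplying
every amount and the energy of all meals by a constant leaves them
unchanged — a property the test suite checks to 1e-9.

Two conventions deserve explanation:

* **Meal counts exclude between-meal snacks** by default. Meal frequency
  and snacking prevalence are distinct behaviours in this literature
  ("4–5 meals a day" alongside "70% snack daily"), so conflating them
  would make both summaries uninterpretable. A flag restores the inclusive
  count.
* **Sweets energy** is derived from sweets mass at a configurable energy
  density, default 3 kcal/g. The diary schema records sweets as mass; the
  share of energy from sweets is nevertheless a standard reported quantity
  and a split cutoff (12%E). The default reconciles typical
  cake/confectionery composition with the cohort-level energy share of
  sweets at the observed mean intakes.

# The four indices

## HDI-2015 and Mellen's DASH index

Both are threshold scores; the implementation honors the printed strictness
of every boundary exactly, with no floating-point tolerance: scores are
pure functions of their inputs, and a diet at exactly 400 g of fruit and
vegetables scores 0 on that criterion (strict `>`), while exactly 3500 mg
potassium scores 1 (`≥`). The DASH components award the half point on the
closed intermediate interval, e.g. protein `< 18` to `≥ 16.5` %E.

The DASH consistency boundary is `≥ 4.5` by default. The descriptive
phrase "above 4.5 points" appears alongside group splits defined as
"scores ≥ 4.5", which cannot both be the classifier; the `≥` reading is
used because the group comparisons are defined with it, and the `gt`
convention remains available via `classify_dash(..., boundary = "gt")`.

## HEI-2015 and AHEI-2010

Both indices publish only a zero-score and a full-score criterion per
component; linear proration between them is the established scoring
convention and the only way intermediate intakes can score at all.
`prorate()` implements the two-point interpolation for both orientations,
and the test suite verifies every component against an independently coded
interpolation (`stats::approxfun`) at 1000 random points per component.

Component-specific decisions:

* **Fatty-acid ratio (HEI).** `(PUFA + MUFA)/SFA` on the %E scale (the
  fat Atwater factor cancels). A diet with zero saturated fat has an
  undefined ratio; it is treated as meeting the maximum criterion, which
  is the limit behaviour.
* **Sodium (AHEI).** Scored against the studied population's lowest and
  highest intake deciles, computed with the linear-interpolation
  percentile definition (R's default type 7). With fewer than ten
  participants the scorer falls back, with a warning, to fixed reference
  cutoffs (1279.47 / 2840.26 mg/d) from a published shift-worker cohort;
  a degenerate (equal-cutoff) distribution scores the midpoint 5.
* **EPA+DHA (AHEI).** Full score at 250 mg/d, the published criterion for
  this component; the source table's typography runs the criteria
  together, so the value is kept configurable in the scoring table.
* **Alcohol (AHEI).** 10 points within 0.5–1.5 drinks/d, 0 at ≥ 2.5,
  linear in between on both sides, and exactly 2.5 points at zero drinks:
  non-drinkers are deliberately not awarded the moderate-intake optimum.

## Adherence bands

The printed HEI band list ("60–69 moderate, < 59 low") leaves 59–60
unassigned; `low` is defined as `< 60` so the bands partition the range
contiguously. The AHEI list overlaps at 100 ("110–100 perfect", "90–100
extremely high"); `perfect` is defined as `> 100`. An exhaustive 0.01-step
scan in the test suite confirms both band systems partition their full
score ranges with no gaps.

## Concordance

`concordance_table()` reports, for each index subset, the percentage of
participants simultaneously above low adherence and simultaneously at
good-or-high adherence. The DASH index is binary, so consistency stands in
for both levels; for the HDI, whose bands top out at `high`, good-or-high
means the 6–7 band.

# The statistical battery

* **Two-group comparisons** (`gated_two_group()`): Shapiro–Wilk on each
  group at α = 0.05; the pooled-variance two-sided t-test runs only when
  *both* groups pass (the gate's per-group handling is unspecified in most
  reports; requiring both is the conservative reading, and Welch is a
  flag). Otherwise a two-sided Mann–Whitney: exact enumeration when
  `n1·n2 ≤ 400` with no ties, else the normal approximation with tie
  correction and no continuity correction. Legacy-software defaults are
  unrecoverable in general; these choices are fixed and documented.
* **McNemar** (`mcnemar_test()`): `(b − c)²/(b + c)` on the discordant
  counts, df = 1, continuity correction off by default and available by
  flag — published chi-square values in this literature do not reveal
  which convention produced them, so both are provided.
* **Friedman + post hoc** (`friedman_shifts()`): mid-rank Friedman over
  the three day types; Wilcoxon signed-rank pairs run only when the
  Friedman p falls below α, with Bonferroni m = 3 (the three day-type
  pairs), never across the wider table of comparisons (the analyses this
  mirrors apply no family-wide correction, and neither does the package).
* **Homogeneity permutation tests** (`permutation_homogeneity()`): both
  tests standardize features to z-scores and work in Euclidean space — the
  defensible default for mixed anthropometric/dietary features, and
  configurable by pre-transforming the input. The dispersion test computes
  each observation's distance to its group centroid and a one-way F on
  those distances; PERMANOVA partitions the squared-distance matrix into
  within- and between-group sums. Both refer the observed F to label
  permutations with the add-one estimator `(1 + #{F* ≥ F})/(1 + n_perm)`,
  so p can never fall below `1/(n_perm + 1)`. Seeded runs are
  bit-reproducible, and the observed statistics are cross-checked in the
  test suite against vegan's `adonis2`/`betadisper`.

# The synthetic cohort

The generator emulates a 50-midwife, 3-day shift diary study: one morning
shift, one night shift, one day off per participant.

**Stated world.** Item intakes follow the published cohort means and SDs
(added sugar 9.0 ± 13.1 g, sweets 70.6 ± 108.8 g, caffeine 147.3 ± 100.6
mg, processed meat 53.0 ± 59.1 g, vegetables 442.5 ± 235.0 g, fruit 250.5
± 233.1 g, fish 14.9 ± 42.1 g, nuts and seeds 6.9 ± 21.5 g, natural dairy
185.4 ± 165.5 g, legumes 4.5 ± 18.1 g, sweet beverages 41.3 ± 158.4 mL);
daily meal count 4.78 ± 0.94 with breakfast always present; 70% daily
snackers with a snacking energy share targeting the 13%E cohort mean; 56%
sweets consumers and 44% beverage sweeteners; 8% alcohol consumers, none
daily. Where the underlying reports disagree between a summary table and
running text (caffeine SD 100.56 vs 100.89; fruit mean 250.54 vs 254.40;
processed-meat SD 59.14 vs 59.34), the table values are the defaults.
Values with no published counterpart were fixed once at physiologically
ordinary levels for adult women (total energy 1870 ± 470 kcal/d between
participants; fat 33 ± 5 %E, protein 16 ± 2.5 %E, SFA 12.5 ± 2.5 %E,
PUFA 5 ± 1.8 %E; sodium 1900 ± 600 mg/d; potassium 3400 ± 900 mg/d;
calcium 650 ± 300 mg/d — deliberately below requirements; magnesium 330 ±
100 mg/d; cholesterol 300 ± 130 mg/d) and are not revisited.

**Mechanics.** Each item is zero-inflated truncated-normal: a
participant-level consumer indicator (probability one minus the item's
zero-inflation, which defaults to the published consumer fraction where
one exists), a day-level consumption probability (0.9), and a
zero-truncated normal amount whose location parameter is solved
numerically so the *overall* expected intake equals the configured mean —
published tables with MIN 0 and SD larger than the mean imply exactly this
mixture shape. The realized cohort SD of a mixture does not equal the
configured SD; the generator calibrates means, and the parameter-recovery
acceptance test asserts pooled realized means within 3 standard errors
over 100 seeds.

Energy bookkeeping is exact rather than approximate: daily macronutrient
grams are derived from per-participant %E shares, so energy equals the
Atwater sum of macronutrients plus alcohol by construction (the 2%
consistency check in the test suite passes with zero slack). Meal slots
fill in the order breakfast, lunch, brunch, afternoon snack, supper, so
supper is the most commonly missed meal, matching the reported missing
pattern; slot energies are Dirichlet-distributed with a breakfast weight
chosen so breakfast contributes about 16% of energy and falls below 100
kcal on roughly one day in seven. Eggs are generated as a latent quantity
feeding the lean-protein equivalents only, since the diary schema carries
no egg column; the generator report therefore covers diary-visible items.

**What it does not emulate.** Inter-item correlation beyond energy
bookkeeping (a heavy sweets day does not depress vegetables), circadian
meal timing, under-reporting, seasonal variation, or the coupling of
micronutrients to their food-group sources (potassium is drawn
independently of vegetables). A green test therefore establishes that the
pipeline's arithmetic, classifications, and statistical calibration are
correct on data with the right marginal structure — not that the generator
reproduces the joint distribution of any real cohort, and cohort-level
index summaries from the generator are *not* expected to match published
cohort results.

# Degenerate inputs and numerical policy

Zero mean energy aborts scoring with a typed error; empty diaries write
header-only files and read back as empty cohorts; a cohort whose members
all snack (or none do) skips the snacking split with a warning rather than
failing the run; constant two-group samples return p = 1 with a warning;
fully tied Friedman tables return a zero statistic and p = 1. Boundary
comparisons never apply tolerances — scores are exact functions of exact
inputs — while round-trip I/O is checked to 1e-9 and proration to 1e-9
against the independent oracle.

# Limitations

The package consumes resolved nutrient amounts and does not translate
foods to nutrients; serving equivalents are derived through a small
shipped conversion table rather than a full equivalents database; no
multiplicity correction is applied across the many two-group comparisons,
matching the practice it mirrors; and the synthetic world, while
calibrated marginally, is not a substitute for deposited raw diaries.
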