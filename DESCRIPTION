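Package: dietquality
Title: Diet-Quality Index Scoring and Shift-Worker Food-Diary Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring food-diary data against four diet-quality
    indices (the WHO-based Healthy Diet Indicator 2015, Mellen's nutrient-based
    DASH index, the Healthy Eating Index 2015 and the Alternative Healthy
    Eating Index 2010), classifying adherence, and comparing intake across
    shift-schedule day types and anthropometric subgroups.  Includes a
    validated long-format diary interchange CSV, per-day and per-participant
    aggregation with percent-of-energy and per-1000 kcal densities, a
    statistical battery (Shapiro-Wilk-gated two-group tests, McNemar,
    Friedman with Wilcoxon post hoc, permutation tests for multivariate
    dispersion and PERMANOVA), and a seeded synthetic cohort generator that
    emulates a 50-participant, 3-day shift-worker diary study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
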