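#' Normality-gated two-group comparison
#'
#' Compares two independent samples the way the study's battery does: a
#' Shapiro-Wilk test on each group at `alpha` gates the choice between a
#' two-sided pooled-variance t-test (both groups non-rejecting) and a
#' two-sided Mann-Whitney test.  The Mann-Whitney p-value is exact when
#' `n1 * n2 <= exact_max` and there are no ties, otherwise a normal
#' approximation with tie correction (no continuity correction) is used.
#'
#' @param x,y Numeric samples, each of length >= 3.
#' @param alpha Significance level for both the gate and the verdict.
#' @param var_equal Use the pooled-variance t-test (default); `FALSE` gives
#'   Welch.
#' @param exact_max Largest `n1 * n2` for which the exact Mann-Whitney
#'   distribution is enumerated.
#' @param test `"auto"` (Shapiro-Wilk gate, default) or a forced choice of
#'   `"t_test"` / `"mann_whitney"`.
#' @return An object of class `dietquality_two_group`: test used, statistic,
#'   p-value, significance at `alpha`, per-group summaries (n, mean, sd,
#'   median) and the Shapiro-Wilk gate p-values.  [tidy()] and [glance()]
#'   methods are available.
#' @export
gated_two_group <- function(x, y, alpha = 0.05, var_equal = TRUE,
                            exact_max = 400,
                            test = c("auto", "t_test", "mann_whitney")) {
  test <- match.arg(test)
  if (length(x) < 3 || length(y) < 3) {
    rlang::abort("each group needs at least 3 observations",
                 class = "dietquality_contract_error")
  }
  summaries <- tibble::tibble(
    group = c("x", "y"),
    n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)),
    sd = c(stats::sd(x), stats::sd(y)),
    median = c(stats::median(x), stats::median(y))
  )
  if (stats::var(c(x, y)) == 0) {
    rlang::warn("both samples are constant and identical; returning p = 1")
    res <- list(test_used = "mann_whitney",
                statistic = length(x) * length(y) / 2, p_value = 1,
                shapiro_p = c(x = NA_real_, y = NA_real_))
  } else {
    sw <- function(v) {
      if (stats::var(v) == 0) return(0)  # constant: certainly not normal
      stats::shapiro.test(v)$p.value
    }
    shapiro_p <- c(x = sw(x), y = sw(y))
    use_t <- switch(test, auto = all(shapiro_p >= alpha),
                    t_test = TRUE, mann_whitney = FALSE)
    if (use_t) {
      tt <- stats::t.test(x, y, var.equal = var_equal)
      res <- list(test_used = "t_test", statistic = unname(tt$statistic),
                  p_value = tt$p.value, shapiro_p = shapiro_p)
    } else {
      ties <- anyDuplicated(c(x, y)) > 0
      exact <- !ties && length(x) * length(y) <= exact_max
      wt <- suppressWarnings(
        stats::wilcox.test(x, y, exact = exact, correct = FALSE)
      )
      res <- list(test_used = "mann_whitney",
                  statistic = unname(wt$statistic),
                  p_value = min(1, wt$p.value), shapiro_p = shapiro_p)
    }
  }
  structure(
    c(res, list(alpha = alpha, significant = res$p_value < alpha,
                group_summaries = summaries)),
    class = "dietquality_two_group"
  )
}

#' McNemar test for paired prevalence change
#'
#' Chi-square on the discordant pairs: `(b - c)^2 / (b + c)` with 1 df,
#' where `b` counts pairs flagged only in the first condition and `c` only
#' in the second.  Continuity correction (`(|b - c| - 1)^2 / (b + c)`) is
#' off by default.
#'
#' @param first,second Logical vectors of per-subject flags under the two
#'   paired conditions.
#' @param correct Apply the continuity correction?
#' @return A list: `statistic`, `p_value`, `df`, discordant counts `b`, `c`,
#'   `n`, and `correct`.
#' @export
mcnemar_test <- function(first, second, correct = FALSE) {
  if (length(first) != length(second) || length(first) < 1) {
    rlang::abort("paired flag vectors of equal positive length required",
                 class = "dietquality_contract_error")
  }
  b <- sum(first & !second)
  cc <- sum(!first & second)
  if (b + cc == 0) {
    rlang::warn("no discordant pairs; McNemar statistic is 0")
    stat <- 0
  } else {
    num <- if (correct) (abs(b - cc) - 1)^2 else (b - cc)^2
    stat <- num / (b + cc)
  }
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1, b = b, c = cc, n = length(first), correct = correct)
}

#' Friedman comparison across the three shift-day types
#'
#' Friedman rank test for repeated measures over the morning-shift,
#' night-shift and off-day values of each participant, followed — only when
#' the Friedman p is below `alpha` — by the three pairwise Wilcoxon
#' signed-rank tests with Bonferroni correction (m = 3).  Participants with
#' an incomplete triple are dropped with a message.
#'
#' @param data A tibble with `participant_id`, `day_type` and the column
#'   named by `value`.
#' @param value Name of the value column.
#' @param alpha Post-hoc gate level.
#' @return An object of class `dietquality_friedman`: `friedman_statistic`,
#'   `friedman_df`, `friedman_p`, `n`, and `posthoc` (tibble of pairs with
#'   raw and Bonferroni p-values; empty unless the Friedman test rejects).
#' @export
friedman_shifts <- function(data, value, alpha = 0.05) {
  wide <- tidyr::pivot_wider(
    data[c("participant_id", "day_type", value)],
    names_from = "day_type", values_from = dplyr::all_of(value)
  )
  for (dt in setdiff(day_types(), names(wide))) wide[[dt]] <- NA_real_
  complete <- stats::complete.cases(wide[day_types()])
  if (any(!complete)) {
    message(sum(!complete), " participant(s) dropped with incomplete triples")
  }
  wide <- wide[complete, ]
  if (nrow(wide) < 5) {
    rlang::abort("fewer than 5 complete morning/night/off triples",
                 class = "dietquality_contract_error")
  }
  m <- as.matrix(wide[day_types()])
  ft <- stats::friedman.test(m)
  if (is.nan(ft$statistic)) {  # every row fully tied: no variation to rank
    ft$statistic[] <- 0
    ft$p.value <- 1
  }
  posthoc <- tibble::tibble(pair = character(0), wilcoxon_p_raw = numeric(0),
                            p_bonferroni = numeric(0))
  if (ft$p.value < alpha) {
    pairs <- utils::combn(day_types(), 2, simplify = FALSE)
    posthoc <- purrr::map_dfr(pairs, function(p) {
      wp <- suppressWarnings(
        stats::wilcox.test(m[, p[1]], m[, p[2]], paired = TRUE,
                           exact = FALSE, correct = FALSE)$p.value
      )
      tibble::tibble(pair = paste(p, collapse = " vs "),
                     wilcoxon_p_raw = wp,
                     p_bonferroni = min(1, 3 * wp))
    })
  }
  structure(
    list(friedman_statistic = unname(ft$statistic),
         friedman_df = unname(ft$parameter), friedman_p = ft$p.value,
         n = nrow(wide), alpha = alpha, posthoc = posthoc),
    class = "dietquality_friedman"
  )
}

#' Built-in cohort split definitions
#'
#' The cutoff-defined two-group splits of the analysis: BMI 25 kg/m2 (equality
#' in the upper group), waist circumference 80 cm, body fat 30%, age 50
#' years, snacking 13%E, sweets 12%E, processed meat 50 g/d (equality in the
#' lower group for these), and the index-score splits DASH 4.5, HDI 4,
#' HEI 60 and AHEI 60 points (equality upper).
#'
#' @return A tibble: `split`, `metric`, `cutoff`, `equality`
#'   (`"lower"`: groups are `<= cutoff` / `> cutoff`; `"upper"`: `< cutoff` /
#'   `>= cutoff`).
#' @export
cohort_split_specs <- function() {
  tibble::tribble(
    ~split,    ~metric,            ~cutoff, ~equality,
    "bmi25",   "bmi",              25,      "upper",
    "waist80", "waist_cm",         80,      "lower",
    "bf30",    "body_fat_pct",     30,      "lower",
    "age50",   "age",              50,      "lower",
    "snack13", "pe_snacking",      13,      "lower",
    "sweets12","pe_sweets",        12,      "lower",
    "meat50",  "processed_meat_g", 50,      "lower",
    "dash45",  "total_DASH_MELLEN", 4.5,    "upper",
    "hdi4",    "total_HDI2015",    4,       "upper",
    "hei60",   "total_HEI2015",    60,      "upper",
    "ahei60",  "total_AHEI2010",   60,      "upper"
  )
}

#' Split a cohort at a cutoff
#'
#' Partitions a per-participant table into a low and a high group at a
#' cutoff, with the printed equality convention: `equality = "lower"` puts
#' values equal to the cutoff in the low group (`<=` / `>`),
#' `equality = "upper"` in the high group (`<` / `>=`).
#'
#' @param data Per-participant tibble.
#' @param metric Name of the numeric column to split on.
#' @param cutoff Numeric cutoff.
#' @param equality `"lower"` or `"upper"`.
#' @return `data` with an added factor column `group` with levels
#'   `"low"`, `"high"`.
#' @export
split_cohort <- function(data, metric, cutoff, equality = c("lower", "upper")) {
  equality <- match.arg(equality)
  if (!metric %in% names(data)) {
    rlang::abort(paste0("unknown split metric: ", metric),
                 class = "dietquality_contract_error")
  }
  v <- data[[metric]]
  high <- if (equality == "lower") v > cutoff else v >= cutoff
  data$group <- factor(ifelse(high, "high", "low"), levels = c("low", "high"))
  data
}
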