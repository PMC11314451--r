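#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for test-result objects
#'
#' broom-style `tidy()` and `glance()` methods for the statistical result
#' objects of the package: one row per estimated quantity (`tidy`), one row
#' per fit (`glance`).
#'
#' @param x A `dietquality_two_group`, `dietquality_friedman` or
#'   `dietquality_permhomog` object.
#' @param ... Unused.
#' @return A tibble.
#' @name dietquality-tidiers
NULL

#' @rdname dietquality-tidiers
#' @export
tidy.dietquality_two_group <- function(x, ...) {
  gs <- x$group_summaries
  tibble::tibble(
    group = gs$group, n = gs$n, mean = gs$mean, sd = gs$sd,
    median = gs$median, shapiro_p = unname(x$shapiro_p)
  )
}

#' @rdname dietquality-tidiers
#' @export
glance.dietquality_two_group <- function(x, ...) {
  tibble::tibble(test = x$test_used, statistic = x$statistic,
                 p.value = x$p_value, alpha = x$alpha,
                 significant = x$significant)
}

#' @rdname dietquality-tidiers
#' @export
tidy.dietquality_friedman <- function(x, ...) {
  if (nrow(x$posthoc) == 0) {
    return(tibble::tibble(pair = character(0), p.value = numeric(0),
                          p.adjusted = numeric(0)))
  }
  tibble::tibble(pair = x$posthoc$pair, p.value = x$posthoc$wilcoxon_p_raw,
                 p.adjusted = x$posthoc$p_bonferroni)
}

#' @rdname dietquality-tidiers
#' @export
glance.dietquality_friedman <- function(x, ...) {
  tibble::tibble(statistic = x$friedman_statistic, df = x$friedman_df,
                 p.value = x$friedman_p, n = x$n)
}

#' @rdname dietquality-tidiers
#' @export
tidy.dietquality_permhomog <- function(x, ...) {
  tibble::tibble(
    test = c("dispersion", "permanova"),
    statistic = c(x$dispersion_F, x$permanova_F),
    df = c(x$dispersion_df, x$permanova_df),
    p.value = c(x$dispersion_p, x$permanova_p)
  )
}

#' @rdname dietquality-tidiers
#' @export
glance.dietquality_permhomog <- function(x, ...) {
  tibble::tibble(n = x$n, n_groups = x$n_groups,
                 n_permutations = x$n_permutations)
}

#' @export
print.dietquality_two_group <- function(x, ...) {
  cat("Normality-gated two-group comparison\n")
  cat("  test: ", x$test_used, "  statistic = ", format(x$statistic),
      ", p = ", format.pval(x$p_value), "\n", sep = "")
  print(x$group_summaries)
  invisible(x)
}

#' @export
print.dietquality_friedman <- function(x, ...) {
  cat("Friedman shift-day comparison (n = ", x$n, ")\n", sep = "")
  cat("  chi-squared = ", format(x$friedman_statistic), ", df = ",
      x$friedman_df, ", p = ", format.pval(x$friedman_p), "\n", sep = "")
  if (nrow(x$posthoc) > 0) print(x$posthoc)
  invisible(x)
}

#' @export
print.dietquality_permhomog <- function(x, ...) {
  cat("Permutation homogeneity tests (", x$n_permutations,
      " permutations)\n", sep = "")
  print(tidy(x))
  invisible(x)
}
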