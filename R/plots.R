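#' Bar chart of adherence-band percentages per index
#'
#' The cohort-level adherence summary as a grouped bar chart: for each
#' diet-quality index, the percentage of participants in each adherence
#' band.
#'
#' @param totals An [index_totals()] tibble.
#' @return A ggplot object.
#' @export
plot_adherence <- function(totals) {
  dist <- adherence_distribution(totals)
  band_levels <- c("low", "not_consistent", "moderate", "consistent",
                   "good", "high", "extremely_high", "perfect")
  dist$adherence <- factor(dist$adherence,
                           levels = intersect(band_levels, dist$adherence))
  ggplot2::ggplot(dist, ggplot2::aes(x = .data$index, y = .data$pct,
                                     fill = .data$adherence)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of participants",
                  fill = "adherence") +
    ggplot2::theme_minimal()
}

#' Bar chart of daily meal counts by shift-day type
#'
#' Percentage of diary days with each meal count, split by day type —
#' the layout used to show that meal frequency is stable across the shift
#' schedule.
#'
#' @param days A day-totals tibble from [day_totals()].
#' @return A ggplot object.
#' @export
plot_meal_counts <- function(days) {
  counts <- dplyr::mutate(
    dplyr::count(days, .data$day_type, .data$n_meals),
    pct = 100 * .data$n / sum(.data$n), .by = "day_type"
  )
  ggplot2::ggplot(counts, ggplot2::aes(x = factor(.data$n_meals),
                                       y = .data$pct,
                                       fill = .data$day_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "meals per day", y = "% of diary days",
                  fill = "day type") +
    ggplot2::theme_minimal()
}
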