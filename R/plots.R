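#' Plot a cohort shell profile as a histogram with SEM error bars
#'
#' The standard presentation of erosion analysis: mean normalized probe
#' proportion per shell (shell 1 = nuclear periphery, shell 5 = interior)
#' with standard-error bars.
#'
#' @param object A `cohort_profile`.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot cohort_profile
#' @export
autoplot.cohort_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$shell), y = .data$mean)) +
    ggplot2::geom_col(fill = "grey35", width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      width = 0.25) +
    ggplot2::labs(
      x = "shell (1 = periphery, 5 = interior)",
      y = "normalized probe / DAPI proportion",
      title = sprintf("%s (n = %d nuclei)", object$condition, object$n)) +
    ggplot2::theme_classic()
}

#' Side-by-side comparison of two cohort profiles with significance marks
#'
#' Plots both cohorts' mean ± SEM profiles and marks shells where the
#' per-shell Welch test falls below `alpha` with a filled square above the
#' bars.
#'
#' @param a,b `cohort_profile` objects.
#' @param alpha Per-shell significance level.
#'
#' @return A ggplot object.
#' @export
plot_cohort_comparison <- function(a, b, alpha = 0.05) {
  df <- dplyr::bind_rows(tidy(a), tidy(b))
  tests <- compare_cohorts(a, b, alpha = alpha)
  marks <- df |>
    dplyr::group_by(.data$shell) |>
    dplyr::summarise(y = max(.data$mean + .data$sem) * 1.08, .groups = "drop") |>
    dplyr::inner_join(dplyr::filter(tests, .data$significant), by = "shell")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$shell), y = .data$mean,
                                   fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(0.8), width = 0.25) +
    ggplot2::geom_point(data = marks, inherit.aes = FALSE, shape = 15, size = 3,
                        ggplot2::aes(x = factor(.data$shell), y = .data$y)) +
    ggplot2::labs(
      x = "shell (1 = periphery, 5 = interior)",
      y = "normalized probe / DAPI proportion",
      caption = sprintf("filled squares: Welch p < %.2g", alpha)) +
    ggplot2::scale_fill_grey(start = 0.3, end = 0.7) +
    ggplot2::theme_classic()
}

#' Plot a frequency distribution of periphery distances
#'
#' Line plot of count against distance (bin midpoints), the usual
#' presentation of 3D center-to-periphery measurements.
#'
#' @param object A [frequency_distribution()] result.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @method autoplot frequency_distribution
#' @export
autoplot.frequency_distribution <- function(object, ...) {
  df <- tibble(mid = (object$bin_start + object$bin_end) / 2,
               count = object$count)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "distance to nearest nuclear periphery (μm)",
                  y = "frequency") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
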