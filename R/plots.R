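#' Plot band power by condition
#'
#' @param band_powers Tibble from [condition_band_power()].
#' @return A ggplot.
#' @export
plot_power_bands <- function(band_powers) {
  ggplot2::ggplot(band_powers,
                  ggplot2::aes(x = .data$locomotion, y = .data$power,
                               fill = .data$laser_on)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "locomotion state", y = "band power (uV^2/Hz)",
                  fill = "laser on") +
    ggplot2::theme_minimal()
}

#' Plot laser-on/laser-off rate ratios by cell class
#'
#' @param ratios Tibble from [laser_rate_ratios()] with an added
#'   `cell_class` column.
#' @return A ggplot.
#' @export
plot_rate_ratios <- function(ratios) {
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$cell_class, y = .data$ratio,
                               colour = .data$cell_class)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, colour = "black") +
    ggplot2::labs(x = NULL, y = "laser-on / laser-off rate ratio") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Scatter of per-unit mutual information, laser-off vs laser-on
#'
#' @param mi_table Tibble from [mi_by_condition()] split by `laser_on`.
#' @return A ggplot with the unity line dashed.
#' @export
plot_mi_scatter <- function(mi_table) {
  wide <- mi_table |>
    dplyr::select("unit_id", "laser_on", "mi") |>
    tidyr::pivot_wider(names_from = "laser_on", values_from = "mi",
                       names_prefix = "laser_")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$laser_FALSE,
                                     y = .data$laser_TRUE)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "MI, laser off (bits)", y = "MI, laser on (bits)") +
    ggplot2::theme_minimal()
}

#' Plot accuracy versus matched population spike count
#'
#' @param curve A `count_matched_curve` from [count_matched_decoding()].
#' @param chance Optional chance level drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_count_matched <- function(curve, chance = NULL) {
  dat <- curve[!is.na(curve$accuracy), , drop = FALSE]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$bin_mid,
                                         y = .data$accuracy,
                                         colour = .data$laser_on)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$accuracy - .data$boot_se,
      ymax = .data$accuracy + .data$boot_se)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "population spike count", y = "decoding accuracy",
                  colour = "laser on") +
    ggplot2::theme_minimal()
  if (!is.null(chance)) {
    p <- p + ggplot2::geom_hline(yintercept = chance, linetype = "dashed")
  }
  p
}

#' @export
autoplot.count_matched_curve <- function(object, ...) {
  plot_count_matched(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
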