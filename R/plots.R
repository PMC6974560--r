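# ggplot2 views of the main result types.

#' Plot growth curves
#'
#' OD600 (log scale) and headspace CO2 over time, one panel per measurement,
#' coloured by replicate.
#'
#' @param growth_data Tidy growth table (see [simulate_growth_experiment()]).
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(growth_data) {
  d <- growth_data |>
    tidyr::pivot_longer(c("od600", "co2_ppm"),
                        names_to = "measure", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_h, .data$value,
                                  colour = .data$replicate)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(measure ~ isolate + substrate + temperature_c,
                        scales = "free_y") +
    ggplot2::labs(x = "Time (h)", y = NULL, colour = "Replicate") +
    ggplot2::theme_bw()
}

#' Plot the distribution of CUE across conditions
#'
#' Box plots of per-replicate CUE by temperature, faceted by substrate.
#'
#' @param records CUE records (e.g. from [qc_filter()]).
#' @return A ggplot object.
#' @export
plot_cue_distribution <- function(records) {
  ggplot2::ggplot(records, ggplot2::aes(factor(.data$temperature_c),
                                        .data$cue)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6, size = 1) +
    ggplot2::facet_wrap(~substrate) +
    ggplot2::labs(x = "Temperature (°C)", y = "CUE") +
    ggplot2::theme_bw()
}

#' Plot Q10 estimates with bootstrap intervals
#'
#' Log-scale Q10 by temperature range, coloured by substrate; estimates whose
#' 95% interval overlaps 1 (temperature-insensitive) are drawn faded, and the
#' horizontal line marks Q10 = 1.
#'
#' @param q10_tbl Output of [q10_table()].
#' @return A ggplot object.
#' @export
plot_q10 <- function(q10_tbl) {
  d <- q10_tbl |>
    dplyr::mutate(
      range = sprintf("%g-%g", .data$t_low, .data$t_high),
      insensitive = is.na(.data$sensitive) | !.data$sensitive
    )
  ggplot2::ggplot(d, ggplot2::aes(.data$range, .data$q10,
                                  colour = .data$substrate,
                                  alpha = .data$insensitive)) +
    ggplot2::geom_hline(yintercept = 1, colour = "grey40") +
    ggplot2::geom_point(position = ggplot2::position_jitter(width = 0.15),
                        size = 1.5) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 0.35, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(x = "Temperature range (°C)", y = "Q10 of CUE",
                  colour = "Substrate") +
    ggplot2::theme_bw()
}

#' Plot observed versus phylogenetically predicted tip values
#'
#' Scatter of leave-one-out predictions against observations with the 1:1
#' line.
#'
#' @param loo Output of [predict_tip_loo()].
#' @return A ggplot object.
#' @export
plot_tip_predictions <- function(loo) {
  ggplot2::ggplot(loo$predictions,
                  ggplot2::aes(.data$observed, .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Observed", y = "Predicted (leave-one-out)") +
    ggplot2::theme_bw()
}

#' Diagnostic plot for a PGLS fit
#'
#' Residuals against fitted values.
#'
#' @param object A `cue_pgls` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cue_pgls <- function(object, ...) {
  d <- tibble(fitted = fitted(object), residual = residuals(object))
  ggplot2::ggplot(d, ggplot2::aes(.data$fitted, .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Fitted", y = "Residual") +
    ggplot2::theme_bw()
}
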