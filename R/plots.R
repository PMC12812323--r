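#' Plot Kaplan-Meier cumulative event probability by group
#'
#' Step curves of the cumulative event probability (1 - survival) with the
#' 95% confidence band, one curve per group.
#'
#' @param object An `hfmos_km` tibble from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hfmos_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$cum_event,
                                       colour = .data$group, fill = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = 1 - .data$upper, ymax = 1 - .data$lower),
                         alpha = 0.15, colour = NA) +
    ggplot2::labs(x = "Days since index", y = "Cumulative event probability",
                  colour = "MOS tertile", fill = "MOS tertile") +
    ggplot2::theme_minimal()
}

#' Plot the longitudinal MOS distribution by interval
#'
#' Median and interquartile range of the patient-level interval means, with
#' the mean overlaid.
#'
#' @param interval_summary Output of [summarise_mos_by_interval()].
#' @return A ggplot object.
#' @export
plot_mos_trend <- function(interval_summary) {
  ggplot2::ggplot(interval_summary, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q25, ymax = .data$q75),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), colour = "black") +
    ggplot2::labs(x = "6-month interval since baseline",
                  y = "Medication optimization score (%)") +
    ggplot2::theme_minimal()
}

#' Plot the distribution of MSM weights
#'
#' @param weights A [build_msm_weights()] table.
#' @return A ggplot object.
#' @export
plot_weight_distribution <- function(weights) {
  long <- weights |>
    select("interval", iptw = "iptw_cum", ipcw = "ipcw_cum",
           combined = "weight") |>
    pivot_longer(-"interval", names_to = "kind", values_to = "w")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$interval), y = .data$w)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_wrap(~kind, scales = "free_y") +
    ggplot2::labs(x = "Interval", y = "Stabilized weight") +
    ggplot2::theme_minimal()
}
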