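#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: recorded
#' traces (signal and stimulus panels), I-F curves, and Ih step
#' measurements; plus `plot_class_proportions()` for cohort class
#' shares.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name drgexcite-plots
NULL

#' @rdname drgexcite-plots
#' @export
autoplot.ephys_trace <- function(object, ...) {
  units <- attr(object, "units", exact = TRUE)
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object), c("signal", "stimulus"),
    names_to = "channel", values_to = "value")
  long$channel <- factor(long$channel, levels = c("signal", "stimulus"),
                         labels = c(paste0("signal (", units$signal, ")"),
                                    paste0("stimulus (", units$stimulus, ")")))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL,
                  title = paste0(trace_mode(object), " recording")) +
    ggplot2::theme_minimal()
}

#' @rdname drgexcite-plots
#' @export
autoplot.if_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$current, .data$frequency)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "injected current (pA)", y = "firing frequency (Hz)",
                  title = "intensity-frequency relation") +
    ggplot2::theme_minimal()
}

#' @rdname drgexcite-plots
#' @export
autoplot.ih_measurement <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("instantaneous_current", "steady_state_current",
                              "ih_amplitude"),
                            names_to = "quantity", values_to = "pA")
  ggplot2::ggplot(df, ggplot2::aes(.data$command, .data$pA,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "command potential (mV)", y = "current (pA)",
                  title = "Ih step measurement") +
    ggplot2::theme_minimal()
}

#' @rdname drgexcite-plots
#' @param report A [proportion_shift_report()] tibble.
#' @export
plot_class_proportions <- function(report, ...) {
  long <- tidyr::pivot_longer(report, c("control_pct", "ccd_pct"),
                              names_to = "cohort", values_to = "pct")
  long$cohort <- sub("_pct$", "", long$cohort)
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$pct,
                                     fill = .data$cohort)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "share of cohort (%)",
                  title = "excitability class proportions") +
    ggplot2::theme_minimal()
}
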