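#' Quantify Ih from a voltage-clamp step family
#'
#' For each hyperpolarizing command step, Ih is the difference between
#' the steady-state current and the initial (instantaneous) current.
#' The instantaneous current is averaged 12-15 ms after command onset
#' (past the capacitance artifact, before appreciable HCN activation);
#' the steady-state current over the final `window_steady` ms of the
#' step. Ih is inward (negative) at hyperpolarized commands whenever the
#' HCN conductance is non-zero. The current density is the magnitude of
#' the Ih amplitude at the -120 mV step per pF of membrane capacitance.
#'
#' @param traces Voltage-clamp trace family (list, one trace per
#'   command), e.g. from [simulate_voltage_clamp()].
#' @param window_initial Length-2 ms window after command onset for the
#'   instantaneous current.
#' @param window_steady Length of the steady-state window at the end of
#'   the step, ms.
#' @param capacitance Membrane capacitance used for density, pF
#'   (typically from [passive_properties()] of the same neuron). `NULL`
#'   leaves the density `NA`.
#' @return An `ih_measurement` tibble, one row per command, columns
#'   `command` (mV, decreasing from -60), `instantaneous_current` (pA),
#'   `steady_state_current` (pA), `ih_amplitude` (pA); attributes
#'   `capacitance_used` (pF) and `current_density` (pA/pF at -120 mV).
#' @export
measure_ih <- function(traces, window_initial = c(12, 15),
                       window_steady = 100, capacitance = NULL) {
  if (inherits(traces, "ephys_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L)
  if (window_initial[1L] >= window_initial[2L])
    rlang::abort("`window_initial` must be an increasing (start, end) pair.")

  rows <- purrr::map(traces, function(tr) {
    assert_mode(tr, "voltage_clamp")
    win <- stimulus_window(tr)
    if (diff(win) < window_initial[2L] + window_steady)
      rlang::abort("command step too short for the measurement windows.")
    cmd <- trace_metadata(tr)$command %||%
      stats::median(tr$stimulus[tr$time >= win[1L] & tr$time < win[2L]])
    ini <- tr$time >= win[1L] + window_initial[1L] &
      tr$time < win[1L] + window_initial[2L]
    ss <- tr$time >= win[2L] - window_steady & tr$time < win[2L]
    tibble::tibble(command = cmd,
                   instantaneous_current = mean(tr$signal[ini]),
                   steady_state_current = mean(tr$signal[ss]))
  })
  out <- dplyr::bind_rows(rows)
  out$ih_amplitude <- out$steady_state_current - out$instantaneous_current
  out <- dplyr::arrange(out, dplyr::desc(.data$command))

  density <- NA_real_
  if (!is.null(capacitance)) {
    at_max <- out$command == -120
    if (!any(at_max))
      rlang::abort("current density needs the -120 mV step.",
                   class = "drgexcite_protocol_error")
    density <- abs(out$ih_amplitude[at_max][1L]) / capacitance
  }
  structure(out, class = c("ih_measurement", class(out)),
            capacitance_used = capacitance, current_density = density)
}

#' @export
glance.ih_measurement <- function(x, ...) {
  tibble::tibble(
    n_steps = nrow(x),
    ih_at_max_step = x$ih_amplitude[x$command == min(x$command)][1L],
    capacitance_used = attr(x, "capacitance_used", exact = TRUE) %||% NA_real_,
    current_density = attr(x, "current_density", exact = TRUE))
}

#' Measure Ih for one model neuron under the standard protocol
#'
#' Convenience wrapper: runs the -60 to -120 mV voltage-clamp family on
#' the parameter set, recovers the capacitance from a passive fit of a
#' small hyperpolarizing current step, and returns the Ih measurement.
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [vclamp_protocol()].
#' @param dt Integration step, ms.
#' @param ... Passed to [measure_ih()].
#' @return An `ih_measurement` (see [measure_ih()]).
#' @export
simulate_ih_measurement <- function(params, protocol = vclamp_protocol(),
                                    dt = 0.025, ...) {
  fam <- simulate_voltage_clamp(params, protocol, dt = dt)
  rest <- simulate_current_clamp(params, step_protocol(0, duration = 300,
                                                      onset = 50, tail = 0),
                                 dt = dt)
  small <- simulate_current_clamp(params, step_protocol(-20, duration = 400,
                                                        onset = 100),
                                  dt = dt)
  cm <- passive_properties(rest, small)$capacitance
  measure_ih(fam, capacitance = cm, ...)
}

#' Compare Ih current density across excitability classes
#'
#' Group means and SEMs of the Ih current density by assigned class,
#' together with a tidy per-neuron table ready for
#' [one_way_anova_lsd()], and a flag indicating whether the CLASS2_1
#' mean density is strictly the largest (the hallmark reported for these
#' neurons).
#'
#' @param measurements A data frame with one row per neuron: a `class`
#'   column and a `density` column (pA/pF).
#' @return An `ih_comparison` list: `summary` (class, n, mean_density,
#'   sem_density), `anova_input` (the per-neuron table), `class2_1_max`
#'   (logical), `min_class` (label of the smallest mean).
#' @export
compare_ih_across_classes <- function(measurements) {
  stopifnot(is.data.frame(measurements),
            all(c("class", "density") %in% names(measurements)))
  grp <- dplyr::count(measurements, .data$class)
  if (nrow(grp) < 2L)
    rlang::abort("need at least two classes to compare.",
                 class = "drgexcite_insufficient_replication")
  if (any(grp$n < 2L))
    rlang::abort(
      sprintf("class %s has fewer than 2 measurements.",
              paste(grp$class[grp$n < 2L], collapse = ", ")),
      class = "drgexcite_insufficient_replication")
  summ <- measurements |>
    dplyr::group_by(.data$class) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_density = mean(.data$density),
                     sem_density = stats::sd(.data$density) / sqrt(dplyr::n()),
                     .groups = "drop")
  m21 <- summ$mean_density[summ$class == "CLASS2_1"]
  others <- summ$mean_density[summ$class != "CLASS2_1"]
  flag <- length(m21) == 1L && all(m21 > others)
  structure(list(summary = summ,
                 anova_input = tibble::as_tibble(measurements),
                 class2_1_max = flag,
                 min_class = as.character(summ$class[which.min(summ$mean_density)])),
            class = "ih_comparison")
}

#' @export
print.ih_comparison <- function(x, ...) {
  cat("<ih_comparison> Ih current density by class\n")
  print(x$summary)
  cat(sprintf("CLASS2_1 strictly largest: %s; smallest mean: %s\n",
              x$class2_1_max, x$min_class))
  invisible(x)
}

#' @export
tidy.ih_comparison <- function(x, ...) x$summary

#' @export
glance.ih_comparison <- function(x, ...) {
  tibble::tibble(n_classes = nrow(x$summary),
                 class2_1_max = x$class2_1_max,
                 min_class = x$min_class)
}
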