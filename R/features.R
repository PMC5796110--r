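#' Extract excitability features from recorded protocols
#'
#' Pools the classification evidence for one neuron: the I-F statistics
#' from a family of depolarizing steps, the spike count and subthreshold
#' oscillation report from a depolarizing ramp, and (optionally) the
#' rheobase. `neuron_features()` works from traces; [simulate_features()]
#' runs the standard protocols on a parameter set first.
#'
#' @param step_traces List of current-clamp step traces (one per
#'   amplitude, shared timing).
#' @param ramp_trace Optional current-clamp ramp trace; without it the
#'   ramp/oscillation features are `NA` and Class 2 subdivision is not
#'   possible.
#' @param rheobase Optional rheobase (pA) to carry through.
#' @param ... Passed to [detect_spikes()].
#' @return An `excitability_features` one-row tibble: `rheobase`,
#'   `n_supra`, `if_slope`, `if_r2`, `if_cv`, `if_dynamic_range`,
#'   `max_spikes_per_step`, `max_current`, `ramp_spike_count`,
#'   `osc_present`, `osc_peak_frequency`, `osc_power_ratio`, plus the
#'   I-F curve itself in the `if_curve` list-column.
#' @export
neuron_features <- function(step_traces, ramp_trace = NULL, rheobase = NA_real_,
                            ...) {
  curve <- build_if_curve(step_traces, ...)
  st <- if_stats(curve)
  if (!is.null(ramp_trace)) {
    ramp_spikes <- detect_spikes(ramp_trace, ...)
    osc <- detect_oscillations(ramp_trace, ...)
    ramp <- tibble::tibble(ramp_spike_count = nrow(ramp_spikes),
                           osc_present = osc$present,
                           osc_peak_frequency = osc$peak_frequency,
                           osc_power_ratio = osc$peak_power_ratio)
  } else {
    ramp <- tibble::tibble(ramp_spike_count = NA_integer_,
                           osc_present = NA,
                           osc_peak_frequency = NA_real_,
                           osc_power_ratio = NA_real_)
  }
  out <- dplyr::bind_cols(tibble::tibble(rheobase = rheobase), st, ramp,
                          tibble::tibble(if_curve = list(curve)))
  structure(out, class = c("excitability_features", class(out)))
}

#' @rdname neuron_features
#' @param params A [neuron_params()] object.
#' @param step_amplitudes Step amplitudes for the I-F family, pA.
#' @param step_duration Step duration, ms.
#' @param ramp_peak,ramp_duration Ramp peak (pA) and duration (ms).
#' @param with_rheobase Also run the bisection rheobase search.
#' @param dt Integration step, ms.
#' @param out_dt Output sampling interval, ms.
#' @export
simulate_features <- function(params,
                              step_amplitudes = seq(100, 1000, by = 100),
                              step_duration = 500,
                              ramp_peak = 1000, ramp_duration = 1000,
                              with_rheobase = FALSE,
                              dt = 0.025, out_dt = 0.1, ...) {
  steps <- simulate_current_clamp(
    params, step_protocol(step_amplitudes, duration = step_duration),
    dt = dt, out_dt = out_dt)
  if (inherits(steps, "ephys_trace")) steps <- list(steps)
  ramp <- simulate_current_clamp(
    params, ramp_protocol(peak = ramp_peak, duration = ramp_duration),
    dt = dt, out_dt = out_dt)
  rheo <- NA_real_
  if (with_rheobase) {
    rheo <- find_rheobase(params, step_duration = step_duration, dt = dt,
                          ...)$rheobase
  }
  neuron_features(steps, ramp, rheobase = rheo, ...)
}
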