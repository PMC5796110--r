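#' Passive membrane properties from a resting trace and a small step
#'
#' Resting membrane potential (RMP) is the mean pre-stimulus voltage;
#' input resistance Rm is the steady-state voltage deflection divided by
#' the step current; membrane capacitance Cm is `tau / Rm` with `tau`
#' from a single-exponential fit of the relaxation onto the step. With
#' Rm in GOhm (mV/pA) and tau in ms, `tau / Rm` is in pF.
#'
#' @param resting_trace Current-clamp trace at zero (baseline) stimulus.
#' @param step_trace Current-clamp trace of a small subthreshold
#'   (typically hyperpolarizing) step.
#' @return A `passive_props` one-row tibble: `resting_potential` (mV),
#'   `input_resistance` (GOhm), `capacitance` (pF), `tau` (ms).
#' @export
passive_properties <- function(resting_trace, step_trace) {
  assert_mode(resting_trace, "current_clamp")
  assert_mode(step_trace, "current_clamp")
  rmp <- mean(resting_trace$signal)

  if (nrow(detect_spikes(step_trace)) > 0)
    rlang::abort("step trace contains spikes; passive fit would be contaminated.",
                 class = "drgexcite_contamination_error")

  win <- stimulus_window(step_trace)
  pre <- step_trace$time < win[1L]
  on <- step_trace$time >= win[1L] & step_trace$time < win[2L]
  baseline_i <- step_trace$stimulus[which(pre)[1L] %||% 1L]
  step_i <- stats::median(step_trace$stimulus[on]) - (baseline_i %||% 0)
  if (!is.finite(step_i) || step_i == 0)
    rlang::abort("step amplitude is zero; input resistance is undefined.")

  v0 <- if (any(pre)) mean(step_trace$signal[pre]) else step_trace$signal[1L]
  tail_n <- max(5L, round(0.2 * sum(on)))
  vss <- mean(step_trace$signal[utils::tail(which(on), tail_n)])
  rm <- (vss - v0) / step_i # mV / pA = GOhm
  if (rm <= 0) rlang::abort("non-positive input resistance estimate.")

  # single-exponential fit of the onset relaxation
  t_rel <- step_trace$time[on] - win[1L]
  v_rel <- step_trace$signal[on]
  defl <- vss - v0
  # crude tau from the 63% crossing seeds the nls fit
  i63 <- which(abs(v_rel - v0) >= 0.632 * abs(defl))[1L]
  tau0 <- if (is.na(i63)) diff(range(t_rel)) / 5 else max(t_rel[i63], 1e-3)
  fit_win <- t_rel <= min(6 * tau0, max(t_rel))
  df <- data.frame(t = t_rel[fit_win], v = v_rel[fit_win])
  tau <- tryCatch({
    fit <- stats::nls(v ~ vinf + a * exp(-t / tau),
                      data = df,
                      start = list(vinf = vss, a = v0 - vss, tau = tau0))
    unname(stats::coef(fit)[["tau"]])
  }, error = function(e) tau0)

  structure(tibble::tibble(resting_potential = rmp, input_resistance = rm,
                           capacitance = tau / rm, tau = tau),
            class = c("passive_props", "tbl_df", "tbl", "data.frame"))
}

#' Cell-inclusion quality-control filter
#'
#' A neuron is included when its resting membrane potential is strictly
#' more negative than -50 mV and it fires at least one overshooting
#' action potential (peak > 0 mV) at some tested step. A cell resting at
#' exactly -50.0 mV is excluded (strict inequality).
#'
#' @param props A `passive_props` row (or anything with a
#'   `resting_potential` column/field).
#' @param spikes_at_suprathreshold A `spike_train` pooled over the tested
#'   steps (peaks in mV).
#' @return `TRUE` if the neuron passes QC, otherwise `FALSE`.
#' @export
qc_filter <- function(props, spikes_at_suprathreshold) {
  rmp <- props[["resting_potential"]]
  isTRUE(rmp < -50) && any(spikes_at_suprathreshold[["peak"]] > 0)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a
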