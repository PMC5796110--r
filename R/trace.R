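#' Recording traces
#'
#' A trace is a tibble with columns `time` (ms), `signal` (membrane
#' potential in mV for current clamp, membrane current in pA for voltage
#' clamp) and `stimulus` (injected current in pA, or command potential in
#' mV), uniformly sampled at `dt` ms (default saved rate 10 kHz,
#' `dt = 0.1` ms). Mode, units and provenance (parameters, protocol,
#' amplitude, seed) travel as attributes.
#'
#' @param time,signal,stimulus Numeric vectors of equal length.
#' @param dt Sampling interval, ms.
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param metadata Named list of provenance fields.
#' @return An `ephys_trace` tibble.
#' @export
new_trace <- function(time, signal, stimulus, dt,
                      mode = c("current_clamp", "voltage_clamp"),
                      metadata = list()) {
  mode <- match.arg(mode)
  if (!(length(time) == length(signal) && length(signal) == length(stimulus)))
    rlang::abort("`time`, `signal` and `stimulus` must have equal length.")
  if (!all(is.finite(signal)))
    rlang::abort("trace contains non-finite samples.")
  if (!is.finite(dt) || dt <= 0) rlang::abort("`dt` must be > 0 ms.")
  units <- if (mode == "current_clamp") {
    list(signal = "mV", stimulus = "pA")
  } else {
    list(signal = "pA", stimulus = "mV")
  }
  out <- tibble::tibble(time = time, signal = signal, stimulus = stimulus)
  structure(out,
            class = c("ephys_trace", class(out)),
            dt = dt, mode = mode, units = units, metadata = metadata)
}

#' @export
print.ephys_trace <- function(x, ...) {
  cat(sprintf("<ephys_trace> %s, %d samples at dt = %g ms (%.4g ms)\n",
              trace_mode(x), nrow(x), trace_dt(x), nrow(x) * trace_dt(x)))
  NextMethod()
}

#' Trace accessors
#'
#' @param trace An `ephys_trace`.
#' @return `trace_dt()` the sampling interval (ms); `trace_mode()` the
#'   recording mode; `trace_metadata()` the provenance list.
#' @export
trace_dt <- function(trace) attr(trace, "dt", exact = TRUE)

#' @rdname trace_dt
#' @export
trace_mode <- function(trace) attr(trace, "mode", exact = TRUE)

#' @rdname trace_dt
#' @export
trace_metadata <- function(trace) attr(trace, "metadata", exact = TRUE)

assert_mode <- function(trace, mode) {
  if (!identical(trace_mode(trace), mode))
    rlang::abort(
      sprintf("expected a %s trace, got %s.", mode, trace_mode(trace)),
      class = "drgexcite_mode_error")
  invisible(trace)
}

# Protocol carried in trace metadata (NULL for hand-built traces).
trace_protocol <- function(trace) trace_metadata(trace)$protocol

# Stimulus window (onset, offset) in ms, from metadata when available,
# otherwise inferred from the stimulus channel departing its initial value.
stimulus_window <- function(trace) {
  pr <- trace_protocol(trace)
  if (!is.null(pr)) return(c(pr$onset, pr$onset + pr$duration))
  s <- trace$stimulus
  idx <- which(s != s[1L])
  if (length(idx) == 0L) return(c(0, nrow(trace) * trace_dt(trace)))
  c(trace$time[idx[1L]], trace$time[idx[length(idx)]])
}
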