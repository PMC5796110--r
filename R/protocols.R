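#' Stimulus protocols
#'
#' Constructors for the three stimulation protocols used throughout the
#' pipeline. Amplitudes must be non-empty and strictly monotone in list
#' order; durations are in ms.
#'
#' * `step_protocol()` - square depolarizing (or hyperpolarizing) current
#'   steps from a baseline, one trace per amplitude (pA).
#' * `ramp_protocol()` - a linear current ramp from the baseline to the
#'   peak amplitude over `duration` ms (the standard excitability ramp is
#'   1000 pA over 1000 ms).
#' * `vclamp_protocol()` - voltage-clamp steps from a -60 mV holding
#'   potential to hyperpolarizing command potentials between -60 and
#'   -120 mV (default -10 mV increments, 2.5 s duration), the protocol
#'   used to activate and measure Ih.
#'
#' @param amplitudes Step amplitudes in pA (steps) or command potentials
#'   in mV (voltage clamp), strictly monotone.
#' @param baseline Holding current before/after the stimulus, pA.
#' @param onset Stimulus onset time, ms.
#' @param duration Stimulus duration, ms.
#' @param tail Recording time after stimulus offset, ms.
#' @param peak Ramp peak amplitude, pA.
#' @param holding_potential Voltage-clamp holding potential, mV.
#' @return A `stimulus_protocol` object (a classed list).
#' @name protocols
NULL

new_protocol <- function(kind, amplitudes, baseline, onset, duration, tail,
                         holding_potential = NULL) {
  if (length(amplitudes) < 1L)
    rlang::abort("`amplitudes` must be non-empty.")
  if (length(amplitudes) > 1L) {
    d <- diff(amplitudes)
    if (!(all(d > 0) || all(d < 0)))
      rlang::abort("`amplitudes` must be strictly monotone in list order.")
  }
  if (duration <= 0) rlang::abort("`duration` must be > 0 ms.")
  structure(list(kind = kind, amplitudes = as.numeric(amplitudes),
                 baseline = baseline, onset = onset, duration = duration,
                 tail = tail, holding_potential = holding_potential),
            class = "stimulus_protocol")
}

#' @rdname protocols
#' @export
step_protocol <- function(amplitudes, baseline = 0, onset = 100,
                          duration = 500, tail = 100) {
  new_protocol("current_step", amplitudes, baseline, onset, duration, tail)
}

#' @rdname protocols
#' @export
ramp_protocol <- function(peak = 1000, baseline = 0, onset = 100,
                          duration = 1000, tail = 100) {
  new_protocol("current_ramp", peak, baseline, onset, duration, tail)
}

#' @rdname protocols
#' @export
vclamp_protocol <- function(amplitudes = seq(-60, -120, by = -10),
                            holding_potential = -60, onset = 100,
                            duration = 2500, tail = 200) {
  if (any(amplitudes < -120 | amplitudes > -60))
    rlang::abort(
      "voltage-clamp command potentials must lie in [-120, -60] mV.",
      class = "drgexcite_protocol_error")
  if (holding_potential != -60)
    rlang::abort("the Ih protocol uses a -60 mV holding potential.",
                 class = "drgexcite_protocol_error")
  new_protocol("vclamp_step", amplitudes, baseline = NA_real_,
               onset = onset, duration = duration, tail = tail,
               holding_potential = holding_potential)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s: %d amplitude(s), onset %g ms, duration %g ms\n",
              x$kind, length(x$amplitudes), x$onset, x$duration))
  invisible(x)
}

protocol_total_ms <- function(protocol) {
  protocol$onset + protocol$duration + protocol$tail
}

# Sample the stimulus waveform for one amplitude on the integration grid.
protocol_stim_vector <- function(protocol, amplitude, dt) {
  n <- round(protocol_total_ms(protocol) / dt)
  t <- (seq_len(n) - 1) * dt
  on <- t >= protocol$onset & t < protocol$onset + protocol$duration
  if (protocol$kind == "current_step") {
    stim <- rep(protocol$baseline, n)
    stim[on] <- amplitude
  } else if (protocol$kind == "current_ramp") {
    stim <- rep(protocol$baseline, n)
    frac <- (t[on] - protocol$onset) / protocol$duration
    stim[on] <- protocol$baseline + frac * (amplitude - protocol$baseline)
  } else if (protocol$kind == "vclamp_step") {
    stim <- rep(protocol$holding_potential, n)
    stim[on] <- amplitude
  } else {
    rlang::abort(paste0("unknown protocol kind: ", protocol$kind))
  }
  stim
}
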