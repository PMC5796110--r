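#' Simulate current-clamp recordings
#'
#' Integrates the conductance model under a current-step or current-ramp
#' protocol and returns membrane-potential traces. The model is settled
#' to its resting state at the baseline current before the recording
#' starts, so with zero stimulus every shipped archetype rests more
#' negative than -50 mV. Integration uses a fixed step `dt <= 0.025` ms;
#' the saved trace is subsampled to `out_dt` (default 0.1 ms, i.e. the
#' standard 10 kHz acquisition rate). Identical parameters, protocol,
#' `dt` and seed give bit-identical traces.
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [step_protocol()] or [ramp_protocol()].
#' @param dt Integration step, ms (must be <= 0.025).
#' @param out_dt Output sampling interval, ms (a multiple of `dt`).
#' @param noise_sd Optional Gaussian recording-noise SD added to the
#'   saved signal (mV); 0 disables noise.
#' @param seed Seed for the recording noise (ignored when `noise_sd = 0`).
#' @param settle_ms Settling time at baseline before the recording, ms.
#' @return A single `ephys_trace` when the protocol has one amplitude,
#'   otherwise a list of traces (one per amplitude, in protocol order).
#' @export
simulate_current_clamp <- function(params, protocol, dt = 0.025,
                                   out_dt = 0.1, noise_sd = 0, seed = NULL,
                                   settle_ms = 1500) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "stimulus_protocol"))
  if (!protocol$kind %in% c("current_step", "current_ramp"))
    rlang::abort("current-clamp simulation needs a step or ramp protocol.",
                 class = "drgexcite_protocol_error")
  if (dt > 0.025 + 1e-12)
    rlang::abort("integration requires dt <= 0.025 ms.")
  rec <- as.integer(round(out_dt / dt))
  if (abs(rec * dt - out_dt) > 1e-9)
    rlang::abort("`out_dt` must be an integer multiple of `dt`.")
  sp <- as_sim_pars(params)

  traces <- lapply(seq_along(protocol$amplitudes), function(i) {
    amp <- protocol$amplitudes[[i]]
    stim <- protocol_stim_vector(protocol, amp, dt)
    v <- .sim_current_clamp(sp, stim, dt, rec, settle_ms, params$leak_reversal)
    keep <- seq(1L, length(stim), by = rec)
    sig <- if (noise_sd > 0) {
      add_recording_noise(v, noise_sd, seed, i)
    } else v
    new_trace(time = (keep - 1) * dt, signal = sig, stimulus = stim[keep],
              dt = out_dt, mode = "current_clamp",
              metadata = list(params = params, protocol = protocol,
                              amplitude = amp, dt_integration = dt,
                              seed = seed, noise_sd = noise_sd))
  })
  if (length(traces) == 1L) traces[[1L]] else traces
}

#' Simulate a voltage-clamp step family (Ih protocol)
#'
#' Holds the model at -60 mV, steps the command to each hyperpolarizing
#' potential for the protocol duration, and records the membrane current
#' under an ideal clamp. With a non-zero HCN conductance the current at
#' commands below -60 mV relaxes inward over hundreds of ms as the
#' channel activates; with `g_h = 0` the current is flat after the
#' instantaneous leak step.
#'
#' @inheritParams simulate_current_clamp
#' @param protocol A [vclamp_protocol()].
#' @param noise_sd Optional Gaussian recording-noise SD on the current, pA.
#' @return A list of `ephys_trace` objects, one per command potential.
#' @export
simulate_voltage_clamp <- function(params, protocol, dt = 0.025,
                                   out_dt = 0.1, noise_sd = 0, seed = NULL,
                                   settle_ms = 2000) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "stimulus_protocol"))
  if (protocol$kind != "vclamp_step")
    rlang::abort("voltage-clamp simulation needs a vclamp protocol.",
                 class = "drgexcite_protocol_error")
  rec <- as.integer(round(out_dt / dt))
  if (abs(rec * dt - out_dt) > 1e-9)
    rlang::abort("`out_dt` must be an integer multiple of `dt`.")
  sp <- as_sim_pars(params)

  lapply(seq_along(protocol$amplitudes), function(i) {
    cmd <- protocol$amplitudes[[i]]
    stim <- protocol_stim_vector(protocol, cmd, dt)
    cur <- .sim_voltage_clamp(sp, stim, dt, rec, settle_ms)
    keep <- seq(1L, length(stim), by = rec)
    sig <- if (noise_sd > 0) add_recording_noise(cur, noise_sd, seed, i) else cur
    new_trace(time = (keep - 1) * dt, signal = sig, stimulus = stim[keep],
              dt = out_dt, mode = "voltage_clamp",
              metadata = list(params = params, protocol = protocol,
                              command = cmd, dt_integration = dt,
                              seed = seed, noise_sd = noise_sd))
  })
}

# Seeded additive recording noise; leaves the caller's RNG state intact.
add_recording_noise <- function(x, sd, seed, trace_index) {
  s <- if (is.null(seed)) stats::runif(1, 0, 2^30) else seed + 7919 * trace_index
  withr::with_seed(as.integer(s %% .Machine$integer.max),
                   x + stats::rnorm(length(x), 0, sd))
}
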