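#' Detect subthreshold membrane-potential oscillations
#'
#' Operates on the stimulus window of a current-clamp ramp trace.
#' Spikes are excised (a short window around each peak is blanked and
#' linearly interpolated), the slow ramp depolarization is removed with
#' a running-mean detrend, and a periodogram is computed. Oscillations
#' are reported present when the peak power inside `band` exceeds the
#' median broadband power by at least `min_ratio` and the band-limited
#' signal is larger than `min_rms` (guards against declaring structure
#' in numerically silent traces).
#'
#' @param trace A current-clamp `ephys_trace` (typically a ramp response).
#' @param band Frequency band to search, Hz (default 20-200 Hz, the
#'   range of the subthreshold oscillations that accompany ramp-evoked
#'   bursting).
#' @param min_ratio Presence threshold: peak band power over median
#'   broadband power.
#' @param min_rms Minimum root-mean-square amplitude of the detrended
#'   subthreshold signal, mV.
#' @param blank Length-2 ms window blanked around each spike peak
#'   (before, after).
#' @param ... Passed to [detect_spikes()].
#' @return An `osc_report`: one-row tibble with `present`,
#'   `peak_frequency` (Hz), `peak_power_ratio`.
#' @export
detect_oscillations <- function(trace, band = c(20, 200), min_ratio = 5,
                                min_rms = 0.1, blank = c(3, 8), ...) {
  assert_mode(trace, "current_clamp")
  dt <- trace_dt(trace)
  fs <- 1000 / dt # Hz
  win <- stimulus_window(trace)
  idx <- which(trace$time >= win[1L] & trace$time < win[2L])
  seg_ms <- length(idx) * dt
  if (seg_ms < 4 * 1000 / band[1L])
    rlang::abort(sprintf(
      "segment (%.0f ms) shorter than 4 periods of the band's low edge (%.0f ms).",
      seg_ms, 4 * 1000 / band[1L]), class = "drgexcite_insufficient_data")

  v <- trace$signal[idx]
  t <- trace$time[idx]

  # excise spikes, interpolate across the gaps
  sp <- detect_spikes(trace, ...)
  keep <- rep(TRUE, length(v))
  for (ts in sp$spike_time) {
    keep[t >= ts - blank[1L] & t <= ts + blank[2L]] <- FALSE
  }
  if (!any(keep)) keep[c(1L, length(keep))] <- TRUE
  v <- stats::approx(t[keep], v[keep], xout = t, rule = 2)$y

  # running-mean detrend removes the ramp depolarization (< band Hz)
  w <- max(3L, round(1000 / band[1L] / dt))
  if (w %% 2L == 0L) w <- w + 1L
  trend <- stats::filter(v, rep(1 / w, w), sides = 2)
  half <- (w - 1L) / 2L
  trend[seq_len(half)] <- trend[half + 1L]
  trend[(length(v) - half + 1L):length(v)] <- trend[length(v) - half]
  resid <- v - as.numeric(trend)

  pg <- stats::spec.pgram(stats::ts(resid, frequency = fs), taper = 0.1,
                          detrend = TRUE, plot = FALSE)
  freq <- pg$freq
  pow <- pg$spec
  in_band <- freq >= band[1L] & freq <= band[2L]
  broad <- freq >= 1
  if (!any(in_band) || sum(pow[broad]) <= 0) {
    return(new_osc_report(FALSE, NA_real_, 0))
  }
  peak_i <- which(in_band)[which.max(pow[in_band])]
  ratio <- pow[peak_i] / stats::median(pow[broad])
  band_rms <- sqrt(stats::sd(resid)^2 * sum(pow[in_band]) / sum(pow))
  present <- is.finite(ratio) && ratio >= min_ratio && band_rms >= min_rms
  new_osc_report(present, freq[peak_i], ratio)
}

new_osc_report <- function(present, peak_frequency, ratio) {
  out <- tibble::tibble(present = present,
                        peak_frequency = peak_frequency,
                        peak_power_ratio = ratio)
  structure(out, class = c("osc_report", class(out)))
}
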