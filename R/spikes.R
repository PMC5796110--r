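#' Detect action potentials in a current-clamp trace
#'
#' A spike is counted at each upward crossing of `threshold` that is
#' followed by a local maximum overshooting 0 mV (the "overshooting
#' action potential" criterion used for cell inclusion). Crossings within
#' `refractory` ms of a counted spike's peak are ignored.
#'
#' @param trace A current-clamp `ephys_trace`.
#' @param threshold Detection threshold, mV.
#' @param refractory Refractory window after a counted spike, ms.
#' @param min_peak Minimum peak voltage for a counted spike, mV
#'   (0 mV = overshoot).
#' @return A `spike_train` tibble with columns `spike_time` (ms, at the
#'   peak) and `peak` (mV), plus `threshold`/`refractory` attributes.
#' @export
detect_spikes <- function(trace, threshold = -10, refractory = 2,
                          min_peak = 0) {
  assert_mode(trace, "current_clamp")
  v <- trace$signal
  t <- trace$time
  n <- length(v)

  cross <- which(v[-1L] >= threshold & v[-n] < threshold) + 1L
  times <- numeric(0)
  peaks <- numeric(0)
  last_peak_t <- -Inf
  for (i in cross) {
    if (t[i] - last_peak_t < refractory) next
    j <- i
    while (j < n && v[j + 1L] >= threshold) j <- j + 1L
    seg <- i:j
    k <- seg[which.max(v[seg])]
    if (v[k] > min_peak) {
      if (t[k] - last_peak_t < refractory) next
      times <- c(times, t[k])
      peaks <- c(peaks, v[k])
      last_peak_t <- t[k]
    }
  }
  new_spike_train(times, peaks, threshold, refractory)
}

#' Construct a spike train
#'
#' Low-level constructor for a detected (or hand-built) spike train:
#' strictly increasing peak times with their peak voltages.
#'
#' @param spike_time Peak times, ms, strictly increasing.
#' @param peak Peak voltages, mV.
#' @param threshold,refractory Detection settings to record, mV / ms.
#' @return A `spike_train` tibble.
#' @export
new_spike_train <- function(spike_time, peak, threshold = -10, refractory = 2) {
  out <- tibble::tibble(spike_time = spike_time, peak = peak)
  if (is.unsorted(spike_time, strictly = TRUE) && length(spike_time) > 1L)
    rlang::abort("spike times must be strictly increasing.")
  structure(out, class = c("spike_train", class(out)),
            threshold = threshold, refractory = refractory)
}

#' Mean firing frequency over a time window
#'
#' Spike count inside the window divided by the window length.
#'
#' @param spikes A `spike_train` (from [detect_spikes()]).
#' @param window Numeric length-2, window `(start, end)` in ms.
#' @return Frequency in Hz.
#' @export
firing_frequency <- function(spikes, window) {
  if (length(window) != 2L || !all(is.finite(window)) || diff(window) <= 0)
    rlang::abort("`window` must be a finite (start, end) pair with end > start.")
  n <- sum(spikes$spike_time >= window[1L] & spikes$spike_time < window[2L])
  1000 * n / diff(window)
}
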