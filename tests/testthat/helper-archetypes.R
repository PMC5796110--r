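# Simulation results shared across test files (computed once per run).
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

archetype_features <- function(cl) {
  cached(paste0("feat_", cl), simulate_features(drg_archetype(cl)))
}

archetype_rheobase <- function(cl) {
  cached(paste0("rheo_", cl), find_rheobase(drg_archetype(cl))$rheobase)
}

archetype_passive <- function(cl) {
  cached(paste0("pass_", cl), {
    p <- drg_archetype(cl)
    rest <- simulate_current_clamp(p, step_protocol(0, duration = 300,
                                                    onset = 50, tail = 0))
    small <- simulate_current_clamp(p, step_protocol(-20, duration = 400))
    passive_properties(rest, small)
  })
}

archetype_ih <- function(cl) {
  cached(paste0("ih_", cl), {
    measure_ih(simulate_voltage_clamp(drg_archetype(cl), vclamp_protocol()),
               capacitance = 100)
  })
}

# Hand-built current-clamp trace from a voltage vector (dt in ms).
make_cc_trace <- function(v, dt = 0.1, stimulus = rep(0, length(v))) {
  new_trace(time = (seq_along(v) - 1) * dt, signal = v, stimulus = stimulus,
            dt = dt, mode = "current_clamp")
}

# Gaussian depolarization bump, used to compose synthetic spike traces.
bump <- function(t, centre, peak, base = -60, width = 1) {
  base + (peak - base) * exp(-((t - centre) / width)^2)
}

# Independent brute-force spike scan: walk every sample, find threshold
# crossings, local maxima and refractory violations directly.
brute_force_spikes <- function(v, t, threshold = -10, refractory = 2,
                               min_peak = 0) {
  times <- numeric(0)
  last <- -Inf
  i <- 2L
  n <- length(v)
  while (i <= n) {
    if (v[i] >= threshold && v[i - 1L] < threshold) {
      j <- i
      while (j < n && v[j + 1L] >= threshold) j <- j + 1L
      pk <- which.max(v[i:j]) + i - 1L
      if (v[pk] > min_peak && t[pk] - last >= refractory) {
        times <- c(times, t[pk])
        last <- t[pk]
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  times
}
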