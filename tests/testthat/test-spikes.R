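test_that("three overshooting depolarizations give three spikes at their peaks", {
  t <- seq(0, 400, by = 0.1)
  v <- pmax(bump(t, 100, 20), pmax(bump(t, 200, 20), bump(t, 300, 20)))
  sp <- detect_spikes(make_cc_trace(v))
  expect_identical(nrow(sp), 3L)
  expect_equal(sp$spike_time, c(100, 200, 300), tolerance = 0.11)
  expect_true(all(sp$peak > 0))
})

test_that("spike detection matches an exhaustive sample-by-sample scan", {
  set.seed(202)
  for (rep in 1:15) {
    t <- seq(0, 500, by = 0.1)
    n_ev <- sample(0:8, 1)
    v <- rep(-60, length(t))
    if (n_ev > 0) {
      centres <- sort(runif(n_ev, 10, 490))
      peaks <- runif(n_ev, -20, 30) # some sub-overshoot, some counted
      for (k in seq_len(n_ev)) v <- pmax(v, bump(t, centres[k], peaks[k]))
    }
    got <- detect_spikes(make_cc_trace(v))$spike_time
    want <- brute_force_spikes(v, t)
    expect_equal(got, want)
  }
})

test_that("non-overshooting depolarizations and refractory doublets are not counted", {
  t <- seq(0, 200, by = 0.1)
  expect_identical(nrow(detect_spikes(make_cc_trace(bump(t, 100, -5)))), 0L)
  # two crossings 1 ms apart: second falls in the 2 ms refractory window
  v <- pmax(bump(t, 100, 25, width = 0.3), bump(t, 101, 25, width = 0.3))
  expect_identical(nrow(detect_spikes(make_cc_trace(v))), 1L)
})

test_that("constant traces and voltage-clamp traces are handled", {
  expect_identical(nrow(detect_spikes(make_cc_trace(rep(-60, 1000)))), 0L)
  vc <- new_trace(time = 0:9, signal = rep(0, 10), stimulus = rep(-60, 10),
                  dt = 1, mode = "voltage_clamp")
  expect_error(detect_spikes(vc), class = "drgexcite_mode_error")
})

test_that("firing frequency is count over window length", {
  sp <- new_spike_train(seq(50, 400, by = 50), rep(20, 8)) # 8 spikes
  expect_equal(firing_frequency(sp, c(0, 500)), 16)
  expect_equal(firing_frequency(new_spike_train(numeric(0), numeric(0)),
                                c(0, 500)), 0)
  # shifting a window that still contains every spike leaves it unchanged
  expect_equal(firing_frequency(sp, c(25, 525)), 16)
  expect_error(firing_frequency(sp, c(100, 100)), "window")
  expect_error(firing_frequency(sp, c(200, 100)), "window")
})
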