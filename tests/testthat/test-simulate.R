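passive_cell <- function(cm = 100, gl = 10, el = -60) {
  neuron_params(membrane_capacitance = cm, leak_conductance = gl,
                leak_reversal = el)
}

test_that("passive step response matches the closed-form RC solution", {
  p <- passive_cell() # tau = C/g = 10 ms, deflection = 100 pA / 10 nS = 10 mV
  tr <- simulate_current_clamp(p, step_protocol(100, onset = 50,
                                                duration = 200, tail = 50))
  on <- tr$time >= 50 & tr$time < 250
  expected <- -60 + 10 * (1 - exp(-(tr$time[on] - 50) / 10))
  expect_lt(max(abs(tr$signal[on] - expected)), 0.1) # 1% of the deflection
  # steady state and relaxation time constant
  expect_equal(mean(tr$signal[tr$time >= 200 & tr$time < 250]), -50,
               tolerance = 1e-3)
  v_tau <- tr$signal[which.min(abs(tr$time - 60))]
  expect_equal(v_tau, -60 + 10 * (1 - exp(-1)), tolerance = 1e-2)
})

test_that("zero stimulus leaves a passive cell at its leak reversal", {
  tr <- simulate_current_clamp(passive_cell(), step_protocol(0, duration = 300))
  expect_lt(max(abs(tr$signal - (-60))), 1e-6)
})

test_that("simulation is deterministic for fixed params, protocol, dt and seed", {
  p <- drg_archetype("CLASS2_1")
  t1 <- simulate_current_clamp(p, step_protocol(600), seed = 42)
  t2 <- simulate_current_clamp(p, step_protocol(600), seed = 42)
  expect_identical(t1$signal, t2$signal)
  n1 <- simulate_current_clamp(p, step_protocol(600), noise_sd = 0.5, seed = 7)
  n2 <- simulate_current_clamp(p, step_protocol(600), noise_sd = 0.5, seed = 7)
  expect_identical(n1$signal, n2$signal)
  n3 <- simulate_current_clamp(p, step_protocol(600), noise_sd = 0.5, seed = 8)
  expect_false(identical(n1$signal, n3$signal))
})

test_that("halving dt preserves spike count and shifts spike times < 0.5 ms", {
  for (cl in c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3")) {
    p <- drg_archetype(cl)
    amp <- 2 * archetype_rheobase(cl)
    s1 <- detect_spikes(simulate_current_clamp(p, step_protocol(amp), dt = 0.025))
    s2 <- detect_spikes(simulate_current_clamp(p, step_protocol(amp), dt = 0.0125))
    expect_identical(nrow(s1), nrow(s2))
    expect_lt(max(abs(s1$spike_time - s2$spike_time)), 0.5)
  }
})

test_that("every shipped archetype rests more negative than -50 mV", {
  for (cl in c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3")) {
    expect_lt(archetype_passive(cl)$resting_potential, -50)
  }
})

test_that("Class 1 ramp firing accelerates through the ramp", {
  tr <- simulate_current_clamp(drg_archetype("CLASS1"), ramp_protocol())
  isi <- diff(detect_spikes(tr)$spike_time)
  expect_gt(length(isi), 10)
  # instantaneous frequency (1/ISI) increases monotonically, up to solver
  # resolution on successive intervals
  expect_true(all(diff(isi) < 0.5))
  expect_lt(isi[length(isi)], isi[1] / 2)
})

test_that("protocol validation rejects malformed stimuli", {
  expect_error(step_protocol(numeric(0)), "non-empty")
  expect_error(step_protocol(c(100, 300, 200)), "monotone")
  expect_error(step_protocol(100, duration = 0), "duration")
  expect_error(vclamp_protocol(amplitudes = c(-60, -130)),
               class = "drgexcite_protocol_error")
  expect_error(vclamp_protocol(holding_potential = -70),
               class = "drgexcite_protocol_error")
  expect_error(
    simulate_current_clamp(passive_cell(), vclamp_protocol()),
    class = "drgexcite_protocol_error")
  expect_error(
    simulate_voltage_clamp(passive_cell(), step_protocol(100)),
    class = "drgexcite_protocol_error")
  expect_error(simulate_current_clamp(passive_cell(), step_protocol(100),
                                      dt = 0.05), "dt")
})

test_that("voltage-clamp family develops inward current only with HCN", {
  fam <- simulate_voltage_clamp(drg_archetype("CLASS2_1"), vclamp_protocol())
  m <- measure_ih(fam, capacitance = 100)
  expect_true(all(m$ih_amplitude[m$command < -60] < -10))
  fam0 <- simulate_voltage_clamp(block_ih(drg_archetype("CLASS2_1")),
                                 vclamp_protocol())
  m0 <- measure_ih(fam0, capacitance = 100)
  expect_lt(max(abs(m0$ih_amplitude)), 0.5)
})

test_that("block_ih zeroes only the HCN conductance and is idempotent", {
  p <- drg_archetype("CLASS2_1")
  b <- block_ih(p)
  expect_identical(b$hcn$max_conductance, 0)
  p0 <- p; p0$hcn$max_conductance <- 0
  expect_identical(b, p0)
  expect_identical(block_ih(b), b)
})
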