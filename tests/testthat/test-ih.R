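# Surrogate with first-order HCN activation at a fixed time constant: the
# clamp current follows I(t) = I_leak + g_h * r(t) * (V - E_h) with
# r(t) = r0 + (r_inf - r0) * (1 - exp(-t / tau)), which gives a closed
# form for the windowed Ih measurement.
surrogate <- function(tau, gh = 5) {
  neuron_params(membrane_capacitance = 100, leak_conductance = 10,
                leak_reversal = -60,
                hcn = list(max_conductance = gh, half_activation = -90,
                           slope = -6, tau_min = tau, tau_amp = 0,
                           reversal = -30))
}

closed_form_ih <- function(tau, gh = 5, cmd = -120,
                           win_init = c(12, 15), win_ss = 100,
                           duration = 2500) {
  rinf <- function(v) 1 / (1 + exp(-(v + 90) / (-6)))
  r0 <- rinf(-60)
  ih_t <- function(t) gh * (r0 + (rinf(cmd) - r0) * (1 - exp(-t / tau))) *
    (cmd + 30)
  mean(ih_t(seq(duration - win_ss, duration, by = 0.1))) -
    mean(ih_t(seq(win_init[1], win_init[2], by = 0.1)))
}

test_that("measured Ih matches the first-order closed form within 2%", {
  for (tau in c(100, 300, 500)) {
    tr <- simulate_voltage_clamp(surrogate(tau),
                                 vclamp_protocol(amplitudes = c(-60, -120)))
    m <- measure_ih(tr, capacitance = 100)
    got <- m$ih_amplitude[m$command == -120]
    expect_equal(got, closed_form_ih(tau), tolerance = 0.02)
    expect_lt(got, 0) # inward
  }
})

test_that("a blocked or HCN-free model measures Ih at the noise floor", {
  fam <- simulate_voltage_clamp(block_ih(drg_archetype("CLASS2_1")),
                                vclamp_protocol())
  m <- measure_ih(fam, capacitance = 100)
  expect_true(all(abs(m$ih_amplitude) < 0.5))
})

test_that("Ih measurement is linear in the current scale", {
  fam <- simulate_voltage_clamp(drg_archetype("CLASS1"), vclamp_protocol())
  m1 <- measure_ih(fam, capacitance = 100)
  scaled <- lapply(fam, function(tr) {
    tr$signal <- 2.5 * tr$signal
    tr
  })
  m2 <- measure_ih(scaled, capacitance = 100)
  expect_equal(m2$ih_amplitude, 2.5 * m1$ih_amplitude, tolerance = 1e-12)
})

test_that("per-step table is ordered -60 to -120 with protocol checks", {
  m <- archetype_ih("CLASS2_1")
  expect_true(all(diff(m$command) < 0))
  expect_identical(m$command[1], -60)
  expect_identical(m$command[nrow(m)], -120)
  # density requires the -120 mV step
  fam <- simulate_voltage_clamp(drg_archetype("CLASS1"),
                                vclamp_protocol(amplitudes = c(-60, -90)))
  expect_error(measure_ih(fam, capacitance = 100),
               class = "drgexcite_protocol_error")
  expect_error(measure_ih(fam, window_initial = c(15, 12)), "increasing")
})

test_that("archetype Ih densities follow the class ordering", {
  d <- vapply(c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3"),
              function(cl) attr(archetype_ih(cl), "current_density"),
              numeric(1))
  expect_gt(d[["CLASS2_1"]], d[["CLASS1"]])
  expect_gte(d[["CLASS1"]], d[["CLASS2_2"]])
  expect_gt(d[["CLASS2_2"]], d[["CLASS3"]])
})

test_that("class comparison summarises densities and flags the 2-1 maximum", {
  set.seed(5)
  df <- tibble::tibble(
    class = rep(c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3"),
                times = c(7, 11, 9, 8)),
    density = c(rnorm(7, 5), rnorm(11, 16), rnorm(9, 4), rnorm(8, 1)))
  cmp <- compare_ih_across_classes(df)
  expect_true(cmp$class2_1_max)
  expect_identical(cmp$min_class, "CLASS3")
  an <- one_way_anova_lsd(cmp$anova_input, density, class)
  expect_identical(unname(an$df), c(3L, 31L))
  # identical constant groups: equal means, no maximum
  flat <- tibble::tibble(class = rep(c("CLASS1", "CLASS2_1"), each = 3),
                         density = 2)
  cmp0 <- compare_ih_across_classes(flat)
  expect_false(cmp0$class2_1_max)
  expect_true(all(cmp0$summary$mean_density == 2))
  expect_error(
    compare_ih_across_classes(
      tibble::tibble(class = c("CLASS1", "CLASS1", "CLASS3"),
                     density = 1:3)),
    class = "drgexcite_insufficient_replication")
})
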