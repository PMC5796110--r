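test_that("Class 1 intensity-frequency relation is approximately linear", {
  f <- archetype_features("CLASS1")
  expect_gt(f$if_slope, 0)
  expect_gte(f$if_r2, 0.9)
  curve <- f$if_curve[[1]]
  expect_true(all(diff(curve$frequency) >= 0))
})

test_that("Class 2 subtypes fire at near-constant frequency", {
  for (cl in c("CLASS2_1", "CLASS2_2")) {
    f <- archetype_features(cl)
    expect_lt(f$if_cv, 0.2)
    expect_gt(f$max_spikes_per_step, 5)
  }
})

test_that("a Class 3 neuron fires at most one spike per step", {
  f <- archetype_features("CLASS3")
  expect_lte(f$max_spikes_per_step, 1)
  # and stays at a handful of spikes even at 2 nA
  tr <- simulate_current_clamp(drg_archetype("CLASS3"), step_protocol(2000))
  expect_lte(nrow(detect_spikes(tr)), 5)
  tr800 <- simulate_current_clamp(drg_archetype("CLASS3"), step_protocol(800))
  expect_identical(nrow(detect_spikes(tr800)), 1L)
})

test_that("the I-F curve is invariant to the order of the input traces", {
  traces <- simulate_current_clamp(drg_archetype("CLASS1"),
                                   step_protocol(c(100, 300, 500)))
  c1 <- build_if_curve(traces)
  c2 <- build_if_curve(rev(traces))
  expect_equal(as.data.frame(c1), as.data.frame(c2))
})

test_that("subthreshold families give all-zero frequencies", {
  traces <- simulate_current_clamp(drg_archetype("CLASS3"),
                                   step_protocol(c(100, 200, 300)))
  curve <- build_if_curve(traces)
  expect_true(all(curve$frequency == 0))
  expect_identical(if_stats(curve)$n_supra, 0L)
})

test_that("mismatched step timing is rejected", {
  a <- simulate_current_clamp(drg_archetype("CLASS1"), step_protocol(300))
  b <- simulate_current_clamp(drg_archetype("CLASS1"),
                              step_protocol(500, onset = 200))
  expect_error(build_if_curve(list(a, b)), class = "drgexcite_protocol_error")
})

test_that("bisection finds any monotone spike threshold to within resolution", {
  set.seed(33)
  for (theta in runif(12, 5, 1995)) {
    provider <- function(a) a >= theta
    res <- find_rheobase(provider, search_range = c(0, 2000), resolution = 10)
    expect_false(res$inexcitable)
    expect_gte(res$rheobase, theta - 1e-9)
    expect_lte(res$rheobase - theta, 10)
  }
})

test_that("rheobase search reports floor and inexcitable boundary cases", {
  always <- find_rheobase(function(a) TRUE, search_range = c(50, 2000))
  expect_true(always$floor_reached)
  expect_identical(always$rheobase, 50)
  never <- find_rheobase(function(a) FALSE)
  expect_true(never$inexcitable)
  expect_true(is.na(never$rheobase))
})

test_that("archetype rheobases fall in their class bands", {
  expect_lte(archetype_rheobase("CLASS1"), 200)
  expect_gte(archetype_rheobase("CLASS1"), 50)
  expect_gte(archetype_rheobase("CLASS2_1"), 200)
  expect_lte(archetype_rheobase("CLASS2_1"), 500)
  expect_gte(archetype_rheobase("CLASS2_2"), 200)
  expect_gt(archetype_rheobase("CLASS3"), 500)
})
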