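fake_features <- function(max_spikes = 0, n_supra = 0, if_cv = NA_real_,
                          if_slope = NA_real_, if_r2 = NA_real_,
                          ramp_spike_count = NA_integer_, osc_present = NA) {
  tibble::tibble(max_spikes_per_step = max_spikes, n_supra = n_supra,
                 if_cv = if_cv, if_slope = if_slope, if_r2 = if_r2,
                 ramp_spike_count = ramp_spike_count,
                 osc_present = osc_present)
}

test_that("each archetype's features map back to its class", {
  for (cl in c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3")) {
    lab <- classify(archetype_features(cl))
    expect_identical(as.character(lab$class), cl)
  }
})

test_that("silent neurons are unclassified, capped firing is Class 3", {
  expect_identical(as.character(classify(fake_features())$class),
                   "UNCLASSIFIED")
  lab <- classify(fake_features(max_spikes = 4))
  expect_identical(as.character(lab$class), "CLASS3")
  # the cap is configurable (strict "three spike" reading)
  lab3 <- classify(fake_features(max_spikes = 4),
                   classifier_config(spike_cap = 3))
  expect_false(as.character(lab3$class) == "CLASS3")
})

test_that("flat I-F without ramp evidence raises an incomplete-features error", {
  f <- fake_features(max_spikes = 20, n_supra = 5, if_cv = 0.1)
  expect_error(classify(f), class = "drgexcite_incomplete_features")
  # with ramp evidence the subdivision resolves
  f$ramp_spike_count <- 0L; f$osc_present <- FALSE
  expect_identical(as.character(classify(f)$class), "CLASS2_2")
  f$ramp_spike_count <- 12L
  expect_identical(as.character(classify(f)$class), "CLASS2_1")
})

test_that("non-flat non-linear relations stay unclassified", {
  f <- fake_features(max_spikes = 20, n_supra = 6, if_cv = 0.5,
                     if_slope = -0.01, if_r2 = 0.3,
                     ramp_spike_count = 0L, osc_present = FALSE)
  expect_identical(as.character(classify(f)$class), "UNCLASSIFIED")
})

test_that("evidence records every rule evaluated on the path taken", {
  lab <- classify(archetype_features("CLASS2_1"))
  ev <- lab$evidence[[1]]
  expect_true(all(c("any_spike", "spike_cap", "flat_if", "ramp_active",
                    "oscillations") %in% names(ev)))
  expect_true(ev$flat_if)
})

test_that("cohort classification keeps one label per neuron and full counts", {
  expect_error(classify_cohort(tibble::tibble()), "at least one")
  one <- classify_cohort(archetype_features("CLASS1"))
  cc <- class_counts(one)
  expect_identical(sum(cc$n), 1L)
  expect_identical(cc$n[cc$class == "CLASS1"], 1L)
  many <- dplyr::bind_rows(lapply(c("CLASS1", "CLASS2_2", "CLASS3"),
                                  archetype_features))
  got <- classify_cohort(many)
  expect_identical(nrow(got), 3L)
  expect_identical(sum(class_counts(got)$n), 3L)
  expect_setequal(class_counts(got)$class,
                  c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3", "UNCLASSIFIED"))
})

test_that("class assignment is unchanged when recordings are sampled at 20 kHz", {
  for (cl in c("CLASS1", "CLASS2_2")) {
    f20 <- simulate_features(drg_archetype(cl), out_dt = 0.05)
    expect_identical(as.character(classify(f20)$class), cl)
  }
})
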