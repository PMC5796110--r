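brute_chi2 <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

test_that("pearson_chi2 equals the direct (O-E)^2/E sum on random tables", {
  set.seed(88)
  for (i in 1:20) {
    m <- matrix(rpois(4, 40) + 1, 2, 2)
    expect_equal(pearson_chi2(m)$statistic, brute_chi2(m), tolerance = 1e-10)
  }
})

test_that("pearson_chi2 is invariant to row and column swaps", {
  m <- matrix(c(23, 156, 36, 98), 2, 2, byrow = TRUE)
  s <- pearson_chi2(m)$statistic
  expect_equal(pearson_chi2(m[2:1, ])$statistic, s)
  expect_equal(pearson_chi2(m[, 2:1])$statistic, s)
  expect_identical(pearson_chi2(m)$df, 1L)
})

test_that("equal-proportion and degenerate tables behave as expected", {
  expect_equal(pearson_chi2(matrix(c(10, 90, 20, 180), 2, 2,
                                   byrow = TRUE))$statistic, 0)
  expect_error(pearson_chi2(matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)),
               class = "drgexcite_degenerate_table")
  expect_error(pearson_chi2(matrix(1:6, 2, 3)), "2x2")
  expect_error(pearson_chi2(matrix(c(-1, 2, 3, 4), 2, 2)), "non-negative")
})

test_that("ANOVA F equals the explicit sums-of-squares ratio", {
  # fixed fixture: 3 groups x 4 values
  fx <- list(a = c(4.1, 5.2, 4.8, 5.0), b = c(6.3, 6.0, 5.8, 6.6),
             c = c(4.9, 5.1, 5.3, 4.7))
  an <- one_way_anova_lsd(fx)
  allv <- unlist(fx)
  ssb <- sum(vapply(fx, function(g) length(g) * (mean(g) - mean(allv))^2,
                    numeric(1)))
  ssw <- sum(vapply(fx, function(g) sum((g - mean(g))^2), numeric(1)))
  f_brute <- (ssb / 2) / (ssw / 9)
  expect_equal(an$F, f_brute, tolerance = 1e-10)
  expect_identical(unname(an$df), c(2L, 9L))

  set.seed(12)
  for (i in 1:10) {
    gs <- lapply(sample(2:6, 3, replace = TRUE), function(n) rnorm(n))
    an <- one_way_anova_lsd(gs)
    allv <- unlist(gs)
    ssb <- sum(vapply(gs, function(g) length(g) * (mean(g) - mean(allv))^2,
                      numeric(1)))
    ssw <- sum(vapply(gs, function(g) sum((g - mean(g))^2), numeric(1)))
    expect_equal(an$F, (ssb / (length(gs) - 1)) /
                   (ssw / (length(allv) - length(gs))), tolerance = 1e-10)
  }
})

test_that("degrees of freedom follow the classical group-size conventions", {
  set.seed(3)
  mk <- function(sizes) {
    tibble::tibble(g = rep(letters[seq_along(sizes)], times = sizes),
                   y = rnorm(sum(sizes)))
  }
  expect_identical(unname(one_way_anova_lsd(mk(c(10, 8, 9, 12)), y, g)$df),
                   c(3L, 35L))
  expect_identical(unname(one_way_anova_lsd(mk(c(7, 11, 9, 8)), y, g)$df),
                   c(3L, 31L))
})

test_that("identical groups give F = 0 with all LSD p-values 1", {
  an <- one_way_anova_lsd(list(a = rep(2, 4), b = rep(2, 4), c = rep(2, 4)))
  expect_identical(an$F, 0)
  expect_identical(an$p, 1)
  expect_true(all(tidy(an)$p_lsd == 1))
})

test_that("two-group LSD reduces to the pooled-variance t-test", {
  set.seed(9)
  a <- rnorm(8); b <- rnorm(6, 1)
  an <- one_way_anova_lsd(list(a = a, b = b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(tidy(an)$p_lsd, tt$p.value, tolerance = 1e-12)
  expect_equal(glance(an)$p_value, tt$p.value, tolerance = 1e-12)
})

test_that("undersized groups are rejected", {
  expect_error(one_way_anova_lsd(list(a = 1:3, b = 2)),
               class = "drgexcite_insufficient_replication")
  expect_error(one_way_anova_lsd(list(a = 1:3)),
               class = "drgexcite_insufficient_replication")
})

test_that("cohort generation is reproducible and respects proportions", {
  c1 <- generate_cohort(30, seed = 4)
  c2 <- generate_cohort(30, seed = 4)
  expect_identical(c1$true_class, c2$true_class)
  expect_identical(c1$params, c2$params)
  only1 <- generate_cohort(20, proportions = c(CLASS1 = 1, CLASS2_1 = 0,
                                               CLASS2_2 = 0, CLASS3 = 0),
                           seed = 2)
  expect_true(all(only1$true_class == "CLASS1"))
  expect_error(generate_cohort(10, proportions = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  # law of large numbers at n = 10,000: class shares within 3 SE
  big <- generate_cohort(10000, seed = 6)
  p <- control_proportions()
  for (cl in names(p)) {
    se <- sqrt(p[[cl]] * (1 - p[[cl]]) / 10000)
    expect_lt(abs(mean(big$true_class == cl) - p[[cl]]), 3 * se)
  }
  # recorded-cohort size over a seed sweep: mean Class 3 share near 60.3%
  shares <- vapply(1:20, function(s) {
    mean(generate_cohort(179, jitter = 0, seed = s)$true_class == "CLASS3")
  }, numeric(1))
  p3 <- control_proportions()[["CLASS3"]]
  se <- sqrt(p3 * (1 - p3) / (179 * 20))
  expect_lt(abs(mean(shares) - p3), 3 * se)
})

test_that("proportion shifts reproduce the printed cohort percentages", {
  counts <- drg_cohort_counts()
  rep <- proportion_shift_report(
    stats::setNames(counts$control, counts$class),
    stats::setNames(counts$ccd, counts$class))
  expect_equal(rep$control_pct, c(12.8, 26.8, 60.3))
  expect_equal(rep$ccd_pct, c(26.9, 32.8, 40.3))
  expect_equal(rep$statistic, c(9.842, 1.338, 12.321), tolerance = 1e-3)
  # identical cohorts shift nothing
  same <- proportion_shift_report(c(a = 10, b = 20), c(a = 10, b = 20))
  expect_true(all(same$statistic == 0))
  expect_error(proportion_shift_report(c(a = 0), c(a = 0)), "positive")
})
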