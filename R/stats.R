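#' Pearson chi-square test on a 2x2 contingency table
#'
#' Uncorrected Pearson chi-square (no Yates continuity correction),
#' `sum((O - E)^2 / E)` with expected counts from the row/column
#' margins, on 1 degree of freedom. This is the test used for
#' class-proportion shifts between cohorts (in-class vs not-in-class by
#' cohort).
#'
#' @param table A 2x2 matrix of non-negative counts, or a data frame
#'   with two numeric columns of two rows.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
pearson_chi2 <- function(table) {
  m <- as.matrix(table)
  storage.mode(m) <- "double"
  if (!all(dim(m) == c(2L, 2L)))
    rlang::abort("`table` must be 2x2.")
  if (any(m < 0) || any(!is.finite(m)))
    rlang::abort("counts must be finite and non-negative.")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    rlang::abort("degenerate table: a row or column margin is zero.",
                 class = "drgexcite_degenerate_table")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  tibble::tibble(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value))
}

#' One-way ANOVA with uncorrected Fisher's LSD comparisons
#'
#' Classical between/within sums-of-squares decomposition, followed by
#' pairwise least-significant-difference t-tests using the pooled
#' within-group variance, without multiple-testing correction
#' (uncorrected Fisher's LSD). With `k` groups and `N` observations the
#' degrees of freedom are `(k - 1, N - k)`.
#'
#' @param data A data frame in long format.
#' @param value,group Columns (tidy-eval) holding the response and the
#'   grouping factor. Alternatively `data` may be a named list of
#'   numeric vectors, in which case `value`/`group` are ignored.
#' @return An `anova_lsd` object; [tidy()] returns the pairwise LSD
#'   table, [glance()] the F statistic, degrees of freedom and p-value.
#' @export
one_way_anova_lsd <- function(data, value, group) {
  if (is.list(data) && !is.data.frame(data)) {
    if (is.null(names(data))) names(data) <- paste0("group", seq_along(data))
    data <- purrr::imap(data, function(x, nm) {
      tibble::tibble(value = as.numeric(x), group = nm)
    }) |> dplyr::bind_rows()
    value <- rlang::sym("value"); group <- rlang::sym("group")
    df <- data
  } else {
    df <- dplyr::transmute(data,
                           value = {{ value }},
                           group = as.character({{ group }}))
  }
  df <- df[stats::complete.cases(df), ]
  sizes <- table(df$group)
  if (length(sizes) < 2L)
    rlang::abort("need at least two groups.",
                 class = "drgexcite_insufficient_replication")
  if (any(sizes < 2L))
    rlang::abort(
      sprintf("group %s has fewer than 2 observations.",
              paste(names(sizes)[sizes < 2L], collapse = ", ")),
      class = "drgexcite_insufficient_replication")

  fit <- stats::lm(value ~ group, data = df)
  # a perfect fit warns here; the degenerate branch below handles it
  an <- suppressWarnings(stats::anova(fit))
  df_b <- an$Df[1L]; df_w <- an$Df[2L]
  mse <- an$`Mean Sq`[2L]
  fstat <- an$`F value`[1L]
  p <- an$`Pr(>F)`[1L]
  # degenerate data (all observations equal): both sums of squares are
  # numerical noise, so report no effect rather than a noise ratio
  ss_tol <- 1e-12 * (1 + sum(df$value^2))
  if (an$`Sum Sq`[1L] + an$`Sum Sq`[2L] < ss_tol) {
    fstat <- 0; p <- 1; mse <- 0
  }

  means <- tapply(df$value, df$group, mean)
  ns <- tapply(df$value, df$group, length)
  gnames <- names(means)
  pairs <- utils::combn(gnames, 2L, simplify = FALSE)
  pairwise <- purrr::map(pairs, function(pr) {
    i <- pr[1L]; j <- pr[2L]
    diff_ij <- means[[i]] - means[[j]]
    se <- sqrt(mse * (1 / ns[[i]] + 1 / ns[[j]]))
    tval <- if (se > 0) diff_ij / se else 0
    tibble::tibble(group1 = i, group2 = j, mean_difference = diff_ij,
                   p_lsd = 2 * stats::pt(-abs(tval), df_w))
  }) |> dplyr::bind_rows()

  structure(list(F = fstat, df = c(between = df_b, within = df_w), p = p,
                 pairwise = pairwise,
                 means = tibble::tibble(group = gnames,
                                        n = as.integer(ns[gnames]),
                                        mean = as.numeric(means[gnames]))),
            class = "anova_lsd")
}

#' @export
print.anova_lsd <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d,%d) = %.4g, p = %.4g\n",
              x$df[["between"]], x$df[["within"]], x$F, x$p))
  cat("Uncorrected Fisher's LSD comparisons:\n")
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.anova_lsd <- function(x, ...) x$pairwise

#' @export
glance.anova_lsd <- function(x, ...) {
  tibble::tibble(statistic = x$F, df_between = x$df[["between"]],
                 df_within = x$df[["within"]], p_value = x$p)
}

#' Per-class proportion-shift report between two cohorts
#'
#' For every class, forms the in-class / not-in-class 2x2 table against
#' the two cohorts and runs the uncorrected Pearson chi-square test;
#' percentages are reported to one decimal.
#'
#' @param control_counts,ccd_counts Named integer vectors of per-class
#'   neuron counts for the two cohorts (same names, e.g. `class1`,
#'   `class2`, `class3`).
#' @param cohort_names Length-2 labels for the cohorts.
#' @return A tibble with one row per class: counts, percentages (1
#'   decimal), `statistic`, `df`, `p_value`.
#' @export
proportion_shift_report <- function(control_counts, ccd_counts,
                                    cohort_names = c("control", "CCD")) {
  stopifnot(length(control_counts) == length(ccd_counts))
  if (!is.null(names(ccd_counts)) && !is.null(names(control_counts)))
    stopifnot(identical(names(control_counts), names(ccd_counts)))
  n1 <- sum(control_counts); n2 <- sum(ccd_counts)
  if (n1 == 0 || n2 == 0) rlang::abort("cohort size must be positive.")
  cls <- names(control_counts) %||% paste0("class", seq_along(control_counts))
  purrr::map(seq_along(cls), function(i) {
    tab <- matrix(c(control_counts[[i]], n1 - control_counts[[i]],
                    ccd_counts[[i]], n2 - ccd_counts[[i]]),
                  nrow = 2L, byrow = TRUE,
                  dimnames = list(cohort_names, c("in_class", "not_in_class")))
    chi <- pearson_chi2(tab)
    tibble::tibble(class = cls[[i]],
                   control_n = control_counts[[i]],
                   control_pct = round(100 * control_counts[[i]] / n1, 1),
                   ccd_n = ccd_counts[[i]],
                   ccd_pct = round(100 * ccd_counts[[i]] / n2, 1),
                   statistic = chi$statistic, df = chi$df,
                   p_value = chi$p_value)
  }) |> dplyr::bind_rows()
}

#' Published cohort class counts
#'
#' The per-class neuron counts of the two recorded cohorts (control:
#' 179 neurons; CCD, chronic compression of the DRG: 134 neurons) used
#' for the proportion-shift tests. Shipped as a small in-code fixture.
#'
#' @return A tibble with columns `class`, `control`, `ccd`.
#' @export
drg_cohort_counts <- function() {
  tibble::tibble(class = c("class1", "class2", "class3"),
                 control = c(23L, 48L, 108L),
                 ccd = c(36L, 44L, 54L))
}
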