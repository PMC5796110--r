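#' Classifier thresholds
#'
#' Configurable numeric thresholds of the class decision rules. The
#' defaults encode: Class 3 neurons fire no more than `spike_cap` spikes
#' at any step up to 2 nA (the description "no more than three to five
#' spikes" read as <= 5, configurable down to 3); Class 2 neurons have a
#' flat suprathreshold I-F relation (coefficient of variation below
#' `cv_max`); Class 1 neurons have a positive, approximately linear I-F
#' relation (R-squared at least `r2_min`).
#'
#' @param spike_cap Maximum spikes per step for Class 3.
#' @param cv_max Maximum suprathreshold frequency CV for "constant
#'   frequency" (Class 2).
#' @param r2_min Minimum I-F linearity R-squared for Class 1.
#' @return A named list of thresholds.
#' @export
classifier_config <- function(spike_cap = 5, cv_max = 0.2, r2_min = 0.8) {
  stopifnot(spike_cap >= 1, cv_max > 0, r2_min > 0, r2_min <= 1)
  list(spike_cap = spike_cap, cv_max = cv_max, r2_min = r2_min)
}

#' Assign a Hodgkin-style excitability class from features
#'
#' Decision rules, in order of precedence:
#' 1. no spike at any step: `UNCLASSIFIED` (no evidence);
#' 2. `CLASS3` if the maximum spike count over all tested steps is at
#'    most `spike_cap`;
#' 3. `CLASS2` if the suprathreshold I-F relation is flat
#'    (CV < `cv_max`), subdivided by the ramp response: `CLASS2_1` when
#'    the ramp evokes spikes or subthreshold oscillations are present,
#'    `CLASS2_2` when the ramp is silent. Missing ramp features make the
#'    subdivision impossible and raise an incomplete-features error;
#' 4. `CLASS1` if the I-F slope is positive with linearity R-squared at
#'    least `r2_min`;
#' 5. otherwise `UNCLASSIFIED`.
#'
#' The spike-count rule precedes the I-F shape rules because a cell that
#' barely fires has no meaningful I-F relation to test.
#'
#' @param features An `excitability_features` row (see
#'   [neuron_features()]).
#' @param config Thresholds from [classifier_config()].
#' @return A `class_label` one-row tibble: `class` (factor over CLASS1,
#'   CLASS2_1, CLASS2_2, CLASS3, UNCLASSIFIED) and an `evidence`
#'   list-column mapping each evaluated rule to its boolean outcome.
#' @export
classify <- function(features, config = classifier_config()) {
  f <- features
  ev <- list()
  decide <- function(value) {
    tibble::tibble(class = factor(value, levels = label_levels()),
                   evidence = list(ev))
  }

  ev$any_spike <- f$max_spikes_per_step > 0
  if (!ev$any_spike) return(decide("UNCLASSIFIED"))

  ev$spike_cap <- f$max_spikes_per_step <= config$spike_cap
  if (ev$spike_cap) return(decide("CLASS3"))

  ev$flat_if <- isTRUE(f$n_supra >= 2 && is.finite(f$if_cv) &&
                         f$if_cv < config$cv_max)
  if (ev$flat_if) {
    if (is.na(f$ramp_spike_count) && is.na(f$osc_present))
      rlang::abort(
        "flat I-F relation but no ramp features: Class 2 subdivision impossible.",
        class = "drgexcite_incomplete_features")
    ev$ramp_active <- isTRUE(f$ramp_spike_count > 0)
    ev$oscillations <- isTRUE(f$osc_present)
    return(decide(if (ev$ramp_active || ev$oscillations) "CLASS2_1" else "CLASS2_2"))
  }

  ev$linear_if <- isTRUE(f$n_supra >= 2 && is.finite(f$if_slope) &&
                           f$if_slope > 0 && f$if_r2 >= config$r2_min)
  if (ev$linear_if) return(decide("CLASS1"))
  decide("UNCLASSIFIED")
}

#' Classify a cohort of neurons
#'
#' Applies [classify()] to each row of a features table and appends the
#' assigned class. Counts over all five labels are available with
#' [class_counts()].
#'
#' @param features_tbl A tibble of `excitability_features` rows (one per
#'   neuron), e.g. from [generate_cohort()] plus [simulate_features()].
#' @param config Thresholds from [classifier_config()].
#' @return The input tibble with `class` and `evidence` columns added.
#' @export
classify_cohort <- function(features_tbl, config = classifier_config()) {
  if (is.null(features_tbl) || nrow(features_tbl) == 0L)
    rlang::abort("`features_tbl` must contain at least one neuron.")
  labs <- purrr::map(seq_len(nrow(features_tbl)),
                     function(i) classify(features_tbl[i, ], config))
  dplyr::bind_cols(features_tbl, dplyr::bind_rows(labs))
}

#' @rdname classify_cohort
#' @param labels A factor/character vector of assigned classes, or a
#'   tibble with a `class` column.
#' @return `class_counts()`: a tibble `class`, `n` covering all five
#'   labels (zeros included); counts sum to the number of neurons.
#' @export
class_counts <- function(labels) {
  if (is.data.frame(labels)) labels <- labels$class
  f <- factor(labels, levels = label_levels())
  tibble::tibble(class = label_levels(), n = as.integer(table(f)))
}
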