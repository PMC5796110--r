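#' Generate a synthetic cohort of model neurons
#'
#' Draws each neuron's subclass from the multinomial with the given
#' proportions, takes the corresponding calibrated archetype, and
#' jitters its magnitude parameters (capacitance and the five maximal
#' conductances) multiplicatively with a unit-mean lognormal factor of
#' the given relative SD. Kinetic constants and reversal potentials stay
#' at the archetype values, so jitter varies cell size and channel
#' expression but not channel identity. Fully reproducible from the
#' seed.
#'
#' @param n_neurons Cohort size.
#' @param proportions Named (CLASS1, CLASS2_1, CLASS2_2, CLASS3) or
#'   positional length-4 vector of subclass probabilities summing to 1.
#'   The default is the control-cohort composition: 23/179 Class 1,
#'   48/179 Class 2 (split 70.8% / 29.2% into 2-1 / 2-2), 108/179
#'   Class 3.
#' @param jitter Relative SD of the multiplicative parameter jitter.
#' @param seed Integer seed.
#' @return A tibble: `neuron_id`, `true_class`, `params` (list-column of
#'   [neuron_params()]).
#' @export
generate_cohort <- function(n_neurons,
                            proportions = control_proportions(),
                            jitter = 0.1, seed = 1L) {
  stopifnot(n_neurons > 0, length(proportions) == 4L, jitter >= 0)
  if (abs(sum(proportions) - 1) > 1e-9)
    rlang::abort("`proportions` must sum to 1.")
  if (is.null(names(proportions))) names(proportions) <- class_levels()
  stopifnot(setequal(names(proportions), class_levels()))
  proportions <- proportions[class_levels()]

  withr::with_seed(as.integer(seed), {
    cls <- sample(class_levels(), n_neurons, replace = TRUE,
                  prob = proportions)
    params <- lapply(cls, function(cl) jitter_params(drg_archetype(cl), jitter))
  })
  tibble::tibble(neuron_id = seq_len(n_neurons),
                 true_class = factor(cls, levels = class_levels()),
                 params = params)
}

#' @rdname generate_cohort
#' @export
control_proportions <- function() {
  p2 <- 48 / 179
  c(CLASS1 = 23 / 179, CLASS2_1 = p2 * 0.708, CLASS2_2 = p2 * 0.292,
    CLASS3 = 108 / 179)
}

#' @rdname generate_cohort
#' @export
ccd_proportions <- function() {
  p2 <- 44 / 134
  c(CLASS1 = 36 / 134, CLASS2_1 = p2 * 0.708, CLASS2_2 = p2 * 0.292,
    CLASS3 = 54 / 134)
}

# Multiplicative lognormal jitter with unit mean and relative SD `rel`,
# applied to the magnitude parameters only. Uses the current RNG stream.
jitter_params <- function(params, rel) {
  if (rel <= 0) return(params)
  sdlog <- sqrt(log(1 + rel^2))
  draw <- function() exp(stats::rnorm(1L, -sdlog^2 / 2, sdlog))
  params$membrane_capacitance <- params$membrane_capacitance * draw()
  params$leak_conductance <- params$leak_conductance * draw()
  params$fast_sodium$max_conductance <-
    params$fast_sodium$max_conductance * draw()
  params$delayed_rectifier_potassium$max_conductance <-
    params$delayed_rectifier_potassium$max_conductance * draw()
  params$hcn$max_conductance <- params$hcn$max_conductance * draw()
  params$persistent_sodium$max_conductance <-
    params$persistent_sodium$max_conductance * draw()
  validate_neuron_params(params)
}

#' Balanced archetype cohort
#'
#' A cohort with exactly `n_per_class` jittered neurons per subclass, in
#' a fixed class order, for recovery and ordering studies where equal
#' group sizes are wanted (cohort composition itself is not under
#' study).
#'
#' @param n_per_class Neurons per subclass.
#' @inheritParams generate_cohort
#' @return A tibble like [generate_cohort()]'s.
#' @export
balanced_cohort <- function(n_per_class, jitter = 0.1, seed = 1L) {
  stopifnot(n_per_class > 0, jitter >= 0)
  cls <- rep(class_levels(), each = n_per_class)
  withr::with_seed(as.integer(seed), {
    params <- lapply(cls, function(cl) jitter_params(drg_archetype(cl), jitter))
  })
  tibble::tibble(neuron_id = seq_along(cls),
                 true_class = factor(cls, levels = class_levels()),
                 params = params)
}
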