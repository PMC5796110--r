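#' Construct a conductance-model parameter set
#'
#' A single-compartment neuron with Hodgkin-Huxley-style fast sodium
#' (`m^3 h`) and delayed-rectifier potassium (`n^4`) currents, a
#' first-order Boltzmann-gated HCN current carrying Ih, and an optional
#' instantaneous persistent sodium current. All gates use
#' `x_inf(V) = 1/(1 + exp(-(V - half)/slope))` steady states (the sign of
#' `slope` sets the direction of voltage dependence) with bell-shaped
#' voltage-dependent time constants
#' `tau(V) = tau_min + tau_amp * exp(-((V - tau_v0)/tau_sig)^2)`.
#'
#' Units are fixed internally: mV, ms, pA, nS and pF, so that
#' `dV/dt` in mV/ms equals current in pA over capacitance in pF.
#'
#' @param membrane_capacitance Membrane capacitance, pF.
#' @param leak_conductance Leak conductance, nS.
#' @param leak_reversal Leak reversal potential, mV.
#' @param fast_sodium Named list: `max_conductance` (nS), `reversal` (mV),
#'   activation `m_half`/`m_slope` (mV) and `m_tau` (ms), inactivation
#'   `h_half`/`h_slope` (mV) and `h_tau_min`/`h_tau_amp` (ms),
#'   `h_tau_v0`/`h_tau_sig` (mV).
#' @param delayed_rectifier_potassium Named list: `max_conductance` (nS),
#'   `reversal` (mV), `n_half`/`n_slope` (mV), `n_tau_min`/`n_tau_amp`
#'   (ms), `n_tau_v0`/`n_tau_sig` (mV).
#' @param hcn Named list: `max_conductance` (nS, the HCN conductance
#'   `g_h`), `half_activation` (mV, about -80), `slope` (mV, negative:
#'   the channel opens with hyperpolarization), `tau_min`/`tau_amp` (ms,
#'   activation time constants of order 100-500 ms), `tau_v0`/`tau_sig`
#'   (mV), `reversal` (mV, about -30).
#' @param persistent_sodium Named list: `max_conductance` (nS),
#'   `half_activation` (mV), `slope` (mV). Activation is treated as
#'   instantaneous; used to produce subthreshold oscillations and
#'   ramp-evoked bursting.
#' @param archetype_label Optional label recording which shipped archetype
#'   (if any) the parameters derive from: one of `"CLASS1"`, `"CLASS2_1"`,
#'   `"CLASS2_2"`, `"CLASS3"`, or `NA`.
#'
#' @return An object of class `neuron_params` (a validated named list).
#' @seealso [drg_archetype()] for the four calibrated class exemplars,
#'   [block_ih()] for the pharmacological-block counterpart.
#' @export
neuron_params <- function(membrane_capacitance = 100,
                          leak_conductance = 10,
                          leak_reversal = -60,
                          fast_sodium = list(),
                          delayed_rectifier_potassium = list(),
                          hcn = list(),
                          persistent_sodium = list(),
                          archetype_label = NA_character_) {
  na_def <- list(max_conductance = 0, reversal = 60,
                 m_half = -32, m_slope = 5.5, m_tau = 0.1,
                 h_half = -50, h_slope = -6,
                 h_tau_min = 0.5, h_tau_amp = 7, h_tau_v0 = -55, h_tau_sig = 15)
  k_def <- list(max_conductance = 0, reversal = -90,
                n_half = -30, n_slope = 8,
                n_tau_min = 0.8, n_tau_amp = 4, n_tau_v0 = -45, n_tau_sig = 25)
  hcn_def <- list(max_conductance = 0, half_activation = -80, slope = -8,
                  tau_min = 120, tau_amp = 250, tau_v0 = -85, tau_sig = 20,
                  reversal = -30)
  nap_def <- list(max_conductance = 0, half_activation = -45, slope = 4)

  p <- structure(list(
    membrane_capacitance = membrane_capacitance,
    leak_conductance = leak_conductance,
    leak_reversal = leak_reversal,
    fast_sodium = utils::modifyList(na_def, fast_sodium),
    delayed_rectifier_potassium = utils::modifyList(k_def, delayed_rectifier_potassium),
    hcn = utils::modifyList(hcn_def, hcn),
    persistent_sodium = utils::modifyList(nap_def, persistent_sodium),
    archetype_label = archetype_label
  ), class = "neuron_params")
  validate_neuron_params(p)
}

validate_neuron_params <- function(p) {
  stopifnot(inherits(p, "neuron_params"))
  if (!is.finite(p$membrane_capacitance) || p$membrane_capacitance <= 0)
    rlang::abort("`membrane_capacitance` must be > 0 pF.")
  gs <- c(leak = p$leak_conductance,
          na = p$fast_sodium$max_conductance,
          k = p$delayed_rectifier_potassium$max_conductance,
          hcn = p$hcn$max_conductance,
          nap = p$persistent_sodium$max_conductance)
  if (any(!is.finite(gs)) || any(gs < 0))
    rlang::abort("all maximal conductances must be finite and >= 0 nS.")
  slopes <- c(p$fast_sodium$m_slope, p$fast_sodium$h_slope,
              p$delayed_rectifier_potassium$n_slope, p$hcn$slope,
              p$persistent_sodium$slope)
  if (any(slopes == 0)) rlang::abort("gating slope parameters must be non-zero.")
  if (!is.na(p$archetype_label) &&
      !p$archetype_label %in% class_levels())
    rlang::abort("unknown `archetype_label`.")
  p
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>",
      if (!is.na(x$archetype_label)) paste0("archetype ", x$archetype_label),
      "\n")
  cat(sprintf("  Cm %.4g pF, g_leak %.4g nS (E_L %.4g mV)\n",
              x$membrane_capacitance, x$leak_conductance, x$leak_reversal))
  cat(sprintf("  g_Na %.4g nS, g_K %.4g nS, g_h %.4g nS, g_NaP %.4g nS\n",
              x$fast_sodium$max_conductance,
              x$delayed_rectifier_potassium$max_conductance,
              x$hcn$max_conductance, x$persistent_sodium$max_conductance))
  invisible(x)
}

class_levels <- function() c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3")

label_levels <- function() c(class_levels(), "UNCLASSIFIED")

#' Calibrated archetype parameter sets for the four excitability subclasses
#'
#' Returns the shipped exemplar model for one of the four subclasses of
#' large DRG neurons. The archetypes are calibrated so that, under the
#' standard step and ramp protocols, they reproduce the qualitative
#' signatures of their classes: Class 1 fires repetitively from a low
#' rheobase (50-200 pA) with an approximately linear intensity-frequency
#' relation; Class 2 subtypes have a higher rheobase (200-500 pA) and fire
#' at a near-constant frequency regardless of step intensity, with
#' Class 2-1 responding to a 1000 pA current ramp with oscillatory
#' bursting and Class 2-2 remaining silent under the same ramp; Class 3
#' has the highest rheobase (> 500 pA) and fires at most a few spikes
#' even at 2 nA. HCN conductance is ordered
#' CLASS2_1 > CLASS1 >= CLASS2_2 > CLASS3, mirroring the measured Ih
#' magnitude ordering across subclasses.
#'
#' @param class One of `"CLASS1"`, `"CLASS2_1"`, `"CLASS2_2"`, `"CLASS3"`
#'   (case-insensitive; `"class2-1"`-style names are accepted).
#' @return A [neuron_params()] object.
#' @export
drg_archetype <- function(class = c("CLASS1", "CLASS2_1", "CLASS2_2", "CLASS3")) {
  cl <- toupper(gsub("-", "_", class[[1L]]))
  cl <- match.arg(cl, class_levels())
  switch(cl,
    CLASS1 = neuron_params(
      membrane_capacitance = 100,
      leak_conductance = 7,
      leak_reversal = -62,
      fast_sodium = list(max_conductance = 1200,
                         m_half = -33, m_slope = 6, m_tau = 0.08,
                         h_half = -47, h_slope = -7,
                         h_tau_min = 0.6, h_tau_amp = 6,
                         h_tau_v0 = -52, h_tau_sig = 18),
      delayed_rectifier_potassium = list(max_conductance = 350,
                                         n_half = -28, n_slope = 9,
                                         n_tau_min = 1.0, n_tau_amp = 4,
                                         n_tau_v0 = -45, n_tau_sig = 30),
      hcn = list(max_conductance = 8),
      archetype_label = "CLASS1"),
    CLASS2_1 = neuron_params(
      membrane_capacitance = 100,
      leak_conductance = 28,
      leak_reversal = -60,
      fast_sodium = list(max_conductance = 1100,
                         m_half = -24, m_slope = 5, m_tau = 0.08,
                         h_half = -46, h_slope = -6,
                         h_tau_min = 0.6, h_tau_amp = 7,
                         h_tau_v0 = -50, h_tau_sig = 16),
      delayed_rectifier_potassium = list(max_conductance = 800,
                                         n_half = -30, n_slope = 7,
                                         n_tau_min = 1, n_tau_amp = 16,
                                         n_tau_v0 = -65, n_tau_sig = 18),
      hcn = list(max_conductance = 22),
      persistent_sodium = list(max_conductance = 20,
                               half_activation = -34, slope = 3),
      archetype_label = "CLASS2_1"),
    CLASS2_2 = neuron_params(
      membrane_capacitance = 100,
      leak_conductance = 20,
      leak_reversal = -60,
      fast_sodium = list(max_conductance = 1100,
                         m_half = -28, m_slope = 5, m_tau = 0.08,
                         h_half = -44, h_slope = -6,
                         h_tau_min = 0.6, h_tau_amp = 7,
                         h_tau_v0 = -50, h_tau_sig = 16),
      delayed_rectifier_potassium = list(max_conductance = 800,
                                         n_half = -30, n_slope = 7,
                                         n_tau_min = 1, n_tau_amp = 16,
                                         n_tau_v0 = -65, n_tau_sig = 18),
      hcn = list(max_conductance = 6),
      archetype_label = "CLASS2_2"),
    CLASS3 = neuron_params(
      membrane_capacitance = 100,
      leak_conductance = 16,
      leak_reversal = -60,
      fast_sodium = list(max_conductance = 900,
                         m_half = -20, m_slope = 5, m_tau = 0.08,
                         h_half = -45, h_slope = -5,
                         h_tau_min = 1.0, h_tau_amp = 300,
                         h_tau_v0 = -45, h_tau_sig = 14),
      delayed_rectifier_potassium = list(max_conductance = 700,
                                         n_half = -30, n_slope = 7,
                                         n_tau_min = 0.9, n_tau_amp = 3,
                                         n_tau_v0 = -45, n_tau_sig = 28),
      hcn = list(max_conductance = 1.5),
      archetype_label = "CLASS3")
  )
}

#' Emulate pharmacological HCN block (ZD7288)
#'
#' Returns a copy of the parameter set with the HCN maximal conductance
#' set to zero, emulating a complete block of Ih as produced by a
#' saturating concentration of the selective blocker ZD7288 (15 uM in the
#' emulated protocol; the concentration is a metadata annotation only).
#' All other fields are unchanged, and the operation is idempotent.
#'
#' @param params A [neuron_params()] object.
#' @return A `neuron_params` object with `hcn$max_conductance = 0`.
#' @export
block_ih <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  params$hcn$max_conductance <- 0
  params
}

# Flatten a neuron_params object into the named vector the C++ core reads.
as_sim_pars <- function(p) {
  validate_neuron_params(p)
  na <- p$fast_sodium; k <- p$delayed_rectifier_potassium
  h <- p$hcn; np <- p$persistent_sodium
  c(cm = p$membrane_capacitance, gl = p$leak_conductance, el = p$leak_reversal,
    gna = na$max_conductance, ena = na$reversal,
    nam_half = na$m_half, nam_k = na$m_slope, nam_tau = na$m_tau,
    nah_half = na$h_half, nah_k = na$h_slope,
    nah_tau_min = na$h_tau_min, nah_tau_amp = na$h_tau_amp,
    nah_tau_v0 = na$h_tau_v0, nah_tau_sig = na$h_tau_sig,
    gk = k$max_conductance, ek = k$reversal,
    kn_half = k$n_half, kn_k = k$n_slope,
    kn_tau_min = k$n_tau_min, kn_tau_amp = k$n_tau_amp,
    kn_tau_v0 = k$n_tau_v0, kn_tau_sig = k$n_tau_sig,
    gh = h$max_conductance, eh = h$reversal,
    hcn_half = h$half_activation, hcn_k = h$slope,
    hcn_tau_min = h$tau_min, hcn_tau_amp = h$tau_amp,
    hcn_tau_v0 = h$tau_v0, hcn_tau_sig = h$tau_sig,
    gnap = np$max_conductance, nap_half = np$half_activation,
    nap_k = np$slope)
}
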