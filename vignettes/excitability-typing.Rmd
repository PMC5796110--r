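---
title: "Excitability typing of large DRG neurons: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Excitability typing of large DRG neurons: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drgexcite)
```

## The problem

Large (> 50 µm) dorsal root ganglion (DRG) neurons are not a homogeneous
population: under current clamp they separate into Hodgkin-style
excitability classes. Class 1 cells fire repetitively from a low rheobase
(50–200 pA) with a firing rate that grows approximately linearly with the
injected current; Class 2 cells need more current (200–500 pA) and fire at
a near-constant rate whatever the step intensity, splitting further by
their response to a 1000 pA current ramp — Class 2-1 cells burst
rhythmically with subthreshold membrane-potential oscillations, Class 2-2
cells stay silent; Class 3 cells have the highest rheobase (> 500 pA) and
fire only one or a few spikes however hard they are driven. The
hyperpolarization-activated cation current Ih tracks this partition: it is
much larger in Class 2-1 cells than in any other subclass and smallest in
Class 3. After chronic compression of the ganglion (CCD), a neuropathic
pain model, the cohort composition shifts toward the more excitable
classes.

The raw recordings behind these observations are not deposited anywhere,
so this package pairs the analysis pipeline with a conductance-based
simulator whose four shipped archetypes reproduce the class signatures.
Everything downstream — spike detection, rheobase search, I–F curves,
oscillation detection, passive properties, Ih quantification, cohort
statistics — operates on recordings, simulated or otherwise, and is
tested against closed forms, brute-force oracles and ground-truth
parameter recovery.

## The neuron model

Each model neuron is a single compartment obeying

$$C_m \frac{dV}{dt} = -g_L (V - E_L) - I_{Na} - I_K - I_h - I_{NaP} + I_{inj},$$

with currents (units fixed internally as mV, ms, pA, nS, pF, so that
pA/pF = mV/ms):

* **Fast sodium** $I_{Na} = \bar g_{Na} m^3 h (V - E_{Na})$ and
  **delayed-rectifier potassium** $I_K = \bar g_K n^4 (V - E_K)$, the
  minimal Hodgkin–Huxley spiking pair.
* **HCN current** $I_h = \bar g_h r (V - E_h)$ with $E_h = -30$ mV, a
  first-order Boltzmann-gated activation centred near $-80$ mV (slope
  $-8$ mV: the channel opens with hyperpolarization) and a
  voltage-dependent time constant of order 100–500 ms. This produces the
  slowly developing inward current that defines Ih under voltage clamp.
* **Persistent sodium** $I_{NaP} = \bar g_{NaP}\, p_\infty(V) (V - E_{Na})$
  with instantaneous activation, present only where subthreshold
  oscillations and ramp-evoked bursting are wanted.

All gates use Boltzmann steady states
$x_\infty(V) = 1/(1 + e^{-(V - V_{1/2})/k})$ (the sign of $k$ sets the
direction) and bell-shaped time constants
$\tau(V) = \tau_{min} + \tau_{amp}\, e^{-((V - V_0)/\sigma)^2}$. The
source never prescribes model equations, so these are deliberately the
most standard minimal formulations that realize the observed
phenomenology; nothing in the pipeline depends on this particular choice.

Integration uses exponential Euler on both the gates and the membrane
equation at a fixed step of 0.025 ms (halving the step leaves spike
counts unchanged and moves spike times by well under 0.5 ms — this is a
tested invariant). Saved traces are subsampled to 0.1 ms, the standard
10 kHz acquisition rate. With all active conductances zeroed the step
response matches the closed-form RC solution to better than 1% of the
deflection, which the test suite asserts against ground truth.

## Archetype calibration

The four archetypes (`drg_archetype()`) were calibrated once, against the
qualitative class descriptions only, and then frozen:

* **CLASS1** — low leak (7 nS), relatively hyperpolarized sodium
  activation: continuous, intensity-graded firing from a low rheobase,
  approximately linear I–F, accelerating spiking throughout a ramp.
* **CLASS2_1** — higher leak, strong delayed rectifier whose gate decays
  slowly at subthreshold voltages (the interspike interval is then set
  by K-conductance recovery rather than by drive, which flattens the
  I–F relation), plus a persistent sodium conductance that destabilizes
  the approach to threshold so that slow ramps evoke oscillatory
  bursting rather than accommodation. Largest HCN conductance (22 nS).
* **CLASS2_2** — the same flat-I–F backbone without persistent sodium:
  under a slow ramp the fast sodium current inactivates before threshold
  is reached and the cell stays silent, while abrupt steps still elicit
  sustained constant-frequency firing. Modest HCN conductance (6 nS).
* **CLASS3** — depolarized sodium activation, high leak and very slow
  recovery from sodium inactivation: one spike at onset, then
  unavailability, whatever the drive. Near-zero HCN conductance
  (1.5 nS).

The HCN conductances are ordered CLASS2_1 > CLASS1 ≥ CLASS2_2 > CLASS3,
which is the measured Ih-magnitude ordering across subclasses. Resting
potentials of all archetypes lie in the recorded −62 to −52 mV range.

`generate_cohort()` and `balanced_cohort()` jitter the magnitude
parameters (capacitance and the five maximal conductances)
multiplicatively with a unit-mean lognormal factor (default relative SD
0.1 — modest animal-to-animal channel-expression variability). Kinetic
constants and reversal potentials are not jittered: varying them would
change channel identity, not expression level. Default cohort
composition is the control cohort's: 12.8% Class 1, 26.8% Class 2
(split 70.8%/29.2% into 2-1/2-2, the recorded ramp-response split) and
60.3% Class 3.

## Feature extraction: numerical choices

* **Spike criterion.** Upward crossing of −10 mV followed by a local
  maximum above 0 mV ("overshooting"), with a 2 ms refractory window.
  The threshold tolerates slow depolarizations; the overshoot
  requirement implements the cell-inclusion criterion. Detection is
  tested for exact agreement with a brute-force sample-by-sample scan.
* **Rheobase.** Bisection over 0–2000 pA at 10 pA resolution with 500 ms
  steps (the source reports bands, not a procedure; bisection is the
  standard search). A silent upper bound returns an "inexcitable over
  the tested range" record, not an error.
* **I–F statistics.** Frequency is spike count over the full step window.
  Steps evoking fewer than 3 spikes straddle the firing threshold (a
  spike or two at onset, then silence) and carry no information about
  the sustained relation, so they are excluded from the shape statistics
  (slope, R², CV); they still count for `max_spikes_per_step`. The
  default step family spans 100–1000 pA in 100 pA increments, the range
  shown for the recorded I–F relations.
* **Oscillation detection.** Spikes are excised (3 ms before to 8 ms
  after each peak, linearly interpolated), the ramp depolarization is
  removed with a running-mean detrend, and a periodogram is taken.
  Oscillations are "present" when the peak power in the 20–200 Hz band
  is at least 5× the median broadband power *and* the band-limited
  residual exceeds 0.1 mV RMS. The absolute floor matters: a noise-free
  silent trace has a near-zero spectrum whose shape alone can produce
  arbitrary power ratios. The source shows oscillations but never
  quantifies them; these are the package's own operational definitions,
  validated on constructed sinusoids.
* **Passive properties.** RMP is the mean pre-stimulus voltage; Rm the
  steady-state deflection of a small (−20 pA) subthreshold step over the
  step current (mV/pA = GΩ); Cm is τ/Rm with τ from a single-exponential
  fit of the onset relaxation. Ground-truth recovery is within 5% over
  Rm ∈ [0.05, 0.2] GΩ × Cm ∈ [60, 140] pF. The published passive-property
  table prints its units as "Cm (GOhms)" and "Rm (MOhms)" against values
  near 100 and 0.08; for 50 µm somata these are only physiologically
  plausible as Cm in pF and Rm in GΩ, and the package interprets them
  that way.
* **Quality control.** A neuron is included iff RMP is strictly below
  −50 mV and at least one overshooting spike occurs at a tested step; a
  cell resting at exactly −50.0 mV is excluded, following the strict
  wording of the inclusion criterion.

## Classification rules

`classify()` applies, in order: (1) no spike anywhere → UNCLASSIFIED;
(2) at most `spike_cap` spikes at every step → CLASS3; (3) flat
suprathreshold I–F (CV < `cv_max`) → CLASS2, subdivided by the ramp —
spikes or detected oscillations → CLASS2_1, silence → CLASS2_2, missing
ramp features → an explicit incomplete-features error rather than a
guess; (4) positive I–F slope with R² ≥ `r2_min` → CLASS1; otherwise
UNCLASSIFIED.

The spike-count rule comes first because a cell that barely fires has no
meaningful I–F shape to test; the source describes the classes but not a
precedence. A ramp that evokes firing without detectable oscillations is
assigned CLASS2_1 (the firing response dominates); only the two extremes
are described. Defaults `spike_cap = 5` ("no more than three to five
spikes" read permissively; configurable down to 3), `cv_max = 0.2`,
`r2_min = 0.8` are exposed in `classifier_config()` since the source
gives only qualitative descriptions. Labels are mutually exclusive and
exhaustive over QC-passing inputs, classification is invariant to
resampling recordings from 10 to 20 kHz, and ≥ 90% of 200 jittered
simulated neurons (50 per subclass, fixed seed) recover their generating
archetype.

## Ih quantification

The voltage-clamp protocol holds at −60 mV and steps to hyperpolarizing
commands for 2.5 s. The methods text says "−60 to −20 mV", the figure
says "−60 to −120 mV"; −20 mV is not hyperpolarizing from −60 mV, so the
package follows the figure: commands −60 to −120 mV in −10 mV
increments. Ih is the steady-state current minus the initial
(instantaneous) current, the instantaneous current averaged 12–15 ms
after command onset (past the capacitance artifact, before appreciable
HCN activation — the window is asserted against protocol timing). The
steady-state window is the final 100 ms of the step (no window is
stated; Ih with τ ≤ 500 ms is fully developed after 2.5 s, so any
late window works). Current density divides the Ih magnitude at the
−120 mV step — the maximal activation shown — by the cell's capacitance
from the passive fit of the same neuron. On single-exponential synthetic
families the measurement matches the closed form within 2%
(sub-per-mille in practice), and `block_ih()` (full ZD7288-style block,
g_h = 0) brings every command's Ih under the noise floor. The
inward-rectifier potassium contamination that plagues such measurements
in other preparations is not modelled, consistent with its reported low
expression in DRG neurons.

## Cohort statistics

Class-proportion shifts between cohorts use the uncorrected Pearson
chi-square on per-class 2×2 (in-class / not-in-class) tables — the
published statistics are labelled "F" but are numerically Pearson χ²
values computed this way without continuity correction, as verification
against the printed cohort counts confirms. Passive properties and Ih
densities are compared with a classical one-way ANOVA followed by
uncorrected Fisher's LSD pairwise t-tests on the pooled within-group
variance; with two groups the LSD comparison reduces exactly to the
pooled-variance t-test, which the suite checks. The F statistic is
tested to 1e-10 against an explicit sums-of-squares oracle.

## What the generator does and does not emulate

The simulator reproduces: overshooting spikes, class-specific rheobase
bands, linear vs. flat I–F relations, ramp-evoked oscillatory bursting
vs. accommodation silence, and a slowly activating inward Ih whose
magnitude is ordered across subclasses. It does not emulate: recording
noise by default (optional seeded Gaussian noise is available),
electrode artifacts, multi-compartment or axonal geometry, temperature
effects, channel stochasticity, dose–response kinetics of the HCN
blocker, or the biological parameter correlations within a class beyond
independent lognormal jitter. Passing the recovery tests therefore shows
that the pipeline's rules are faithful to the class definitions and
robust to expression-level variability — not that they would survive
every pathology of real patch-clamp data.

## Problem sizes

The shipped tests and the acceptance analysis use desk-scale problem
sizes chosen to keep a full run in the minutes range on one core:
recovery over 200 jittered neurons (50 per subclass), Ih ordering over
8 neurons per subclass, the demo pipeline over a 40-neuron cohort, and
bisection rheobase searches at 10 pA resolution. All are configurable
upward.

## Known limitations

* The archetypes are calibrated exemplars, not fits to data; absolute
  Ih densities and passive-property means are plausible but not
  quantitative reproductions (the underlying recordings are
  unavailable).
* The Class 2 flat-I–F mechanism (slow K-gate recovery plus persistent
  sodium) is one of several biophysical routes to the same
  phenomenology; the pipeline is agnostic to the mechanism.
* The oscillation detector assumes a single dominant band (20–200 Hz)
  and a ramp-like trend; pathological multi-band signals would need
  retuning.
* ABF and other proprietary acquisition formats are not read; traces
  enter as the package's CSV + JSON-sidecar format (a converter hook is
  the natural extension point).
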