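---
title: "Normal modes and the adaptation of auditory event-related fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normal modes and the adaptation of auditory event-related fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acnet)
```

## The model

`acnet` describes the auditory pathway as five serially connected areas —
inferior colliculus (IC), thalamus, core, belt and parabelt — each reduced to
one cortical-column-like unit with a mean-field excitatory population `u` and
an inhibitory population `v`.  Membrane dynamics follow the Wilson–Cowan
form with a common time constant `tau_m`; the only long-range connections
are excitatory-to-excitatory (matrix `W_ee`, tridiagonal for the serial
network: lateral weight on the diagonal, feedforward below, feedback above),
while `W_ei`, `W_ie`, `W_ii` are local and hence diagonal.  Every excitatory
synapse carries a Tsodyks–Markram-style efficacy `q` that is consumed in
proportion to presynaptic activity (release time constant `tau_o`) and
replenished slowly (`tau_rec`).  Efficacy acts presynaptically: `q_j` scales
every connection *sent* by area `j` (the efficacy matrix multiplies `W_ee`
on the column side).  IC and thalamus are treated as non-adapting — their
lemniscal synapses recover an order of magnitude faster than cortical ones —
so their efficacies are pinned at 1.

Tone onsets are delta inputs of weight `a` to the IC's excitatory
population; integrating the membrane equation across the impulse turns each
onset into a state jump `a / tau_m`.  Between onsets the (linearised)
system is homogeneous, `d/dt (u, v) = M (u, v)`, and is solved exactly by
the eigendecomposition of `M`: each eigenpair is a *normal mode*, a damped
oscillation `exp((gamma + i omega) t)` with a fixed spatial profile spread
over all areas.  For the default parameters all ten modes of the ten-
dimensional system are underdamped, stable, and organised on a dispersion
curve where faster oscillation implies faster decay.

## Parameters

| name | meaning | default | units |
|---|---|---|---|
| `w_ee_d`, `w_ee_ff`, `w_ee_fb` | lateral / feedforward / feedback excitatory weights | 2, 0.5, 0.4 | – |
| `w_ie_d`, `w_ei_d`, `w_ii_d` | local E→I, I→E, I→I weights | 3.5, 2.2, 2.5 | – |
| `tau_m` | membrane time constant | 0.03 | s |
| `tau_o` | transmitter release time constant | 0.04 | s |
| `tau_rec` | replenishment time constant | 5 | s |
| `a` | afferent input weight (jump `a/tau_m` ≈ 0.67) | 0.02 | – |
| `alpha` | firing-rate gain | 1 | – |
| `k1_d`, `k1_ff`, `k1_fb` | MEG multipliers, excitatory classes | −1, −1, 15 | – |
| `k2_d` | MEG multiplier, inhibitory synapses | 2 | – |

These defaults produce realistic-looking ERFs: a small P1m near 50 ms of
sensor latency, a dominant N1m near 100 ms, a P2m near 180 ms (model times
are ~30 ms earlier; the package treats that conduction allowance purely as a
display shift, never in analysis).  The weights put every isolated column in
the damped-oscillator regime; raising `w_ee_d`/`w_ei_d` substantially can
produce self-sustained oscillation, which is outside the package's intended
regime and will surface as positive decay rates in `spectral_decomposition`.

## The slow-fast scheme

Because `tau_o << tau_rec`, depression splits into a fast drop during the
stimulus-evoked transient and a slow recovery through the silent remainder of
the inter-onset interval.  The scheme holds `Q` constant within each
interval, so the response to stimulus `s` is the mode superposition of
`M_s = M(Q_s)`; the efficacy update composes a closed-form release factor
(the time integral of each mode's contribution to `u`, summed over modes)
with exponential recovery over the full interval.  Release and recovery are
deliberately sequenced, not co-integrated, and recovery uses the whole
interval even though release consumes part of it — this is the scheme's
defining approximation and we do not "improve" it, because the package's
purpose is to analyse exactly this approximation.  Eigenvalues with
`|lambda| * delta < 1e-12` use the limit `(e^(lambda delta) - 1)/lambda ->
delta`.

Consequences worth knowing (quantified by `validate_against_full_model`):

* within an interval the true efficacy keeps falling while the response
  unfolds, so the scheme overestimates first-response peaks downstream of
  the core by ~15–20 %; once adapted, the discrepancy against the linear
  full model settles to a few percent;
* the nonlinear (`tanh`) model transmits the IC jump through a saturating
  firing rate (`tanh(0.67) ≈ 0.58`), making all cortical amplitudes ~10 %
  smaller than in the linearised system.  The *adaptation pattern* —
  which is what the scheme exists to analyse — is captured well: the
  efficacy sequence tracks the full model's within ~2 %.

A warning is emitted for SOIs below 0.5 s, where the assumption that the
state decays to zero between onsets degrades (the sustained-response regime
is out of scope).  The adapted state is defined as the response after 111
stimuli (the block length of the motivating experimental paradigm), with an
early stop once the efficacy update falls below `1e-6`; the update map
contracts by `exp(-SOI/tau_rec)` per stimulus, so this tolerance leaves the
adapted efficacy accurate to ~1e-5.  The dense-grid experiment below
tightens the tolerance to `1e-12` because consecutive conditions differ by
less than the default tolerance at large SOI.

Monotonicity caveat: the *core's* efficacy decreases monotonically to its
fixed point, but belt and parabelt can rebound by up to ~2e-4 per stimulus
once upstream depression has weakened their drive; tests assert strict
monotonicity only for the core.

## The MEG forward model

Each synaptic input contributes to the sensor signal with a multiplier set
by its class: feedforward and lateral excitatory input arrives near the
soma and drives primary current away from the cortical surface (negative
multiplier), feedback input arrives apically and drives it toward the
surface (large positive multiplier), and local inhibition contributes with
its own weight.  Subcortical areas generate no field, but thalamocortical
synapses terminate in cortex and do contribute.  The signal is therefore a
weighted sum over the entries of `K1 ∘ W_ee` and `K2 ∘ W_ei` applied to
`(u, v)` — implemented with the *static* `W_ee` (no efficacy modulation) as
the forward model is written; `meg_weights = "depressed"` exposes the
alternative for sensitivity analyses.

Two exact decompositions follow from linearity and are enforced to 1e-9 in
the tests: the per-mode sum `R(t) = sum c_n kappa_n exp(lambda_n t)`
(input efficiency `|c_n|` × MEG efficiency `kappa_n`), and the partition of
the forward-model summands by incoming area, outgoing area, or connection
type.  Note that `|c_n|` and `kappa_n` individually depend on the
eigenvector normalisation (right vectors have unit Euclidean norm here, left
vectors are rescaled to biorthonormality); only their product and all
signal-level quantities are convention-free, which the tests verify by
recomputing under a perturbed scale convention.

## Design decisions

**Landmark windows.**  The model's N1m peaks at 63–72 ms of *model* time
under the default parameters.  Windows are therefore P1m [0, 40] ms,
N1m [40, 200] ms, P2m [100, 350] ms (configurable); placing the N1m window
at the conventional sensor-latency 70 ms would clip the peak.  Landmark
polarity is anchored structurally: the P1m polarity is that of the
feedforward-dominated group, the N1m is the opposite deflection, so no sign
convention for `R` is assumed.  Peaks of analytically synthesised waveforms
are refined by optimising the mode sum itself (grid-free); other waveforms
use three-point parabolic interpolation.

**Variant shortcuts.**  The CP (core↔parabelt) and TB (thalamus↔belt)
variants add a feedforward connection of the generic weight `w_ee_ff`
one-way by default.  With bidirectional additions the excitation effect on
the adaptation lifetime roughly triples (~1.3 s rather than ~0.5 s) and the
parabelt lifetime inflates under CP; the one-way default reproduces the
reported phenomenology.  `directions = "both"` and custom `added_ff`/
`added_fb` weights remain available.  Normalised variants (CPN, TBN) rescale
`W_ee` uniformly so its element sum equals the serial network's (13.6),
restoring the excitation-inhibition balance.

**Per-area adaptation measure.**  The per-area recovery fits default to each
area's *contribution to the ERF* (the incoming-connection group — the model
analogue of source modelling), not the raw `u(t)` peak.  The contribution
measure yields the coherent picture: lifetimes 2.2–2.8 s with intercepts
−1.5…−0.5 s across the structure-only variants, the belt exceeding the core
by ~0.2–0.3 s, and belt ≈ parabelt in the serial network.  Raw-`u` fits
(available via `area_measure = "state"`) behave differently — the core's
raw activity is shielded by the non-depressing thalamic drive, giving
shallow relative adaptation and intercepts near −1.9 s.

**Recovery fitting.**  All three parameters of
`A (1 - exp(-(SOI - t0)/tau_soi))` are free.  Starting values come from the
integral linear-regression linearisation (a running trapezoidal integral of
the data obeys a linear relation whose slope estimates `-1/tau`), refined by
Levenberg–Marquardt least squares (`minpack.lm`) with 1e-10 parameter
tolerance; non-convergence returns the initialiser's estimate flagged
`converged = FALSE`.  On noiseless model data the parameters are recovered
to 1e-6.  Be aware the problem is ill-conditioned: with 2 % multiplicative
noise on the standard 5-SOI design, the lifetime estimate carries a ~4-fold
noise amplification (mean error ~8 %, 90th percentile ~17 %) — a caution
that applies equally to fitting experimental N1m data.

**Dense-SOI experiment.**  The local-saturation-rate diagnostic uses 99
evenly spaced SOIs from 0.2 to 20 s.  On an exact exponential a finite grid
of step `delta` gives the constant `(1 - exp(-delta/tau))/delta`, not
`1/tau`; the diagnostic is asserted to be *constant* for exponential data
and monotonically decreasing, converging to ~0.2 s⁻¹, for model data — the
converged value is grid-robust, whereas the fitted-curve rate (~0.3 s⁻¹)
depends on the grid and is reported only descriptively.

## Numerical choices

* Reference integration: `deSolve::lsoda`, `rtol 1e-9` / `atol 1e-12`,
  restarted at every onset so jumps never cross a solver step; divergence
  (non-finite state) aborts with a diagnostic.
* Eigendecomposition: base `eigen`; left vectors from `solve(V)`; a
  biorthonormality residual above 1e-8 raises a "numerically defective"
  error rather than silently regularising.  Modes are sorted by `|omega|`
  (positive member of each conjugate pair first); modes with
  `|omega| < 1e-8` are classified overdamped and handled in real
  arithmetic.
* Imaginary residuals of physically real quantities (state superpositions,
  release integrals) are checked against 1e-9 relative tolerance before
  being discarded.
* With efficacy clamped, the integrator and the spectral solution agree to
  ~3e-11 relative L2; the spectral evolution is tested against a dense
  matrix exponential to 1e-9.

## What the simulations do and do not capture

All inputs are self-generated: periodic, identical, delta-like tones into a
noise-free, five-area, single-column-per-area network.  Passing tests
therefore demonstrate internal consistency of the solution machinery and
reproduction of the model's phenomenology — N1m growth and latency increase
with SOI, an SOI-invariant normalised rising flank, feedback-driven
adaptation, area-specific lifetimes — not agreement with any individual
subject's recordings, which involve measurement noise, tonotopy, multiple
fields per area, and non-periodic stimulation.  Conduction delays, stochastic
inputs, oddball designs, sub-500-ms SOIs and realistic head models are out
of scope.  Experimental block length (111 repetitions) and the standard SOI
set {0.5, 1, 2.5, 5, 10} s are used as the default study conditions; the
acceptance pipeline runs the full five-variant sweep (25 adaptation runs,
each at most 111 ten-dimensional eigendecompositions) plus the 99-condition
dense sweep in a few seconds on one CPU.
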