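---
title: "Closed-loop cavitation control and quantitative imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop cavitation control and quantitative imaging: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soniquant)
```

# The problem

Focused ultrasound (FUS) combined with intravenously injected microbubbles
can transiently open the blood-brain barrier (BBB) and let systemically
administered drugs reach brain tissue. The therapeutic window is narrow:
stable microbubble oscillation (visible as harmonics of the drive frequency
in passive cavitation detector recordings) marks effective, safe exposure,
while subharmonic and broadband emissions mark the approach to and onset of
inertial cavitation, which damages microvessels. `soniquant` implements the
complete software side of an acoustic-emissions feedback loop for a
230 kHz volumetric exposure — spectral band analysis, the per-target
proportional power controller, and a synthetic cavitation "plant" to close
the loop against — together with the quantitative MRI (R1 relaxometry,
gadolinium quantification) and treatment-outcome statistics used to evaluate
such treatments.

# Emission band analysis

## Band scheme

With a 230 kHz drive, the monitored bands are the subharmonic at 115 kHz and
the second and third harmonics at 460 and 690 kHz, each integrated over a
10 kHz bin, plus a 40 kHz broadband bin at 640–680 kHz centred on the
broadband hydrophone's 660 kHz resonance. The broadband bin deliberately
excludes both harmonic centres, so broadband energy is not confounded with
strong harmonics; `band_scheme()` enforces this at construction. Detector 1
(resonant at the subharmonic) carries the 115 kHz band; detector 2 carries
the harmonic and broadband bands.

## Band power definition and windowing

`compute_band_powers()` forms a one-sided periodogram of the full 5 ms burst
under a Hann window — a single segment, with no Welch averaging, because the
bursts are short and stationary — and reports `10*log10` of the summed
periodogram power over each half-open bin `[centre - w/2, centre + w/2)`. A
zero-energy band is guarded to a finite sentinel of −120 dB so downstream
dB arithmetic never produces `-Inf`. At the default burst length (5 ms,
i.e. 200 Hz resolution) the Hann main lobe spans under ±500 Hz, so a pure
tone at a band centre contributes essentially all (>99%) of its energy to
its own 10 kHz bin, and the 640–680 kHz broadband bin does not capture the
main lobe of either harmonic.

## Noise floors and event thresholds

Two noise floors are calibrated per sonication, and they serve different
purposes:

* the **pre-sonication floor**, from 3.5 s of passive spectra before the
  exposure, is the reference for the harmonic enhancement `H`;
* the **early-burst floor**, from the bursts applied at the 0.16 W starting
  power during the first 8 s (before the microbubble bolus reaches the
  brain), is the reference for event detection: a subharmonic event requires
  the 115 kHz band to exceed this floor's mean by more than 3.2 sample
  standard deviations, a broadband event requires 3.9 SD at 640–680 kHz.

The assignment of floors to purposes is a design choice: the two floors are
described with those two purposes, but the pairing is not stated explicitly;
this split mirrors each floor's stated role (the harmonic goal is expressed
in dB above "the noise floor" measured passively; the SD thresholds are
defined on the second, burst-condition floor). Threshold comparisons are
strict (`>`): a band power exactly at mean + k·SD is a non-event.

The controlled variable `H` is the arithmetic mean of the second- and
third-harmonic band elevations in dB. Averaging in the dB domain (rather
than averaging linear powers before conversion) is the chosen convention; it
is the natural reading of "mean signal strength at the second and third
harmonics" when magnitudes are handled in dB throughout, and it makes `H`
directly comparable to the 6–7.5 dB goal band.

# The controller

## Phase schedule

Each of the 9 targets is sonicated with 5 ms bursts every 101.6 ms
(per-target pulse repetition frequency 1/(9·0.1016 s) ≈ 1.09 Hz) for 75 s.
Each target's power trajectory moves through three phases:

1. **fixed_pre** (0–8 s): power held at 0.16 W while the bolus transits to
   the brain; these bursts also calibrate the early-burst floor. No event
   detection is evaluated here — the flags would otherwise be tested against
   the very data that defines their floor.
2. **controlling** (8–25 s): proportional feedback (below), with safety
   reduction on any detection event.
3. **frozen** (25–75 s): because the circulating microbubble concentration
   decays, power is never increased after 25 s; it is fixed at the
   arithmetic mean of the powers of all bursts whose `H` fell inside the
   goal band. If the goal was never achieved, the current power is held — a
   conservative, least-surprise fallback for a case the protocol leaves
   open. Averaging in the power domain (not pressure) is the chosen
   convention.

## The proportional law

The source protocol gives the controller's constraints — proportional
control on `H`, gain `P_gain = 0.0167`, the assumption that harmonic
enhancement in dB is proportional to pressure amplitude, and pressure
proportional to the square root of acoustic power — but not the update
equation itself, so the law here is a reconstruction from those constraints
(and is config-swappable). With `H_set = 6.75` dB (the goal-band midpoint —
the protocol specifies a band, not a setpoint):

* if `H ∈ [6.0, 7.5]` dB: power unchanged; the power is recorded as a goal
  hit;
* otherwise, a relative step in the pressure domain,
  `p ← p · (1 + P_gain · (H_set − H))`, equivalently
  `power ← power · (1 + P_gain · (H_set − H))²`, clamped to (0, 0.39 W].

The multiplicative factor is floored at 0.05 so that a pathologically large
`H` cannot drive the pressure through zero. Non-finite `H` (a corrupt burst)
skips the update and holds power, with a warning.

The upper goal edge is configurable because the protocol is internally
inconsistent about it (6–7.7 dB in one place, 6–7.5 dB in another); the
package defaults to 7.5 dB, the value attached to the observed behaviour.

## Safety reduction

A subharmonic or broadband detection on a target's burst reduces that
target's power by 25% and fixes it for the remainder of the sonication.
The reduction is applied at most once per target and also applies to a
target already frozen by the end-of-control rule — detection "at any time"
triggers it — after which the reduced state is terminal; repeated flags
cause no further reduction. Reduction and freezing are per-target (power is
per-target); a `global_freeze` switch applies the reduction to all targets
on any event, for the stricter global reading of the rule.

## Convergence behaviour

On a noise-free plant with `H` linear in pressure and the goal reachable
below the cap, the power sequence from 0.16 W is monotone and enters the
goal band within a few control cycles (the dB error contracts by roughly
`1 − P_gain·H` per update). Because updates stop inside the band, the
steady power is the first in-band power of that monotone sequence — the test
suite verifies it against an independent closed-form iteration of the law,
and verifies separately that the plant's analytic fixed point
`p* = p₀ + H_set/slope` indeed yields `H(p*) = H_set`. On a zero-response
plant the sequence saturates exactly at the 0.39 W cap and never exceeds it.

# The synthetic plant

The plant exists to close the loop without hardware and to generate
realistic fixtures. It models, per burst:

* **power→pressure**: `p = 119 kPa · sqrt(P / 0.16 W)` (calibrated anchor;
  0.16–0.39 W maps to 119–186 kPa);
* **bolus kinetics**: relative concentration 0 before an 8 s arrival, a
  smooth half-cosine ramp to 1 over 1 s, then single-exponential clearance.
  The 40 s default half-life is a synthetic, order-of-magnitude value for a
  lipid-shelled agent — no measured kinetics stand behind it, and it must
  not be read as data;
* **harmonic response**: band power = floor + `slope · (p_eff − p₀)⁺` +
  Gaussian band noise, with `p_eff` = pressure × concentration × per-target
  sensitivity. The default slope 0.04 dB/kPa places the goal band's
  midpoint near 169 kPa (≈0.32 W), comfortably below the cap; the default
  activation floor `p₀` is 0 (pure proportionality, the stated modelling
  assumption);
* **events**: subharmonic and broadband events share a single latent
  uniform draw per burst, compared against logistic probabilities
  `plogis((p_eff − threshold)/width)` with band-specific thresholds
  (defaults 250 and 260 kPa, width 12 kPa) — both event types concentrate
  at the same sensitive locations, which the shared latent encodes. An
  event adds 25 dB to its band. At default calibration events are rare at
  operating pressures (well under 1% of bursts), matching the observed
  regime; doubling pressure beyond the cap makes them frequent;
* **per-target sensitivity**: multipliers on `p_eff`; the default makes the
  second location 12% more sensitive, reproducing in *direction only* the
  observation that one location consistently needed less power.

All randomness flows through named per-target streams derived from one seed
(`rng_streams()`), so identical seeds give bit-identical logs and one
target's draws cannot perturb another's trajectory.

`synthesize_waveform()` inverts the band integrator — one tone per band,
amplitude calibrated against a unit tone under the same window — so the
band-level plant can be pushed through the full waveform-level emissions
path; round trips recover band powers within 0.5 dB.

What the plant does **not** emulate: bubble-size dynamics
(Rayleigh–Plesset), skull reflections and standing waves, spatial focal
geometry (targets are bookkeeping), recirculation boluses, or detector
transfer functions. Passing tests against this plant therefore demonstrate
controller logic and statistical machinery, not in-vivo fidelity.

# R1 relaxometry and gadolinium quantification

The multi-TR fast-spin-echo series is fit per voxel to the
saturation-recovery model `S(TR) = S0 · (1 − exp(−TR·R1))` by
Levenberg–Marquardt least squares. The fixed echo time contributes a
constant T2-weighting factor absorbed into `S0`, so it cancels in the fit.
Initialisation is closed-form and deterministic: `S0` from the maximum
signal, `R1 = ln 2 / TR*` with `TR*` the TR nearest half-maximum. The fit is
unweighted by default even though the acquisition averages differ per TR
(1–4 averages across the 6.0–0.1 s ladder); `weighted = TRUE` applies
weights ∝ √averages. Non-converging voxels and non-positive fitted rates
are flagged and masked, never fatal. On the default TR ladder with 1%
Gaussian noise, recovery across the physiological 0.3–2.0 s⁻¹ range shows
<1% bias and <3% RMSE (verified in the suite).

Contrast-agent concentration follows from the relaxivity identity:
`[Gd] (mM) = ΔR1 / 4.44 s⁻¹mM⁻¹`, and µg/g = mM × molar mass under the
1.0 g/cm³ tissue-density homogenisation assumption. Whether published
mass concentrations use the full chelate molar mass (604.71 g/mol, the
default here) or the Gd³⁺ ion mass is ambiguous in general, so the molar
value is the primary output and the molar mass is a parameter.

`hemispheric_delta()` compares mean R1 within `radius_mm` (default 1.5 mm)
of the sonication targets, per labelled structure and for the whole covered
volume, against the mirror-reflected contralateral region about a
configurable sagittal midline; coordinates are voxel-centre indices and the
mirror is an exact voxel reflection, so swapping hemispheres negates ΔR1
exactly. `percent_enhancement()` computes the voxelwise percent T1 signal
increase and its across-plane maximum-intensity projection, excluding
non-positive pre-contrast voxels.

# Outcome statistics

* **Doubling time**: `V(t) = V0 · 2^(t/Td)` by nonlinear least squares with
  a log-linear warm start; exact on clean exponentials, scale-invariant,
  and `Td = Inf` (flagged, not an error) for zero growth. Group values are
  reported as per-subject fits; the hypointense-core and hyperintense-volume
  channels are fit independently.
* **Kaplan–Meier**: product-limit estimator via the survival package, with
  the standard tie rule (deaths before censorings). Two median conventions
  are exposed: the default averages the bracketing times when the curve hits
  exactly 0.5 (with even n, no censoring, this is the mean of the two middle
  order statistics — e.g. 41.5 for events at 32/35/38/45/50/53 days); the
  alternative `first_leq` takes the earliest time with S ≤ 0.5 (38 in that
  example).
* **Log-rank**: observed-minus-expected chi-square with k−1 df; an exact
  label-permutation reference is available for small samples and is used in
  the suite to check the asymptotic p against the exact one at n = 12
  (agreement within 0.05, the scale of the asymptotic error at that n).
* **Concentration summaries**: geometric mean `exp(mean(ln x))` and
  geometric %CV `100·sqrt(exp(s²_ln) − 1)`; sonicated-vs-control pairs use
  a paired two-tailed t-test on log-transformed values. Zero-variance
  log-ratios are handled explicitly: identical pairs give t = 0, p = 1; a
  perfectly constant non-unit ratio has no valid t statistic and is flagged
  degenerate.
* **Dose conversion**: human equivalent dose mg/m² = mg/kg × Km (Km = 6 for
  rat), so 50 mg/kg ↔ 300 mg/m².

# Numerical and design notes

* Sonication logs are exchanged as CSV (wide per-burst, or long
  burst × band) and JSON summaries; configurations as YAML with full
  validation (unknown keys rejected, range checks at construction).
* The bolus-arrival gate (a controller parameter) and the plant's arrival
  time are deliberately decoupled: the controller waits 8 s because the
  protocol does, regardless of when a particular plant's bubbles arrive.
* Problem sizes in the test suite are chosen for tight feedback while
  keeping estimator error well below the asserted tolerances: 738-burst
  (75 s) closed-loop runs, 500-voxel and 18 × 40 grid-replicate R1
  recoveries, 200 growth-fit replicates, 10⁴-draw event-rate and
  permutation checks.
* Default-plant simulations show the frozen-phase `H` drifting below the
  goal band as the synthetic bubble concentration clears — exactly the
  overexposure-avoidance rationale for freezing the power at 25 s. The
  goal-holding verification therefore uses the non-clearing noise-free
  plant, where the frozen-phase mean `H` must sit inside 6–7.5 dB.

# Known limitations

The plant is a behavioural stand-in, not a physical model; its clearance,
noise, and event parameters are synthetic defaults. The R1 pipeline assumes
given masks and registered geometry (no registration is provided) and
ignores contrast-agent diffusion during the multi-TR scan. Hazard ratios
are out of scope (per-subject survival times cannot be reconstructed from
summary tables). The controller's real-time timing behaviour (latency,
jitter) is not modelled — burst timestamps are ideal.
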