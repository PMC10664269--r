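---
title: "Models and methods behind kinegen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kinegen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinegen)
```

`kinegen` analyses ballistic jump and sprint trials — marker trajectories
from optical motion capture plus vertical ground-reaction force from a
force platform — into joint-level torque/power outcomes, and tests
candidate-gene associations (ACTN3 R577X, ACE I/D) against them. This
vignette explains the models, the algorithmic choices, the tunable
parameters and what the synthetic-data generator does and does not emulate.

## The outcome model

All angular quantities stay in degrees end to end, because that is how this
outcome family is defined and reported in jump testing:

* Relative torque: `RT(t) = m_seg × α(t) / m_body`, where `α` is the joint
  angular acceleration (deg s⁻²), `m_seg` the mass of the segment chain
  distal to the joint, and `m_body` the total body mass. Note the unit
  tension: a kg-normalised product of mass and *angular* (not linear)
  acceleration in degrees is not a newton-metre, although the quantity is
  often labelled as one. We implement the formula literally and make no SI
  claim; `RT` is a mass-normalised angular outcome whose value depends on
  the degree convention.
* Power: `P(t) = RT(t) × ω(t)` with `ω` in deg s⁻¹, reported as the peak of
  the same series over the phase of interest ("peak power" is not a
  separate formula).
* `RFD = F_peak / t_to_peak` over the push phase (eccentric onset to
  takeoff; concentric onset for squat jumps).
* `RSI = h_DJ / t_contact`; `IReaF = (h_DJ − h_SJ)/h_SJ`.
* Jump height, two estimators: flight time (`h = g t_f² / 8`, assuming
  landing at takeoff height) and marker apex (sacrum apex during flight
  minus a reference height).

Segment masses come from an editable anthropometric fraction table
(`anthropometry_config()`), defaulting to adult-female fractions from
de Leva's adjusted Zatsiorsky tables (thigh 0.1478, shank 0.0481, foot
0.0129 of total mass, one side). The hip uses the extensor-chain mass
(thigh + shank + foot), the knee shank + foot. These are deliberately
configuration, not constants: any other table can be supplied and is
recorded with the results.

Hip angles use the marker triplet ASIS–trochanter–condyle (E, D, C) and
knee angles trochanter–condyle–malleolus (D, C, B), per side, following the
text convention for this marker model. (Some descriptions of the same model
list the knee triplet as B–C–E; we implement the D–C–B reading and surface
the discrepancy here rather than resolving it silently.) The angle is the
inner angle at the vertex marker, so an extended knee reads about 180° and
a parallel squat about 90°, matching goniometer practice.

## Signal conditioning

Markers are smoothed with a zero-phase (forward–backward) Butterworth
low-pass, default 4th order at 10 Hz — the conventional range for jump
kinematics — and differentiated by central differences (exact for
polynomials up to degree two at interior samples). The zero-phase filter is
implemented in the package on top of `signal::butter` coefficients, with
odd-reflection edge padding and steady-state initial filter conditions, so
a constant series passes through unchanged to machine precision and edge
transients are suppressed. The `signal::filtfilt` convenience was not
usable here: it initialises the filter state at zero and distorts series
whose level differs from zero by a large offset (metre-scale positions).

Two properties of zero-phase IIR filtering matter for interpretation: the
output *anticipates* upcoming transitions (the backward pass runs time
reversed), and a sharp kink is smeared symmetrically over roughly the
filter's settling width. Event detection therefore does not rely on the
smoothed signal where precision matters (next section).

## Phase segmentation

Trials are segmented into the phase labels D (on-box stance), F1
(box-to-ground fall), L1 (landing instant for drop jumps; quiet standing
for countermovement jumps), E (eccentric descent), C (concentric
propulsion), F2 (jump flight), L2 (final landing).

* **Flight** is detected from the force record: maximal runs with
  `Fz < 10 N` lasting at least 50 ms (debouncing against landing ringing),
  with interval end points linearly interpolated at the threshold
  crossings. For CMJ/SJ the *longest* force-free run is the jump flight: a
  vigorous unweighting can briefly drop `Fz` below threshold
  mid-countermovement, and that dip must not be mistaken for flight.
* **Movement onsets** (CMJ eccentric onset, SJ push onset) come from the
  force record too: the first sustained deviation of `Fz` from the
  quiet-stance body weight (threshold `max(20 N, 6 SD)` of the quiet
  segment, 10 ms sustained, backtracked to the last near-quiet sample).
  Any change of centre-of-mass acceleration registers in the force signal
  instantly and without marker noise, which makes this the most precise
  onset sensor available.
* **The eccentric/concentric boundary** is the instant of zero vertical
  centre-of-mass velocity, located by the impulse–momentum theorem:
  `v(t) = v₀ + ∫ (Fz − m g)/m dt` integrated across ground contact, with
  `m` estimated from the quiet-stance force and, for drop jumps, `v₀` (the
  touchdown velocity) recovered from the whole-contact impulse balance
  combined with the flight-time takeoff velocity. The zero crossing is
  interpolated at the force clock's resolution.
* **Drop-jump step-off** (the D/F1 boundary) has no force signature — the
  athlete stands on the box, off the plate — so it is estimated from the
  *raw* sacrum trajectory by a changepoint fit: motion from rest is locally
  quadratic in time, so `z(t) = b₀ + b₁((t−t₀)₊)²` is fitted by least
  squares over a quarter-frame grid of candidate onsets `t₀`, and the
  residual-minimising candidate wins. Fitting raw samples sidesteps the
  anticipation bias that zero-phase smoothing would add at the kink. The
  same estimator serves as fallback for the force-based onsets whenever the
  force record is unusable, and a two-sided variant (different curvature on
  each side of a shared vertex) is the fallback for the height minimum.

Marker and force clocks are independent (`frequency` vs the plate's own
rate); phase boundaries are kept in seconds and mapped to frame indices per
consumer. DJ ground-contact time is the touchdown-to-takeoff interval on
the force clock. The tie-break for the stretch-shortening-cycle speed
classification places a contact time of exactly 0.250 s in the "slow"
class; the defining brackets are strict inequalities on either side, so the
boundary needed an explicit, documented assignment.

The jump-height "marker" method needs a reference height. For CMJ we use
the mean sacrum height during quiet standing (L1). For SJ (which starts in
a held squat, never standing) and DJ (whose pre-trial stance is on the box,
so a stance reference would be contaminated by the box height) the
reference is the sacrum height at the takeoff instant, interpolated at the
sub-frame flight start — which is exactly the height whose ballistic rise
the flight-time method estimates, so the two estimators measure the same
physical quantity for every jump type. The apex itself is refined by a
parabolic fit through the three samples around the discrete maximum.

## The synthetic-data generator

`simulate_jump_trial()` builds a piecewise-smooth pelvis trajectory per
jump type and derives everything else from it:

* quiet stance → (CMJ) cosine eccentric descent to the countermovement
  depth, ending at zero velocity → quarter-sine-velocity concentric push
  reaching `v_to = √(2 g h)` at takeoff → ballistic flight → quarter-cosine
  landing cushion → final hold. SJ starts in the held squat (depth from the
  90° knee geometry by default) with no descent; DJ starts on the box
  (default 0.20 m), falls (F1), then splits its configured contact time
  half/half into eccentric cushioning and concentric push.
* The leg chain is planar (sagittal): a two-link shank+thigh chain under
  the pelvis, foot fixed during contact, knee position solved by two-link
  inverse kinematics, mirrored left/right across a fixed pelvic half-width;
  during flight the chain is frozen at its takeoff configuration and
  translates rigidly. Hip/knee ground-truth angle series come from the same
  geometry.
* The force plate synthesises `Fz = m (g + z̈)` during floor contact and 0
  otherwise (box stance is off-plate), with `z̈` the closed-form second
  derivative of the pelvis trajectory, sampled on the plate's own clock
  (default 1000 Hz vs 200 Hz cameras, as in real laboratories). Marker
  noise is isotropic Gaussian jitter with configurable SD, seeded.

Profile shapes were chosen so the simulated events are physically
*identifiable*: the push's acceleration peaks at the eccentric/concentric
transition and reaches zero at takeoff, and cushions end at peak
deceleration, so the height minimum has finite curvature on both sides. A
configuration whose descent would require more than `0.95 g` of downward
acceleration is rejected — a real athlete cannot unweight faster than
free fall while keeping the feet on the plate.

What the generator does *not* emulate: arm swing, trunk pitch, bilateral
asymmetry, soft-tissue artefact (noise is white, not autocorrelated),
marker occlusion beyond gap injection in the file format, force-plate noise
and drift, and non-vertical ground-reaction components. Passing the
recovery tests therefore demonstrates correctness of the analysis chain
under the stated motion model, not robustness to every artefact of real
capture sessions.

`simulate_cohort()` draws two alleles per participant per locus (genotype
frequencies p², 2pq, q² in expectation, so Hardy–Weinberg holds by
construction), generates covariates (body mass ≈ N(57, 6) kg, BMI near 23,
age 18–45, female — matching the population the protocol recruits), and
shifts one outcome by `effect_size × model_code(genotype)`; a `cohens_f`
parameterisation solves for the shift that yields a requested
between-genotype SD. `simulate_study()` writes a complete study —
genotype CSV, per-trial marker/force TSVs, manifest — in which the genetic
effect acts on jump vigour (flight height) with ~0.02 m of individual
variability, so torque and power outcomes inherit the effect through the
full biomechanical chain rather than being shifted directly.

## Statistical genetics

Codings follow the classical single-locus schemes — additive 0/0.5/1,
reference-allele-dominant 0/0/1, variant-allele-dominant 0/1/1 — with the
ACE D and ACTN3 X alleles as the counted variants. Analyses:

* Hardy–Weinberg: Pearson chi-square against `n(p̂², 2p̂q̂, q̂²)` on 1 df
  (one allele frequency estimated). Implemented directly; `chisq.test`
  cannot express the estimated-frequency df.
* Genotype ANOVA via `aov`, η² = SS_between/SS_total, Tukey HSD via
  `TukeyHSD`. An outcome that is numerically constant is reported as
  η² = 0 rather than a ratio of rounding residues.
* Two-group comparisons (RR+RX vs XX; DD+ID vs II): Welch t by default
  (a pooled-variance flag exists), plus a one-sample Kolmogorov–Smirnov
  check of each group against its fitted normal. Welch is the safer default
  when only "a t test" is specified and group variances are not known to be
  equal.
* Model discrimination: per-model r² (squared Pearson correlation of coded
  genotype with outcome) expressed as `100 r²/η²`, the share of the
  model-free genotype variance each architecture captures; the largest
  share names the best model, with exact ties resolved toward additive
  (the least committal architecture). Discrimination is reliable at large
  n (the test suite demonstrates ≥ 90% recovery of a dominant architecture
  at n = 1000) and genuinely uncertain in small cohorts — a property of
  the problem, not the estimator.
* Likelihood-ratio covariate tests on Gaussian linear models via `logLik`
  (`LR = 2Δℓ`, chi-square reference on the parameter difference), which for
  these models equals `n log(RSS₀/RSS₁)` — kept as an independent identity
  check in the tests. Mild anti-conservatism at small n is expected of
  ML-based LR tests and visible in the calibration suite's upper band.
* Power/planning: `empirical_power_oneway()` simulates balanced one-way
  designs with means spaced to a requested Cohen's f (n-weighted
  between-group SD over unit within-group SD) and reports the rejection
  fraction; `attrition_adjusted_n(n, rate) = ⌈n(1+rate)⌉`.
* No multiplicity adjustment is applied by default (none is specified for
  this analysis plan); sexes are analysed separately by filtering on the
  cohort's sex field before association.

## Numerical choices and degenerate inputs

* Flight threshold 10 N, 50 ms debounce; onset thresholds `max(20 N, 6 SD)`
  hit / `max(5 N, 4 SD)` backtrack; all configurable where exposed.
* Gap cells in marker files (empty, or an all-zero triple when the dialect
  flag says so) are linearly interpolated up to 10 consecutive frames;
  longer gaps, or gaps touching the trial boundary, reject the trial —
  extrapolated positions would corrupt derivatives silently.
* Coincident markers within 1 µm raise a degenerate-geometry error naming
  the frame; `acos` arguments are clamped to [−1, 1].
* Constant force makes RFD undefined (peak at zero elapsed time) and is
  reported as an error, not infinity.
* Aggregation across a participant's trials: `mean` or `best`, where best
  is the maximum for heights, torque, power, RFD and RSI and the minimum
  for sprint and contact times; the method tag is stored with the results.
* All simulation is seed-deterministic (`withr::with_seed`), and identical
  pipeline inputs produce byte-identical output files (12-significant-digit
  formatting).

## Problem sizes in the test suite

The recovery suite runs 200 simulated trials mixing the three jump types,
flight heights 0.15–0.35 m and marker noise from 0 to 2 mm; calibration
suites use 2000 null replicates per test (HWE, Welch t, LRT) and 200
cohorts of n = 1000 for architecture recovery; Monte-Carlo power uses 1000
replicates at the planned N = 269. These sizes keep the full suite under a
minute of statistical computation while leaving Monte-Carlo standard errors
well inside the asserted bands.

## Known limitations

* The planar linkage cannot produce frontal/transverse-plane angles; the
  angular outcomes are sagittal flexion/extension only.
* Relative torque in deg-based units is internally consistent but not
  comparable with dynamometer newton-metres.
* The eleven-marker model fixes the knee triplet to D–C–B (see above).
* Timing gates for sprints are virtual marker-crossing planes; hardware
  gate latencies are out of scope, and the 5 m interval is measured on the
  sacrum trajectory.
* The genetics layer is single-locus candidate-gene analysis: no kinship
  correction, imputation or genome-wide machinery.
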