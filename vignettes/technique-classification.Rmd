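---
title: "Rule-based sub-technique classification from arm and ski IMUs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based sub-technique classification from arm and ski IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcski)
```

## The problem and the modelling idea

Classical cross-country skiing is built from a small repertoire of cyclic
sub-techniques — diagonal stride (DIA), double poling (DP), double poling
with a kick (DK), herringbone (HRB), and the rotational-kick turn moves
(DPrK, rK). `xcski` classifies these from four body-worn inertial sensors
(left/right wrist, left/right ski) by a *mechanism-based* construction:
first estimate a vector of interpretable motion components per sample, then
apply boolean decision functions whose thresholds are explicit, physically
meaningful tolerance parameters. The decision sets are pairwise disjoint by
construction, so every sample receives exactly one label; anything not
matching a definition falls into the catch-all `noTech` class (tucking,
standing, non-repetitive motion).

Two assumptions underlie the whole chain:

* the athlete is performing classical-style skiing (skating styles, running
  and other look-alike activities are outside the decision functions'
  domain and will be mislabelled rather than rejected);
* all streams are time-synchronous and expressed in a common athlete body
  frame — x vertical, y lateral, z longitudinal. `preprocess_session()`
  establishes the common 20 Hz clock, and `align_ski_sensor()` removes
  ski-sensor mounting tilt using the session-mean specific force
  (zero average horizontal acceleration over a full activity).

## Motion components

Over a centered sliding window Δt the estimators compute, per sample:

| component | definition | units |
|---|---|---|
| `armCorr` | windowed Pearson correlation of left/right arm lateral-axis angular rate | – |
| `armMo` | σ²(A_left) + σ²(A_right), windowed variances of the same rates | (deg/s)² |
| `legMoS` | σ²(angDiff_θ), the left-minus-right leg angle difference about the lateral axis | deg² |
| `legMoST` | legMoS + σ²(angDiff_ψ), adding the vertical axis | deg² |
| `kickRot` | σ(angDiff_ψ) / σ(angDiff_θ) | – |
| `eψ_ski` | (φ_L − φ_R)(θ_L + θ_R) from gravity-based ski roll/pitch | rad² |

Leg angles come from the ski gyros: band-pass filter the angular rate,
integrate, remove the mean (`integrate_debias()`), difference left minus
right. The relative-angle route deliberately avoids absolute attitude
estimation for the legs; only the *herringbone* component needs absolute
angles, and those come from the accelerometer gravity component after a
moving average (`roll_pitch_estimate()`), which is valid exactly because
only the low-frequency part matters there. No gyro/accelerometer fusion
observer is used — it would not improve a low-pass estimate, and yaw is
unobservable without a magnetometer anyway.

`eψ_ski` is signed on purpose: a roll split with *uphill* pitch (skis edged
apart while climbing) is positive; turning or skating downhill makes it
negative, so a positive tolerance confines HRB to uphill terrain. The
`leg_lateral_distance()` helper maps a roll split to an inter-ski distance
in metres and is the physical aid for choosing `tol_epsi`.

## Parameters

Defaults (all overridable via `ski_tolerances()` / `load_tolerances()`):

* **Windows/filters**: Δt = 1.3 s (just above one technique cycle at
  typical race cadences of 0.6–1.2 cycles/s), Δt_skiOri = 2.5 s (long
  enough to average out cycle dynamics from the gravity estimate),
  fs = 20 /s, band 0.3–3 /s (brackets the cadence range; DC and sensor
  drift below, vibration above).
* **Decision tolerances**: tol_armPole = 0.4, tol_armDiagHrb = −0.3,
  tol_armDiagD = −0.4, tol_armMo = 10⁴ (deg/s)², tol_legMoS = 1.5² deg²,
  tol_legMoST = 9² deg², tol_kickRot = 2, tol_eψ = 0.06 rad².
  The DIA arm-correlation bound is stricter than the HRB bound
  (`tol_armDiagD < tol_armDiagHrb`, enforced as a configuration invariant)
  because the herringbone arm swing is less anti-synchronized than the
  diagonal stride. The large gap between tol_armMo and the leg tolerances
  reflects sensor placement: wrist sensors see the arm swing directly,
  while ski-mounted sensors see leg motion only through the binding.

Units are a calibrated convention: gyro rates in deg/s and integrated limb
angles in degrees (matching the magnitudes of the leg/arm tolerances),
while ski roll/pitch and `tol_epsi` are in radians/rad², since the
herringbone estimator is defined on radian angles. Both are stated in the
manifest and enforced by the readers.

## The decision layer

`decision_functions()` evaluates, with *strict* inequalities exactly as the
tolerances are defined:

```
poling   = armMo > tol_armMo ∧ armCorr > tol_armPole
diagonal = armMo > tol_armMo ∧ legMoS > tol_legMoS ∧ armCorr < tol_armDiagHrb
HRB  = diagonal ∧ eψ_ski > tol_eψ
DIA  = diagonal ∧ ¬HRB ∧ armCorr < tol_armDiagD
DPrK = poling ∧ kickRot > tol_kickRot ∧ legMoST > tol_legMoST
DK   = poling ∧ legMoS > tol_legMoS ∧ ¬DPrK
DP   = poling ∧ legMoST < tol_legMoST ∧ legMoS < tol_legMoS
rK   = kickRot > tol_kickRot ∧ armMo < tol_armMo ∧ legMoST > tol_legMoST
noTech = none of the above
```

Design choices made where the construction was genuinely open:

* The herringbone/diagonal super-class uses the *refined* formulation that
  includes a leg-motion gate and the dedicated HRB correlation bound, with
  `eψ_ski` replacing the kick-direction and ski-yaw components (no
  magnetometer yaw is available). The earlier, coarser variant without the
  leg gate is kept only as the `tol_armDiag` record in the tolerance set.
* The leg gate reads `legMoS` (sagittal), since diagonal-type legwork is
  sagittal-dominant; `leg_gate = "legMoST"` is exposed for the alternative
  reading.
* `armMo` is the printed *sum of variances*, not its square root;
  tol_armMo = 10⁴ is interpreted on that scale (150 deg/s arms give
  2·150²/2 = 22 500).
* Values exactly equal to a tolerance deterministically fail the strict
  comparison; the boundary behaviour is tested.
* A duplicated leg-motion clause in the DK definition is treated as a
  single condition.

`check_disjointness()` verifies uniqueness exhaustively on a factorial grid
that brackets every tolerance (below, ±ε, above), and accepts an
alternative rule set so broken variants can be shown to fail.

## Numerical choices

* **Band-pass**: zero-phase (forward–backward) 2nd-order Butterworth
  high-pass then low-pass, hand-built biquads. No filter family is imposed
  by the method itself; zero phase matters because phase distortion would
  corrupt both the correlation estimator and the cycle landmarks.
  Forward–backward application squares the magnitude response, so the
  effective attenuation at 8 Hz (fs = 20) is below 1%.
* **Windows** are centered and truncated at the record boundaries;
  statistics are taken over the samples actually present and divided by
  that count (the biased-variance convention, matching the sample-count
  normalization fr·Δt of the estimator definitions). Samples whose window
  was truncated carry an `edge` flag and are labelled `noTech` by
  `classify_series()`.
* **Integration** is cumulative-trapezoid; the bias removal subtracts the
  mean over the full processed segment, as defined.
* **Zero-variance windows**: `armCorr` is 0 when either arm's windowed
  variance is < 1e-12 — such samples are only classifiable through the
  energy gates, which is the intended behaviour for quiescent phases.
  `kickRot` is capped at 10³ when the sagittal deviation vanishes; the
  classification outcome is unaffected because the rotational-kick classes
  also require leg motion above tolerance.
* **Ski alignment** uses the minimal rotation taking the session-mean
  accelerometer vector onto the negative vertical axis (its axis is
  horizontal, so gravity-frame yaw is untouched); it is idempotent and
  errors on near-zero mean specific force.
* **Cycle landmarks**: "left arm extended all the way behind the body" is
  a visual definition; it is realized as maxima of the band-passed,
  integrated left-arm lateral angle, with peaks required to reach 20% of a
  local (5 s sliding RMS) amplitude envelope and to be ≥ 0.33 s apart (the
  half-cycle floor). The local envelope, rather than a global one, keeps
  low-amplitude techniques (rK) segmentable in mixed sessions. This is one
  realization and is replaceable — any interval set can be fed to
  `cycle_majority_label()`.
* **Majority ties** in a cycle go to the label that occurs earliest in the
  cycle: deterministic and order-stable.
* **Cycle matching** between independently segmented predicted and
  reference cycles (needed because our boundaries are signal landmarks, not
  expert marks) assigns each predicted cycle to the reference cycle of
  maximal temporal overlap and excludes, but counts, cycles under 50%
  overlap.
* **Arm frequency** is the inverse of the first autocorrelation peak
  ≥ 0.3 in the 0.33–10 s lag range, averaged over the arms; below the
  significance floor the estimate is `NA` (absent techniques report no
  frequency).

## The synthetic generator: what a green test establishes

`technique_motif()` / `generate_session()` emulate each technique's
*defining* kinematics with single-harmonic sinusoids: anti-phase
(DIA/HRB) or in-phase (DP/DK/DPrK) arm angular rates of 180 deg/s
amplitude; sagittal ski angles of 6 deg amplitude (two-leg alternation for
diagonal-type techniques, single-leg kicks for the poling-with-kick
family); 18 deg vertical-axis rotation for the rotational kicks; an HRB
arm correlation of −0.45 (between the DIA and HRB bounds, reflecting the
less anti-synchronized herringbone swing); a 0.35 rad roll split on a
0.15 rad incline for HRB (eψ_ski = 0.105 > 0.06); cycle frequencies of
0.77/0.70/0.65/0.75/0.55/1.0 cycles/s for DIA/DP/DK/DPrK/rK/HRB; and
independent Gaussian noise of 5 deg/s and 0.3 m/s² per channel. Ski
accelerometers are generated through the same gravity forward model the
estimator inverts, including the cycle-frequency pitch oscillation from the
leg motion. Segments are joined with 1 s half-cosine cross-fades; samples
and cycles touching a junction are flagged as transitions and excluded from
accuracy accounting, mirroring how expert-labelled transition cycles are
treated separately.

The sagittal amplitudes for ski-mounted sensors are not derivable from
first principles (the ski-to-leg mapping through the binding is nonlinear);
the 6/18 deg defaults were chosen once to clear the leg tolerances with a
wide margin, as real ski signals demonstrably do, and are exposed in the
motif. At generation time every clean motif is checked against its
technique's defining inequalities with a 20% margin, and an impossible
motif (say, DP with strong leg motion) errors with the violated inequality.

A green end-to-end test therefore establishes that the estimator chain
inverts the generator's construction and that the decision layer implements
its algebra — it does *not* establish field accuracy. Real data differ in
multi-harmonic limb trajectories, stride-to-stride variability, ski
vibration and impact transients, imperfect synchronization and athlete
idiosyncrasy; the published field validation of this method family rests on
expert-labelled recordings that are not redistributable.

## Known limitations

* Kick *direction* (which leg kicks, from ski accelerations) is not
  estimated; the component is defined but unpopulated, and DK is classified
  independently of the kicking leg.
* Filter and integration transients extend ~4 s from record boundaries —
  longer than the formal edge flag of the sliding windows; with the default
  amplitudes the tolerance margins absorb this, but very short records
  should be treated with care.
* The disjointness guarantee is conditional on the tolerance invariants
  (e.g. `tol_armDiagD < tol_armDiagHrb`, enforced at construction); the
  completeness guarantee (`noTech` as complement) is unconditional.
* Technique *quality* is not assessed: both good and poor execution
  classify alike as long as the tolerances are met. Tightening tolerances
  shrinks every technique set toward `noTech`, which can be used
  deliberately as a "distinct-execution" filter.
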