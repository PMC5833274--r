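---
title: "Methods: portal-placement biomechanics and the virtual haptic device"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: portal-placement biomechanics and the virtual haptic device}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(portalsim)
```

## The problem

Creating the posterior portal is the first manual skill of shoulder
arthroscopy: the surgeon pushes a blunt trocar through the soft spot between
the infraspinatus and teres minor until the joint capsule gives way. The
forces involved — how stiffly the tissue resists and how hard the final
puncture is — are exactly what a haptic training simulator must reproduce,
and they can only be measured in the operating room. `portalsim` implements
the complete quantitative chain for this problem: a synthetic stand-in for
the operating-room recordings, the signal processing that turns raw force
and motion-capture streams into mechanical parameters, the cohort
statistics, the friction characterization of a 1-DOF cable-driven
force-feedback device, and a software model of that device validated by
replication R².

## The measurement model

A trial is a pair of synchronous 100 Hz streams: the axial force on the
trocar handle and the 3-D positions of two optical markers fixed to the
trocar shaft, plus three event timestamps (start of the procedure, puncture,
end). Three phases follow from the events: preparation (Phase I), loading
from the set point to puncture (Phase II), and the post-puncture state
(Phase III).

The capsule is modeled as linear-elastic up to rupture — Hooke's law

$$F(t) = k\,x(t),$$

with $x$ the travel distance of the instrument along its own shaft. Travel
distance is computed from the markers as the cumulative sum of per-frame
midpoint displacements projected onto the instantaneous shaft axis
(`compute_travel_distance()`): with markers $m_1, m_2$ the axis is
$u_i = (m_2 - m_1)/\lVert m_2 - m_1\rVert$ and the increment is
$u_i \cdot \Delta p_i$. This projection is invariant under rigid motion of
the camera frame (a property test checks this). The per-frame reading of the
"sum of dot products" is used because the projection point (we use the
marker midpoint) travels a straight line in the dominant use case, where the
per-frame and net-displacement readings coincide; for curved paths they
differ, and only the per-frame version is implemented as the default
behavior.

Stiffness is estimated by **through-origin least squares** over Phase II,
$\hat k = \sum x_iF_i / \sum x_i^2$, because the model has no offset: force
and displacement are both zero at the set point, and displacement is
re-zeroed there. An intercept variant exists (`intercept = TRUE`) purely as
a lack-of-fit diagnostic, and `residual_rms` exposes deviation from
linearity. The puncture force is the maximum of the filtered force over the
closed Phase-II window, with ties going to the last occurrence; on monotone
loading this equals the force at the end of Phase II but is robust to filter
ripple.

## Filtering

Force and travel are low-pass filtered at 5 Hz (4th-order Butterworth,
applied forward and backward so the net phase is zero and event timing is
preserved). Two implementation details matter:

* **Edge handling.** The signal is detrended by the straight line through
  its endpoints, extended by odd reflection (about two reel lengths of
  padding), filtered both ways, and re-trended. Constants and straight
  lines therefore pass exactly, which is what makes the noiseless
  round-trip (generate → preprocess → estimate) exact to machine precision
  rather than merely close.
* **Per-phase filtering.** `process_trial()` filters each phase segment
  separately. The event timestamps mark genuine discontinuities — first
  contact and the puncture collapse — and a filter run across the puncture
  step would smear roughly 10 N of the drop back into the last 0.1 s of
  Phase II, biasing both the peak force and the fit. Within Phase II the
  signal is smooth and the segment filter is transparent. Whole-trace
  filtering remains available (`by_phase = FALSE`) and is what the
  automatic puncture detector uses, since it runs precisely when no
  timestamps exist.

`detect_puncture_auto()` is a convenience for timestampless recordings: it
fires at the earliest sample where force has dropped by more than 25% of
its running maximum, provided the maximum exceeds 10 N (so Phase-I contact
jitter, bounded at 5 N, cannot trigger) and was attained within the last
0.5 s. With the generator's post-puncture decay (time constant 0.1 s) a 25%
drop occurs about 29 ms after puncture, so detections land well within one
filter width of the true event.

## The synthetic data

No public recordings exist for this procedure, so the generator *is* the
data source, and its defaults are the study conditions:

* Per-patient $(k, F_{\max})$ are drawn from normal distributions truncated
  to the observed ranges, with mean (SD) of 2560.82 (252.92) N/m and
  66.46 (10.76) N and ranges 2301.04–2889.70 N/m and 43.08–79.58 N.
* Sensor noise: the instruments' stated accuracies (1 N, 1 mm) are read
  conservatively as 3σ bounds, giving Gaussian i.i.d. noise with
  σ_F = 1/3 N and σ_x = 1/3 mm per coordinate.
* Phase II loads at a nominal 0.01 m/s (the protocol does not constrain
  insertion speed; 10 mm/s gives a ~2.6 s loading interval and ~26 mm of
  travel, plausible for a deliberate trocar advance). The generator snaps
  the event timestamps to the sampling grid and adjusts the effective speed
  by less than half a sample period so the noiseless ramp peaks at exactly
  $F_{\max}$ on a grid sample — otherwise "recovers the input exactly"
  would be ill-posed on sampled data.
* Phase I force is uniform jitter in [0, 5] N (trocar seating); Phase III
  decays exponentially to the residual force with τ = 0.1 s. Neither phase
  is characterized by the measurement protocol; both are free parameters
  and nothing downstream depends on their exact shape.
* Markers sit 80 mm apart on the shaft axis; insertion is pure translation
  along the axis, with an optional off-axis sinusoid to exercise the
  projection.
* Marker dropout: with probability 0.5 (five of ten patients lost position
  data in the reference cohort) a trial receives a contiguous 0.5 s marker
  gap mid-Phase-II. Gaps of ≤ 5 samples are repaired by linear
  interpolation; a Phase-II gap longer than 0.2 s flags the trial
  position-invalid, and stiffness is then not estimated for that patient.
  One random patient per cohort carries a synovitis flag and is excluded
  from cohort statistics, mirroring the frozen-shoulder exclusion rule.

What the generator does **not** emulate: viscoelastic or rate-dependent
tissue response, curvature of the insertion path, marker mislabeling,
correlated (non-white) sensor noise, and surgeon-specific speed profiles.
Passing tests therefore demonstrate that the pipeline is correct on the
linear-elastic, straight-path model it assumes — not that real tissue obeys
that model.

## Cohort statistics

`summarize_cohort()` excludes flagged patients (synovitis, failed passive
ROM screen) before computing mean, sample SD (n−1; the convention is not
dictated by the source material, so the standard inferential choice is
used), and range. Puncture force is summarized over all included patients;
stiffness only over the position-valid subset. The summary is
permutation-invariant and is checked against an independently coded
streaming mean/SD oracle.

## Friction characterization

The bench model: the handle is pushed to speed $v_0$ and released; a
constant friction force dissipates the kinetic energy of the handle plus,
when the cable is attached, the rotational energy of the cable reel
($\omega_0 = v_0/r$):

$$F_f = \frac{\tfrac12 m v_0^2 + \tfrac12 I (v_0/r)^2}{d}.$$

Total friction is the mean over attached pushes, guide friction the mean
over detached pushes, and the cable's own contribution is their difference
— identically, by construction. The perceptual check divides total friction
by the mean puncture force and requires the ratio to stay strictly below
the 6% just-noticeable-difference bound.

## The virtual haptic device

The device model is a discrete-time 1-DOF impedance law at 100 Hz:

1. the commanded tip position is quantized to the encoder grid
   (resolution $2\pi r / (2048 \times 4) \approx 15.3\,\mu m$ with the
   default 20 mm reel — the reel radius is not part of the published device
   table and is configurable; quadrature ×4 decoding is assumed);
2. penetration past the capsule surface commands $F = k\delta$;
3. the tick the commanded force reaches $F_{\max}$, the force releases to
   zero *within that tick* and stays released (the flag is monotone);
4. the force is clamped to the 137.1 N device maximum — after the release
   logic, so saturation can never mask a puncture.

The law is static: no inertia, friction or rate terms (those belong to the
bench characterization, not the rendering law), so the force–displacement
curve is invariant to loop rate and insertion speed, which is tested by
running the same spatial trajectory at two rates. Quantization floors
toward −∞, making it a deterministic idempotent projection.

`validate_replication()` renders a standard 5 cm, 0.01 m/s insertion for a
set of capsule targets spanning the in vivo ranges, takes the maximum
rendered force as the reproduced puncture force and refits the rendered
force against the *true* handle penetration (the device only sees the
quantized tip) for the reproduced stiffness, then scores both against the
targets with $R^2 = 1 - SS_{res}/SS_{tot}$. Because the software device is
ideal apart from quantization and discrete ticks, both scores land near
0.9997–1.0, comfortably above the physical device's published 0.998 (force)
and 0.902 (stiffness) — those bounds reflect motor, cable and sensor
imperfections that are deliberately out of scope here. One subtlety: with
same-tick release the rendered peak is always one trajectory step short of
the threshold, so the force score is a hair below 1 even with quantization
disabled; stiffness replication without quantization is exact.

## Numerical choices and degenerate inputs

* Zero-length Phase II, all-invalid displacement, empty fit windows,
  constant R² targets, non-positive travel distances, and cutoffs at or
  above Nyquist are all rejected with typed errors rather than silently
  propagated.
* Peak-force ties resolve to the last occurrence; phase boundaries belong
  to Phase II; a 1 ns tolerance at the boundaries absorbs float jitter
  from serialized timestamps.
* All internal quantities are SI (N, m, s); conversion happens only at
  plotting and reporting boundaries (mm in figures).
* Seeds: every stochastic entry point takes an explicit seed; cohort and
  pipeline runs derive per-trial child seeds from the master seed, so any
  subset of a run is reproducible in isolation.

## Problem sizes

The shipped tests and the acceptance script use the cohort sizes of the
reference study (9–10 patients, 10 bench pushes per condition, 10
replication targets) and Monte-Carlo loops of 200–500 trials for the
detector-accuracy and estimator-bias properties; a full suite runs in well
under a minute on one core. These sizes were chosen because the standard
errors they yield are already an order of magnitude tighter than the
effects being checked.

## Known limitations

* The capsule is a point contact on a 1-D axis; no anatomy, no capsule
  curvature, no multi-DOF kinematics.
* The linear-elastic model holds only to puncture; real capsules show
  rate dependence the model ignores by design.
* The friction estimator assumes constant friction during deceleration; a
  speed-dependent component would bias it.
* The replication validation scores the *rendering law*, not a physical
  device: it bounds what the published hardware numbers could be, it does
  not reproduce their imperfections.
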