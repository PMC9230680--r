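---
title: "Force transmission in a ring external fixator: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Force transmission in a ring external fixator: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilizarov)
```

## The problem

During distraction osteogenesis with an Ilizarov-type circular fixator, two
adjustable rods are lengthened a small amount each day, pulling the cut bone
ends apart across the osteotomy while two passive support rods share the
frame load. The tension actually delivered to the regenerating bone is what
drives healing, but it cannot be prescribed directly: part of the rod force
is lost to pre-tightening of the frame, friction, and imperfect rod
synchrony. This package models the force path from the rods to the bone end
and quantifies the loss as a transfer efficiency.

The reference configuration is a sheep-tibia bench experiment: two 190 mm
rings, four rods, 2.5 mm Kirschner wires, a 6.85 degree initial varus
deformity corrected to zero over 10 periods at 1 mm of lengthening per
period. On the bench each clinical day is compressed to a 24 s period
consisting of a correction stage and a stay stage.

## The screw model

The fixator's motion is described with two screws: a prismatic twist
$\xi_1 = (0,0,0;\,0,0,1)$ for rod lengthening $\Delta l$ and a revolute
twist $\xi_2$ (unit axis $x$, through the hinge at $(0,0,l)$) for the hinge
angle $\theta$. Their matrix exponentials have the closed forms implemented
in `exp_twist()`; the fixator posture is the product of exponentials
`pose_poe()`:

$$
p(\theta) \;=\; e^{\Delta l\,\hat\xi_1}\, e^{\theta\,\hat\xi_2}\, p(0),
\qquad p(0) = \bigl[\,I \;\; (0, l, 0)^T\,\bigr].
$$

The two-exponential product (before the $p(0)$ factor) has rotation
$R_x(\theta)$ and translation $(0,\; l\sin\theta,\; \Delta l +
l(1-\cos\theta))$. Because multiplying by $p(0)$ additionally carries the
$(0, l, 0)$ offset through the rotation, and downstream uses differ on which
pose is wanted, `pose_poe()` exposes both (`include_p0`). This was a
genuinely open design point; the package treats the raw product as the hinge
attitude and the full product as the bone-end pose.

Statics are dual to kinematics: each rod's axial force is a wrench
$F = (f; \tau)$ along the rod axis, and the hinge carries it into the
bone-end frame by the rotation $R_x(\theta)$ (`rotate_wrench()`). Summing
the axial components of the four rotated rod wrenches gives the theoretical
bone-end tension

$$
F_{z,2t} = (F_1 + F_2 + F_3 + F_4)\cos\theta .
$$

`theoretical_tension()` literally performs the per-rod rotation and
summation; the $\cos\theta$ form is used as an independent oracle in the
tests, not as the implementation.

## Transfer efficiency and its orientation

The efficiency is defined here as

$$
\eta_z = \frac{F_{z,2m}}{F_{z,2t}},
$$

measured over theoretical, so that a lossless frame gives $\eta_z = 1$ and
the observed steady state sits near 0.5. Some write-ups print the inverted
ratio; with the numbers at hand that ratio exceeds one (the theoretical
tension is roughly twice the measured), which is incompatible with calling
the quantity a transfer *efficiency* of about 50%. The package follows the
semantics, and `transfer_efficiency()`'s documentation notes the printed
alternative. The analyzer treats $\eta \ge 1.2$ as an error and warns above
1, since a measured tension above the theoretical bound indicates a unit or
configuration mistake rather than physics.

## Parameters that matter

* **Support fraction `kappa`** (dimensionless, default 0.4). The support-rod
  forces are never measured; they are modelled as $F_3 = \kappa F_1$,
  $F_4 = \kappa F_2$. The default is calibrated once so the final-period
  total rod load $(F_1 + F_2)(1 + \kappa)$ reproduces the observed total of
  about 300 N; with the bench table it gives 304.0 N. It is configurable
  everywhere it appears.
* **Angle schedule.** The hinge angle is taken linear in the correction
  index: $\theta(k) = \theta_0 (1 - k/n)$, from 6.85 degrees at $k = 0$ to
  zero at $k = n$, matching a uniformly applied correction. Degrees at every
  user-facing interface; radians internally, converted only at the boundary.
* **Plateau window** (default periods 4 to $n$). The first two to three
  periods pre-tighten the frame and transmit little tension; the plateau
  mean deliberately excludes them.
* **Hinge offsets `a`, `b`** (20 and 30 mm) and **rod length `l`** (150 mm)
  are carried in the geometry for the pose and frame modules but do not
  enter the tension formula, which is a pure rotation. They are
  order-of-magnitude bench conventions, not measured values.

Running the analysis on the packaged bench table:

```{r}
report <- analyze_series(load_table3())
report
```

## The synthetic generator

`generate_force_series()` emulates the bench measurement so the whole
pipeline is testable without hardware. What it reproduces:

* per-period **correction ramps** for $F_1, F_2$: linear rise to a 10%
  overshoot at mid-stage, linear settle onto the period-end anchor — the
  minimal shape consistent with "rises, peaks, settles" without inventing
  dynamics. Default anchors are the measured bench table, so a zero-noise
  series ends every period exactly on it;
* **stay stages** flat up to noise;
* **support forces** $F_3 = \kappa F_1$, $F_4 = \kappa F_2$ with the
  opposite intra-correction trend (dip, then recover), as observed;
* a **pre-tightening deficit**: the transmitted tension is
  $\eta_{\mathrm{target}} \sum F_i \cos\theta$ minus a deficit (default 5 N)
  that decays linearly to zero over the first 2 periods, mimicking the early
  window in which the rods mostly take up play;
* small zero-mean transverse tensions $F_{x,2m}, F_{y,2m}$, additive
  Gaussian noise (default sd 1 N) on every channel, 10 Hz sampling, and a
  mandatory seed — identical seeds give identical series, and the caller's
  RNG state is restored.

Stage durations default to 12 s correction + 12 s stay within the 24 s
period; the split is a convention (only the period ends are anchored by
data). What the generator does **not** emulate: sensor drift, six-axis
cross-talk, viscoelastic relaxation of bone, and any intra-stage force
detail beyond the ramp shape. Passing round-trip tests therefore show that
the analysis recovers what the generator encodes — not that real intra-stage
trajectories look like the synthetic ones.

```{r}
s <- generate_force_series(generator_config(noise_sd = 0))
attr(analyze_series(s), "plateau_mean_eta")   # recovers eta_target = 0.5
```

## Bone material mapping

CT gray values map linearly to apparent density,
$\rho = \rho_{\max} HU / HU_{\max}$, and density maps to elastic modulus by
class-specific power laws: $E = 2065\,\rho^{3.09}$ MPa for compact bone and
$E = 1904\,\rho^{1.64}$ MPa for cancellous bone, Poisson ratio 0.3 for both.
$HU_{\max} = 2000$ and $\rho_{\max} = 2\ \mathrm{g/cm^3}$ are calibration
conventions supplied by the user, not constants of the model. Gray values
outside $[0, HU_{\max}]$ are rejected rather than clamped, because the
linear law is only a positive proportionality. The two power laws cross near
$\rho = 0.946\ \mathrm{g/cm^3}$ (verified against a root-finding oracle in
the tests); the class is a user decision made upstream of this mapping, and
the linear HU law is applied globally rather than per class.

```{r}
material_table(c(500, 1000, 1500), bone_class = "compact")
```

## The frame surrogate

A voxel-accurate finite-element model of the frame and tibia is outside
this package's scope. In its place `solve_frame()` is an intentionally
small linear model whose every behaviour has a closed-form or symmetry
check: rigid rings (the moving ring keeps axial translation and two tilts
after small-displacement linearization), rods as axial springs, and each
pretensioned wire as a simply supported beam-string whose midspan
transverse stiffness is $k = 48EI/L^3 + 4T/L$. A wire crosses the bone
cortex twice, so its stiffness is split over two crossing points offset
from the ring centre; keeping all four crossing points is also what leaves
the ring's tilts constrained and the stiffness matrix positive definite.
The bone segment is a single axial node restrained by a gap spring standing
in for the regenerate/sensor. Default stiffnesses (rod $EA/L = 3.77 \times
10^4$ N/mm for a 6 mm steel rod of 150 mm; wire pretension 1000 N over a
190 mm span; gap 1000 N/mm) are documented conventions — the bench reports
no rod dimensions beyond the wire diameter.

Numerically, the tilt degrees of freedom (radians) are non-dimensionalized
by the ring radius before the rank check, so lever-arm scaling cannot mask
a genuinely unconstrained mode; singular systems are rejected with the
dominant free mode named. The surrogate reproduces directions, not
magnitudes: under the asymmetric final-period loads the wires on the
adjustable-rod side carry more than those on the support side, consistent
with the higher pinhole stresses seen there, but no stress fields are
computed.

## Numerical choices and degenerate inputs

* Rotation validity (orthogonality, unit determinant) is checked to 1e-10 —
  the closed forms are exact up to double-precision rounding.
* Revolute twists must carry a unit axis; the magnitude lives entirely in
  the angle. Non-unit axes are rejected, not normalized silently.
* The matrix-exponential oracle in the tests is a 30-term truncated series,
  independent of the closed forms it checks, with agreement required to
  1e-9 over 100 random unit twists.
* Empty force tables, missing columns, non-numeric cells and unknown
  configuration keys are hard errors with the offending column, line or key
  named; out-of-range gray values and nonpositive theoretical tensions are
  rejected.
* The generator builds its time axis from integer sample indices, so stage
  boundaries are exact regardless of sample rate.

## Problem sizes

The test suite and the reproduction script run the 10-period bench table
(10 rows), synthetic series of 2,400 samples (10 periods at 24 s, 10 Hz),
100-twist oracle sweeps, 20 zero-noise recovery configurations and 50 noisy
seeds; these sizes make every check a desk-scale computation while keeping
the Monte-Carlo error of the noisy-recovery check well below the 0.01
recovery tolerance.

## Known limitations

* The support fraction is a single constant; the real load split varies
  with pre-tightening state and period.
* Only the axial tension is modelled; the transverse components are passed
  through for reporting but stay small and have no predictive model here.
* The frame surrogate is linear and rigid-ring; no contact, no stress
  concentrations, no wire slip.
* The packaged bench tables are period-end averages; intra-stage dynamics
  are reconstructed synthetically, not measured.
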