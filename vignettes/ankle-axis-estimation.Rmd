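---
title: "Estimating the talocrural and subtalar axes from draw-wire captures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the talocrural and subtalar axes from draw-wire captures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anklekin)
```

## The model

The ankle complex is approximated, as is standard in functional
biomechanics, by two fixed revolute axes: the talocrural (TC) axis between
tibia/fibula and talus, which dominates dorsiflexion and plantarflexion,
and the subtalar (ST) axis between talus and calcaneus, which dominates
inversion and eversion. Each axis is a line in the shank-fixed base frame,
written as a unit direction $\omega$ through a point $r$. The frame is
anatomical: the sagittal plane is $y = 0$, $z$ runs up the shank, the
origin $P_0$ sits on the shank axis, and all lengths are centimetres.

A revolute axis generates the twist $\xi = [\nu;\ \omega]$ with
$\nu = -\omega \times r$. A point $p_0$ attached to the foot platform
moves under the product of exponentials

$$ p(\theta_1, \theta_2) \;=\; e^{\hat\xi_{TC}\,\theta_1}\,
   e^{\hat\xi_{ST}\,\theta_2}\, p_0 , $$

with the TC factor outermost; the order is part of the model and is locked
by a test against an independent homogeneous-matrix oracle. Rotations come
from the Rodrigues formula
$R = I + \Omega\sin\theta + \Omega^2(1-\cos\theta)$, and the screw
translation is $(I-R)(\omega\times\nu) + \omega\omega^\top\nu\,\theta$
(zero for revolute twists). Key assumptions: both axes are fixed in the
shank frame over the measured range of motion, the platform is rigid, and
motion is slow enough that frames can be treated quasi-statically.

Because the platform-centre surface $p(\theta_1, \theta_2)$ is a smooth
two-parameter chart, the package also exposes its first fundamental form
(`induced_metric()`) and geodesics of that metric (`geodesic_trace()`),
which model unforced ankle motion in chart coordinates.

## Default geometry and its parameters

All defaults are derived from body height $H$ (default 175 cm, an average
adult male) and a table of anthropometric means: offsets K = 1.2, L = 1.1,
O = 1.6, P = 1.0 cm between the palpable malleoli and the TC-axis points,
the TC→ST sagittal offset Q = 0.5 cm at 41° inclination (a 45° variant is
selectable), and the inter-malleolar ratio R = W/w = 0.54 that places the
TC sagittal intersection $r_1$ along the malleolar segment. Axis
orientations default to the anatomical means: the TC direction is $\hat z$
rotated −80° about $x$ then −6° about $z$; the ST direction is $\hat x$
rotated 41° about $y$ then 23° about $z$.

Derived scales: the origin-to-platform distance is
$d_m = 0.162\,H$ (28.35 cm at $H=175$). The platform circumradius defaults
to two thirds of the foot length, $r_p = \tfrac23 \cdot 0.152\,H$; a
height-proportional circumradius of $\tfrac23 H$ would exceed a metre and
is physically meaningless, so $r_p$ is deliberately tied to the foot and
remains a config override. The platform triangle uses vertex angles
(0°, 120°, −120°): that is the only layout in which the triangle is
equilateral and its centroid is the platform centre, both of which the
trilateration edge checks rely on; a 60° variant is available through
`platform_vertices(angles_deg=)`.

The malleolus markers have no published coordinates; the defaults
(MMP = (0.2, 3.4, −19.8), MLP = (−0.8, −3.6, −20.5) cm at $H=175$, scaled
with height) are anatomically plausible positions that put $r_1$ about
7 cm above the platform plane. They only seed the reference model — every
estimation result is compared against whatever model generated the data.

The seven sensor anchors (three for module A, two each for B and C) sit on
a plate 10 cm above the platform plane at radius $0.8\,r_p$ from the shank
axis, with module radius $r_m = 4$ cm. This reproduces rest wire lengths
of roughly 8–12 cm, the scale a wearable shank-mounted device exhibits,
and it keeps the noise amplification of the tetrahedron solver moderate:
the in-plane apex coordinates scale errors by (wire length)/(anchor
separation), so short wires and wide modules are strongly preferred.
Joint ranges default to ±15° per axis, the physiological envelope used for
workspace plots; a full ±180° torus is representable but flagged
non-physiological.

## Trilateration

Module A's vertex is solved in closed form: in a local orthonormal frame
of the anchor triangle, the two-circle intersection gives the in-plane
coordinates and the height is $\sqrt{l_1^2 - x^2 - y^2}$, with the sign
chosen by the mounting (`apex_side = "below"`). A negative radicand beyond
tolerance means inconsistent lengths and raises a classed error carrying
the radicand. Modules B and C reuse the same construction after rotating
their base triangle (two anchors plus the solved Ap) flat about the axis
$\widehat{n \times \hat z}$ through the first anchor — identical to
rotating about the anchor–anchor line when both anchors share a height, as
they do in the device — and rotating back.

Each of B and C has a mirror ambiguity. Three filters select the physical
pair: (i) candidates must lie on the same side of the module-A anchor
plane as Ap (the foot cannot pass through the sensor plate), (ii) the
solved triangle's winding must match the rest pose (a platform cannot flip
over), and (iii) the remaining free edge $|B_p - C_p|$ must match the
configured platform edge, ties broken toward lower $z$. Noiseless, the
solver inverts the forward model to ~1e−13 cm; under noise the edge check
doubles as a consistency gate (default tolerance 0.5 cm, configurable) and
`solve_capture()` drops gated frames with a summary warning. The platform
pose is recovered by SVD rigid alignment with the determinant forced to
+1, so reflections are never reported.

## Axis estimation

For each movement group the solved trajectories of A, B, C and the
platform centre PM are processed as:

1. **Plane direction.** The classical least-squares plane regresses $z$ on
   $(x, y, 1)$; its normal is $(a, b, -1)$ normalized. That
   parameterization amplifies noise by $1/|n_z|$, so planes tilted past
   ~60° fall back to total least squares (smallest singular vector of the
   centred points). By default the four trajectories of one movement share
   a single jointly fitted direction (`group_plane_normal()`): rotations
   about one axis produce parallel planes, and trajectories that pass
   close to the axis (small circles) carry almost no directional signal on
   their own — the joint fit lets the large-radius trajectories dominate.
   Per-trajectory normals remain available (`shared_normal = FALSE`).
2. **Circle.** Points are rotated so the plane normal becomes $\hat z$
   (Rodrigues rotation about $\hat n \times \hat k$; the antiparallel case
   uses a 180° turn about $x$), and the linearized circle equation
   $c_0 x + c_1 y + c_2 = x^2 + y^2$ is solved in least squares; the
   centre is rotated back. Arcs spanning under 5° warn about conditioning;
   the algebraic fit's radius bias on short arcs is covered by a seeded
   regression test.
3. **Aggregation.** Componentwise medians of centres and sign-aligned
   normals (flipped to a common hemisphere, then oriented to non-positive
   $y$, the mediolateral convention). Medians, not means, are used
   deliberately: they ignore one bad trajectory. The platform-centre
   trajectory participates in the median alongside A, B and C.
4. **Line output.** The aggregated axis is intersected with the sagittal
   plane at $d = -c_y/\omega_y$ (an error if the axis is parallel to it)
   and packed as Plücker coordinates $[\omega : r\times\omega]$, which
   satisfy $\omega\cdot m = 0$ to 1e−6 for every computed estimate.

The dorsiflexion/plantarflexion group is reported as the TC axis and the
inversion/eversion group as the ST axis — estimates are keyed by movement,
never by table position in any external data.

## The synthetic capture generator

`simulate_capture()` drives the forward chain: POE vertices → exact wire
lengths → i.i.d. Gaussian length noise (default σ = 0.05 cm, the scale of
caliper-vs-model discrepancies in bench calibration) → optional 10-bit ADC
round trip through the inverse calibration line → a capture log with
emulated relative-IMU channels for the jerk segmenter. Movement trials are
half-cosine sweeps of one joint across its range with the other held at
zero. Every stochastic path is reproducible from the seed alone; logs are
bitwise identical under a repeated seed.

`run_axis_experiment()` additionally passes the length channels through
the EWMA filter (α = 0.2) before solving — exactly what the acquisition
firmware does. On a slow continuous sweep the filter's group delay
displaces samples *along* the trajectory arc rather than off its plane, so
it suppresses noise without biasing the fitted axis.

What the generator does **not** emulate: skin-motion artefacts of the
marker placement, wire sag or tension-dependent stretch, cross-channel or
temporally correlated noise, axis migration with load, and anchor
calibration error. Passing tests therefore demonstrate the correctness and
noise behaviour of the *algorithms* under the stated error model, not the
field accuracy of a physical device.

## Numerical choices

- Degrees at every file/CLI/API boundary where ranges are configured;
  radians internally.
- Unit-axis checks at 1e−6; rotation orthonormality asserted at 1e−9.
- Trilateration radicand tolerance 1e−8 cm²; edge cross-check 0.5 cm for
  measured data (1e−6 is used in noiseless tests).
- Metric/geodesics: central differences with h = 1e−4 rad; fixed-step RK4
  (default 1000 steps); Christoffel symbols from finite differences of the
  metric; a path leaving the chart is truncated and flagged rather than
  extrapolated.
- Ill-posed inputs raise classed conditions (`anklekin_no_real_apex`,
  `anklekin_ambiguous_apex`, `anklekin_degenerate_geometry`, ...) so
  callers can distinguish impossible data from programming errors.

## Problem sizes

The shipped tests and the acceptance script use 25 frames per movement,
1000 random poses for the round-trip check, and 100 seeded replicates of
the noisy experiment — sizes at which the noise statistics are stable and
a full run stays interactive on a laptop. All of them are arguments, not
constants.

## Known limitations

- The estimator assumes pure single-axis trials; combined motions bias the
  circle fits (the device protocol enforces pure trials).
- Axis points along the axis direction are unobservable from circle fits
  alone; only the line (direction + any point, reported on the sagittal
  plane) is identified.
- The analytic solver uses exactly seven lengths; redundant-sensor fusion
  is out of scope.
- Calibration requires at least two distinct caliper points per sensor;
  a single pair determines only a scale through the origin.
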