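---
title: "Methods: geodesics in the position-orientation-curvature model of V1"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geodesics in the position-orientation-curvature model of V1}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurogeo)
```

## The model and its assumptions

The configuration space is $M = \mathbb{R}^2 \times SO(2) \times
\mathbb{R}$ with coordinates $q = (x, y, \theta, k)$: planar position
(length units), contour orientation (radians) and signed contour
curvature (inverse length).  A contour is traced by the control system

$$\dot q = u_1 X_1 + u_2 X_2, \qquad
X_1 = (\cos\theta, \sin\theta, k, 0), \quad X_2 = (0, 0, 0, 1),$$

so $u_1$ advances along the contour (the orientation turning at the rate
prescribed by the current curvature, $\dot\theta = k u_1$) and $u_2$
changes the curvature.  The cost is the sub-Riemannian length
$\int_0^T \sqrt{u_1^2 + u_2^2}\,dt$.  Completion of an occluded contour
is modelled as the planar projection of the length minimizer joining the
two boundary states read off the edges of the occlusion.

Assumptions worth making explicit:

* **Sign convention.** $k$ is the signed curvature of the planar
  projection relative to the direction of travel $\theta$: positive $k$
  bends the contour counter-clockwise when moving forward.  This is
  forced by $\dot\theta = k u_1$.
* **Angles are unwrapped.**  $\theta$ and the momentum angle $\alpha$
  are stored as plain reals and grow secularly along trajectories;
  wrapping modulo $2\pi$ happens only in comparisons
  (`state_equal()`), in the boundary-mismatch metric of the shooting
  solver, and in return-map plots.  This keeps every quantity smooth
  inside the integrator.
* **Both control signs are admissible.**  Nothing forbids $u_1 =
  \cos\alpha$ from changing sign along a normal extremal; the planar
  projection then has a cusp.  Whether a vision model should exclude
  such arcs is an open modelling question, so the solver permits them
  and reports a cusp count per solution instead of filtering.

The frame is completed by $X_3 = [X_1, X_2]$ and $X_4 = [X_1, X_3]$;
`frame_determinant()` and `growth_vector()` provide the numerical
controllability evidence (determinant identically 1; growth vector
$(2,3,4)$, an Engel-type structure).  Symbolic verification of the
bracket-generation hypotheses is out of scope: brackets are evaluated
from closed-form analytic Jacobians and cross-checked against finite
differences in the tests.

## Extremal systems

The maximum principle produces two families.

**Abnormal.**  The constraint analysis collapses abnormal optimal arcs
to pure curvature motions $\gamma(t) = (0, 0, 0, k_0 \pm t)$ under unit
speed.  `abnormal_state()` implements the closed form; the degenerate
covector $a = b = c = d = 0$ carries no momenta and is excluded by the
nontriviality condition.

**Normal.**  Three equivalent presentations are implemented, all used
by the tests as cross-oracles:

1. the 8-dimensional flow in frame momenta $h_i$ (`normal_rhs()`);
2. the 7-dimensional unit-speed form on $H = 1/2$ with $h_1 =
   \cos\alpha$, $h_2 = \sin\alpha$ (`natural_rhs()`), the default for
   all geodesic computations because length then equals elapsed time;
3. the decoupled 4-dimensional vertical block (`reduced_rhs()`).

The canonical Darboux form of the Hamiltonian system is carried by the
exact conversion maps `costate_to_h()` / `h_to_costate()` rather than by
a fourth right-hand side; the conserved canonical momenta $a, b$ are
evaluated through these maps.  $H$, $a$ and $b$ are three independent
first integrals in involution; the package deliberately claims no
formula for a fourth integral and provides numerical evidence for its
existence instead (below).

## Integration: tolerances and diagnostics

`integrate_arc()` delegates to `deSolve`'s `lsoda` (adaptive order and
step, per-component error control) with the right-hand sides in
compiled C; an `engine = "R"` switch evaluates the exported R formulas
instead and is tested to agree.  Defaults are `rtol = 1e-10`,
`atol = 1e-12`, with about 50 output samples per unit time.

* **Invariant monitoring.**  Every normal/natural arc carries the
  maximum absolute deviation of $H, a, b$ from their initial values over
  the sample grid; arcs whose $H$ drifts beyond `flag_tol = 1e-6` are
  flagged.  Drift is reported absolutely because $a$ or $b$ vanish
  identically on symmetric arcs.
* **Accuracy scaling.**  On arcs that escape to large $|k|$, evaluating
  $a, b$ multiplies the integrator's phase error in the secularly
  growing $\theta$ by factors of order $|k h_3|$, so absolute drift at
  fixed `rtol` grows with the dynamic range of the trajectory.  The
  conservation checks in the test suite therefore run at
  `rtol = 1e-13`, `atol = 1e-15`, where the worst drift over the seeded
  ensemble stays below the $10^{-8}$ bound they assert.  This is a
  property of floating-point quadrature, not of the flow: the integrals
  are exactly conserved.
* **Blow-up guard.**  Integration aborts once any state component
  exceeds $10^8$ in magnitude; the vertical flow is
  polynomial–trigonometric and such magnitudes indicate leaving the
  regime of interest, not physics.
* **Degenerate inputs.**  Non-finite initial states and non-positive
  tolerances are rejected up front; integrator failure reports the last
  valid time.

## Section crossings and the return-map experiment

`section_crossings()` integrates the reduced flow with `lsodar`'s root
detection on $k = 0$ and polishes each event with Newton steps on the
flow until $|k| < 10^{-10}$.  Crossing direction is the sign of $\dot k
= \sin\alpha$ at the event.

Two design choices deserve comment:

* **One-sided crossings by default.**  The closed-form periodic family
  $\alpha = \pi/2 + t h_3(0)$, $h_3 \equiv h_3(0)$, $h_4 \equiv 0$,
  $k = \sin(t h_3(0))/h_3(0)$ crosses $k = 0$ twice per period with
  opposite signs.  Recording only upward crossings ($\dot k > 0$) makes
  the periodic orbit a genuine fixed point of the return map, which is
  the cleanest operational statement of the experiment; `direction = 0`
  exposes two-sided crossings (twice as many points per orbit).
* **The period is measured, not assumed.**  The closed form has
  analytic period $2\pi/|h_3(0)|$; `periodic_orbit()` reports the first
  one-sided return time of the integrated flow and the tests assert it
  equals $2\pi$ at the reference member $h_3(0) = 1$ (to $10^{-6}$).
  Hard-coding a period formula is avoided on purpose: measuring the
  return keeps the experiment self-validating.

The five-orbit experiment (`fig_experiment()`) runs the reference
periodic seed $(\pi/2, 1, 0, 0)$ and four perturbed seeds
$(1.56, 0.94, 0.02)$, $(1.55, 1.06, 0.05)$, $(1.60, 1.14, 0.02)$,
$(1.58, 1.24, 0.01)$ on the section, with no randomness anywhere in the
headline run.  The default is $n = 200$ return-map iterations per orbit
— enough points for the closed-curve diagnostic below while keeping a
test-suite run in seconds; a single argument raises it (e.g.
`n = 1000`) with proportional runtime.

**Orbit thickness.**  "The orbit points fall on a closed curve" is
operationalized by `orbit_thickness()`: order the section points by
nearest-neighbour chaining, parameterize by normalized chord length,
least-squares fit a truncated Fourier series per coordinate, and report
RMS residual divided by cloud diameter.  The fit order is deliberately
low (8 harmonics): high enough to resolve the low-order shape of an
invariant curve, too rigid to chase independently scattered points.
Under this design the two regimes the tests calibrate — seeded uniform
clouds versus exact closed curves and the experiment's own orbits — sit
about two orders of magnitude apart, and the fixed threshold
`chaotic_thickness_threshold() = 0.05` lies between them.  The
diagnostic assumes the orbit closes a single loop; it is not meaningful
for island chains or genuinely chaotic layers, which the experiment's
seeds do not probe.

## The shooting solver

`solve_bvp()` works in the normalized frame: the roto-translation
carrying $q_0$ to $(0, 0, 0, k_0)$ is applied to both states
(`normalizing_transform()`), the unknowns are the initial momentum
$(\alpha_0, h_3(0), h_4(0))$ and the duration $T$, and the residual is
the endpoint mismatch with equal unit weights on $x$, $y$, $k$ and the
wrapped angular distance in $\theta$ (configurable; the model itself
provides no preferred metric on $M$, so transparent equal weights are
the default).

* **Multi-start.**  A deterministic grid
  ($\alpha_0$: 8 values over $[-3\pi/4, 3\pi/4]$; $h_3(0), h_4(0) \in
  \{-2, -0.5, 0, 0.5, 2\}$; $T \in d \cdot \{0.5, 1, 2, 4\}$ with $d$
  the planar distance plus $|\Delta k|$, floored at 0.1) is screened
  with a cheap low-tolerance integration; the 10 best starts are
  polished by Levenberg–Marquardt (`minpack.lm::nls.lm`, $T$ bounded
  below) and verified at full tolerance.  The grid spans both signs of
  $\cos\alpha$ because geodesics may need cusps.
* **Selection and deduplication.**  Converged solutions (weighted
  endpoint error below `tol = 1e-6`) are deduplicated by parameter
  distance ($10^{-3}$) and sorted by $T$; under unit speed $T$ is the
  length, so the first entry is the shortest known extremal.  Global
  minimality is not certified — conjugate/cut-point analysis is out of
  scope — and the returned list keeps the longer candidates visible.
* **Coincident boundary states** short-circuit to a trivial zero-length
  solution rather than entering the optimizer.

## Synthetic fixtures and boundary estimation

`synth_occluded()` emulates the occlusion setting: a smooth closed test
contour (circle, ellipse, or a seeded smooth polar perturbation; a
straight segment as the degenerate case) with a parameter interval
hidden, exact boundary states at the gap edges from the closed-form
tangent and curvature, and the hidden segment retained as ground truth.
Default geometry used across the tests: unit-order radii, sampling step
0.05 length units, occlusions up to a quarter turn.  What the generator
does **not** emulate about real images: pixel quantization, contrast
noise, junctions/T-occlusions, and the isophote-extraction step that
would produce polylines from rasters — passing tests demonstrate the
geodesic machinery on clean geometry, not robustness of a full vision
pipeline.

`estimate_boundary_data()` recovers a boundary state from samples: the
endpoint position, the tangent of an algebraic (Kåsa) circle fit over a
9-point end window, and its signed curvature (sign from bending
relative to travel direction; collinear windows fall back to a
total-least-squares line and $k = 0$).  Taking the tangent from the
fitted circle removes the one-sided chord bias, so orientation
converges at $O(\mathrm{step}^2)$; curvature is exact on circular arcs
and straight segments, while on curves of varying curvature the
one-sided window leaves an $O(\mathrm{step})$ endpoint bias (the fit
reports approximately the mean curvature over the window).  The window
length (9) trades noise averaging against that bias at the default
sampling step.

Rendering uses mathematical axes (y upward, unit aspect); the raster
device handles row order, so no coordinate flip appears in package
code.  Seeded randomness exists only in the spline fixture
coefficients (default seed 20211217); everything else is deterministic.

## Problem sizes used by the checks

The test suite and acceptance script use: 1000 sampled states for the
determinant identity, 100–200 states for bracket and rank checks, 20
seeded initial conditions over $t \in [0, 100]$ for conservation,
$n = 200$ return-map iterations per perturbed orbit, 20 forward-shot
geodesics with $T \in [0.5, 2]$ for the boundary-value round trip, and
quarter-circle occlusions of radius 2 for completion accuracy.  These
sizes were chosen so that each check is statistically meaningful for
the property it probes while a full run stays at desk scale.

## Known limitations

* Optimality of returned arcs is numerical (shortest converged
  extremal), never certified; cut loci and conjugate points are not
  computed.
* The fourth first integral is supported only by the return-map
  evidence; no claim is made beyond the diagnostic reported.
* The boundary-curvature estimator degrades to $O(\mathrm{step})$ on
  curves with rapidly varying curvature, and completion quality is
  correspondingly sensitive to boundary-curvature error.
* The multi-start grid is tuned to boundary pairs at unit-order scale
  (the normalized frame); problems rescaled by orders of magnitude
  should be rescaled to unit order first.
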