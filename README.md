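# neurogeo

Sub-Riemannian geodesics in the four-dimensional
position–orientation–curvature model of the primary visual cortex.

## The problem and who this is for

Neurons of the primary visual cortex V1 respond to the local orientation
of image contours, and experimental evidence points to curvature
detectors as well.  Including curvature in the classical
position–orientation (Petitot–Citti–Sarti) picture lifts a planar
contour into the four-dimensional configuration space

    M = R² × SO(2) × R  ∋  q = (x, y, θ, k),

where `(x, y)` is position, `θ` the contour orientation and `k` its
signed curvature.  Admissible motions in `M` are generated by two vector
fields — advancing along the contour and changing its curvature:

    q̇ = u₁X₁ + u₂X₂,
    X₁ = (cos θ, sin θ, k, 0),   X₂ = (0, 0, 0, 1),

and an occluded contour is completed by the planar projection of the
curve in `M` that joins the boundary data (position, orientation and
curvature at the two edges of the occlusion) with minimal
sub-Riemannian length ∫√(u₁² + u₂²) dt.

The package is a toolkit for researchers in neurogeometric vision
modelling, geometric control and sub-Riemannian geometry: it implements
the frame geometry of this Engel-type structure, the extremal flows of
the Pontryagin maximum principle (PMP), numerical integrability
experiments for the reduced flow, a shooting solver for two-point
geodesic boundary-value problems, and an occluded-contour completion
pipeline with synthetic ground-truth fixtures.

## The model in brief

* **Frame and controllability.**  The iterated brackets
  `X₃ = [X₁, X₂] = (0, 0, −1, 0)` and `X₄ = [X₁, X₃] = (−sin θ, cos θ, 0, 0)`
  complete `X₁, X₂` to a global frame with `det[X₁ X₂ X₃ X₄] ≡ 1`, so the
  distribution span(X₁, X₂) is bracket-generating with growth vector
  `(2, 3, 4)` — every pair of states is connected by an admissible curve.
  (`frame_field()`, `lie_bracket()`, `frame_determinant()`,
  `growth_vector()`.)

* **Extremals.**  PMP yields two families.  Abnormal optimal arcs are
  pure curvature motions `γ(t) = (0, 0, 0, k₀ ± t)` (`abnormal_state()`).
  Normal extremals follow a Hamiltonian flow in the frame momenta
  hᵢ = ⟨p, Xᵢ⟩; on the unit-speed level H = (h₁² + h₂²)/2 = 1/2 with
  h₁ = cos α, h₂ = sin α it reads

      ẋ = cos α cos θ,  ẏ = cos α sin θ,  θ̇ = k cos α,  k̇ = sin α,
      α̇ = h₃,  ḣ₃ = h₄ cos α,  ḣ₄ = −k cos α (k h₃ + cos α),

  with conserved `H` and translation momenta `a`, `b`
  (`natural_rhs()`, `first_integrals()`, `integrate_arc()`).

* **Integrability experiment.**  The vertical block `(α, h₃, h₄, k)`
  decouples (`reduced_rhs()`).  It has a closed-form periodic family
  through `(π/2, h₃(0), 0, 0)`, and the Poincaré return map to the
  section `k = 0` sends nearby seeds onto thin closed curves rather than
  scattering them — numerical evidence for a fourth independent first
  integral and hence Liouville integrability (`poincare_orbit()`,
  `fig_experiment()`, `orbit_thickness()`).  No closed form for the
  fourth integral is claimed.

* **Completion.**  `solve_bvp()` normalizes the boundary pair by the
  roto-translation symmetry and solves the shooting problem for
  `(α₀, h₃(0), h₄(0), T)` by screened multi-start Levenberg–Marquardt;
  `complete_contour()` returns the planar projection of the shortest
  converged arc.  Optimality is numerical, not certified.

## Worked example

```r
library(neurogeo)

## a geodesic between two states of M
sols <- solve_bvp(state_q(0, 0, 0, 0), state_q(1.2, 0.4, pi/3, 0.5))
sols
#> <bvp_solutions> 1 converged arc(s)
#>   [1] length 2.645155, endpoint error 1.31e-09, cusps 1
sols[[1]]$arc
#> <extremal_arc> system = natural, t in [0, 2.64515], 201 samples
#>   max |I(t) - I(0)|:  H 1.11e-16   a 3.19e-11   b 3.23e-11

## the periodic seed is a fixed point of the Poincaré return map
poincare_orbit(c(pi/2, 1, 0, 0), n = 3)
#>   iter         t     alpha alpha_mod h3 h4
#> 1    1  6.283185  7.853982  1.570796  1  0
#> 2    2 12.566371 14.137167  1.570796  1  0
#> 3    3 18.849556 20.420352  1.570796  1  0

## complete an occluded quarter of a circle of radius 2
ct <- synth_occluded(occlusion_spec("circle", list(radius = 2),
                                    gap = c(0, pi/2)))
cc <- complete_contour(ct$boundary_data$q0, ct$boundary_data$q1)
attr(cc, "duration")
#> [1] 3.137763
```

The solver's reported length is the sub-Riemannian length of the arc
(time under unit-speed parameterization); `cusps` counts sign changes of
the longitudinal control u₁ = cos α, i.e. cusps of the planar
projection.  The invariant drifts confirm the integration: `H` is held
to rounding and the translation momenta to ~1e-11 over the arc.  In the
completion example the geodesic of length 3.137763 bridges the gap
slightly more directly than the hidden circular arc (length π ≈
3.141593) and stays within 1.3 % of the radius of the true hidden
segment.

A command-line wrapper with the same functionality is installed as
`exec/neurogeo` (subcommands `simulate`, `poincare`, `complete`,
`synth`); see the header of that script for usage lines.

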