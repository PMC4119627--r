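---
title: "Modeling scalp soft-tissue expansion with scalpexp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling scalp soft-tissue expansion with scalpexp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A tissue expander is an inflatable implant placed under the scalp to grow new
skin for reconstructive surgery. Planning the procedure requires predicting
how much new surface area a given expander produces, whether that area covers
the defect once the flap contracts post-operatively, and what expander volume
(hence catalog size) is needed. `scalpexp` simulates the expansion as a
quasi-static large-deformation finite-element problem and post-processes the
per-step area and volume gains into exactly that planning arithmetic.

## Mechanical model

**Kinematics.** The scalp is modeled as a solid shell of uniform thickness
(default 3.4 mm, the structural thickness of adult scalp) meshed with linear
four-node tetrahedra, in a total-Lagrangian description: all quantities refer
to the undeformed reference configuration, and the strain measure is the
Green-Lagrange tensor \(E = (F^TF - I)/2\), which vanishes under rigid-body
motion. Within each element the strain splits into its linear and nonlinear
parts, \(E = B_L a_e + \tfrac12 A\theta\) with \(\theta = G a_e\) the
displacement-gradient vector; the strain variation is \(\delta E = (B_L +
B_N)\,\delta a_e\) with \(B_N = A G\). Because linear tetrahedra carry
constant strain, single-point integration is exact and every element integral
reduces to \(V_0\,(\cdot)\).

**Material.** Skin stiffens exponentially with stretch. The strain energy is

\[
W = \frac{a}{b}\Bigl(e^{(b/2)(I_1-3)} - 1\Bigr) \;-\; a\ln J \;+\;
\frac{\kappa}{2}(J-1)^2 ,
\]

with \(I_1\) the first invariant of \(C = I + 2E\) and \(J = \det F\). The
second Piola-Kirchhoff stress \(S = \partial W/\partial E\) and tangent
modulus \(D_T = \partial^2 W/\partial E\,\partial E\) are exact closed forms;
the test suite verifies the whole chain \(W \to S \to D_T \to K_T\) by central
finite differences at random states.

Three modeling notes:

* **Near-incompressibility** is enforced weakly by the \(\kappa\)-penalty.
  An exact constraint \(J = 1\) would require a mixed
  (pressure-displacement) formulation; a pure-displacement formulation with a
  stiff penalty (default \(\kappa = 100a\)) is the standard compromise and
  keeps the assembled tangent symmetric positive definite away from
  instabilities.
* **The \(-a \ln J\) term** makes the reference state stress-free. A pure
  \(I_1\)-exponential energy leaves a spurious hydrostatic stress \(aI\) at
  \(E = 0\), which would make an unloaded mesh push against its constraints;
  with the logarithmic term, \(S(0) = 0\) and the small-strain limit of the
  model (at \(b \to 0\)) is isotropic linear elasticity with shear modulus
  \(a\) and bulk-like modulus \(\kappa\).
* **Parameter values.** The defaults \(a = 0.1\) N/mm², \(b = 10\),
  \(\kappa = 100a\) are representative soft-tissue values chosen as package
  conventions; they are *not* measured scalp constants, and every analysis
  accepts a configured material. Units are mm, N and N/mm² (= MPa)
  throughout; pressures quoted clinically in N/cm² are converted once at the
  configuration boundary.

**Expander loading.** The expander is a virtual ellipsoid of fixed axis
ratio 1.53 : 1 : 1 (long axis along x) growing from volume zero at a
configured center point. A surface facet is *contacted* when its deformed
centroid lies inside the ellipsoid; contacted facets on the side of the shell
facing the expander receive the expander's fluid pressure (default
0.3 N/mm² = 30 N/cm²) as a follower load: each contacted triangle of deformed
area \(A\) and outward normal \(n\) contributes the force \(-pAn/3\) to each
of its nodes, recomputed from the deformed geometry at every iteration. The
facing restriction matters on a thin shell: the raw ellipsoid test also
catches the outer face directly above the expander, and pressurizing both
faces would cancel the load almost exactly. Contact is one-way and load-based
(no impenetrability constraint): the growing ellipsoid only decides *where*
pressure acts, which is a faithful reading of a fluid-filled expander pressing
on the galea.

Two details of the driver's load evaluation matter for convergence. First,
the contact decision is re-evaluated from the deformed surface at every
residual evaluation, which makes the load self-limiting exactly as the
physical device is: a facet that inflates past the ellipsoid surface stops
being pushed. (Freezing the contact set per load step instead lets the load
grow with the deforming area without bound and drives the solve into a
genuine pressure limit point.) Second, a sharp in/out contact switch makes
the residual discontinuous and the Newton loop chatter, so the driver tapers
the pressure weight linearly over a thin band of the squared ellipsoid
coordinate (default 0.2, a few millimetres of expander "shoulder" at clinical
sizes); the load Jacobian includes the taper term exactly.

**Equilibrium and solver.** Virtual work gives the balance
\(\varphi(a) = f_{int}(a) - R(a) = 0\) with \(f_{int} = \sum_e V_0 B^T S\)
scattered through the connectivity, and the consistent tangent
\(K_T = \sum_e V_0 (B^T D_T B + G^T M(S) G)\), where \(M(S)\) is the
geometric (stress) stiffness built from the current \(S\). Fixed degrees of
freedom are removed by symmetric elimination, so reactions remain recoverable
and prescribed non-zero boundary displacements are supported (used by the
patch test). A Newton iteration then proceeds exactly as the classical
scheme: a tangent predictor (identical to the linear-elastic predictor
\(K_L a = R\) when starting from rest, since \(S(0) = 0\)), followed by
corrections \(\Delta a = -K_T^{-1}\varphi\) until the residual norm on the
free degrees of freedom falls below a tolerance relative to the load norm
(default \(10^{-8}\), absolute floor \(10^{-10}\) N).

Three robustness layers wrap the plain iteration; all were driven by the
physics of pressure-loaded membranes rather than taste:

1. **Follower-load Jacobian.** The pressure load depends on the deformed
   surface, and at clinical pressure (three times the shear-modulus scale
   \(a\)) ignoring that dependence degrades Newton to a slow linear
   contraction. `pressure_nodal_load(..., jacobian = TRUE)` returns the exact
   load-stiffness \(\partial R/\partial u\) (a cross-product form per
   triangle), and the solver subtracts it from the iteration matrix. The
   assembled \(K_T\) itself remains the symmetric material + geometric
   tangent.
2. **Backtracking line search** that halves the update until the residual
   decreases and never accepts a state with inverted elements
   (\(\det F \le 0\)).
3. **Load ramping with a regularized fallback.** Each schedule step may be
   sub-incremented adaptively (hyperelastic equilibrium is path independent,
   so sub-stepping cannot change the converged state). Pressure-controlled
   inflation can pass a genuine limit point - the load grows with the
   contacted area while the membrane softens geometrically - where \(K_T -
   \partial R/\partial u\) becomes singular and plain Newton stalls. Because
   the exponential stiffening makes the total potential coercive, an
   equilibrium beyond the fold exists, and a Levenberg-regularized direction
   \((A^TA + \mu I)\,\Delta a = -A^T\varphi\) (engaged only when the line
   search collapses, relaxed back to plain Newton as full steps return)
   traverses it. Convergence is always judged on the true residual.

The solver is fully deterministic: no randomness enters anywhere.

## Pseudo-time and the eight-step schedule

The expansion is driven by a schedule of expander volumes (default: linear
growth to 200 mL over 8 steps). Steps are pure load increments - the model is
quasi-static and contains no mass or damping terms, so the "time" attached to
steps is bookkeeping only. Each step warm-starts from the previous converged
state; a failure at step \(k\) raises an error that carries the completed
steps.

## Post-processing and planning

Per-step reports record surface area \(S\) and volume \(V\) with their
per-step deltas and running sums; the delta/cumulative identities hold
exactly by construction. Both measures are exact (no sampling). When the
expander center is known - as in every `expand_scalp()` run - \(S\) is the
area of the skin-side surface (the expander-facing face is mirror tissue,
not new skin) and \(V\) adds the *pocket volume* opened between the
expander-facing surface and its reference position to the material volume.
The pocket is computed exactly: with the rim pinned, the deformed and
reference inner patches share their boundary, so the swept volume is the
difference of their signed cone-volume integrals. This is the quantity that
corresponds to the volume gain of a whole-head solid mesh and to the
implanted expander volume used for sizing; the material volume alone barely
changes (it drifts slightly with the \(\kappa\)-penalty compressibility) and
would say nothing about expander size. Without a center,
`build_step_reports()` falls back to total surface area and material volume. Strain histories of probe elements
report the Frobenius norm of \(E\) (the model does not single out a component,
so the norm is the natural scalar).

The sampling-based area estimator mirrors the clinical measurement workflow:
points are drawn area-uniformly on the surface (area-weighted facet choice,
uniform barycentric coordinates, seeded and reproducible), projected onto
their least-squares plane, triangulated with a 2D Delaunay triangulation
(`interp`), and the lifted 3D triangle areas accumulated. It is kept separate
from the exact per-facet area used in the step tables so that estimator error
never contaminates the mechanics results; on a 45-degree spherical cap sampled
at 5000 points the estimate is within 1% of the analytic \(2\pi R h\). The
estimator requires the patch to be a graph over its best-fit plane and raises
an error (advising the exact area instead) when a lifted triangle is nearly
perpendicular to that plane.

Planning arithmetic: expanded flaps contract after the expander is removed;
with shrinkage fraction \(s\) (default 0.30, the usual clinical allowance) the
new area must exceed the defect by \(1/(1-s)\), reported rounded half-up to
two decimals (0.30 gives 1.43, matching clinical reporting conventions). The
achieved factor is the simulated cumulative area gain over the defect area;
the required expander volume equals the cumulative volume gain (mm³ → mL),
and the recommendation is the smallest catalog size at least that large
(default catalog: 50-800 mL in 50 mL steps, a package convention).

## The synthetic fixture and what it does (not) show

`make_shell_patch()` builds a scalp-like spherical shell: mid-radius 80 mm
(adult head scale), thickness 3.4 mm, a 45-degree angular half-width, and a
16 x 16 x 1 cell grid split into 1536 tetrahedra, with the rim pinned and the
expander center on the inner surface beneath the apex. The patch is the
gnomonic (cubed-sphere) image of a square grid, so each cell is a proper
hexahedron with no degenerate cells at the apex. How the real scalp is
restrained at the margins of the dissected pocket is not documented
clinically; rim-pinning is this package's convention.

The fixture emulates the geometry, curvature, thickness and loading of a real
expansion, and a published clinical case's step tables are bundled for the
planning arithmetic. It does **not** reproduce patient-specific anatomy,
layered scalp histology, anisotropy, viscoelastic or growth (remodeling)
response, or measured material constants - passing tests demonstrate the
correctness of the mechanics and bookkeeping, not a validated patient
prediction. Single-layer linear tetrahedra through the thickness also
overestimate bending stiffness; the fixture's role is verification at a
problem size (about 1700 free degrees of freedom) that solves in minutes.

## Numerical choices

* Voigt order (11, 22, 33, 23, 31, 12), engineering shear for strain; fixed
  package-wide to match the strain-displacement matrices.
* Residual tolerance relative to the external load norm (scale invariance),
  floor \(10^{-10}\) N; degenerate zero-load steps therefore converge
  immediately at zero displacement.
* Direct sparse factorization for every linear solve (desk-scale problems;
  no iterative solver).
* Tetrahedra with negative signed volume on input are reoriented (last two
  nodes swapped) with a warning - a common exporter variation - while
  zero-volume elements are an error naming the element.
* The Delaunay projection plane is the least-squares (principal-component)
  plane of the sample; sampling seeds default to 0 and are stored with the
  sample.
* Ratios in the planning module round half-up (1/0.7 → 1.43), not
  banker's rounding.

## Known limitations

Pressure-controlled one-way contact cannot capture expander impenetrability:
if the schedule grows much faster than the scalp inflates, contacted area
(and so total load) rises sharply and the solve traverses limit points. The
regularized solver handles the bundled conditions, but arc-length
continuation would be the principled extension for tracing unstable branches.
The model also treats the expander as rigid in shape (a growing ellipsoid)
and ignores friction; the abstract planning promise of optimizing expander
*number and placement* is out of scope - placement is the configured center
point, and only single-expander sizing is automated.
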