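---
title: "Modelling peripheral-nerve stretch: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling peripheral-nerve stretch: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nervestretch)
```

## The constitutive model

Peripheral nervous tissue under tension is modelled as homogeneous,
isotropic and fully incompressible, with a reduced Yeoh strain energy
function — a cubic in the first strain invariant only:

$$\Psi(I_1) = c_1 (I_1 - 3) + c_2 (I_1 - 3)^2 + c_3 (I_1 - 3)^3 ,$$

with constants in kPa.  For a homogeneous incompressible uniaxial state with
axial stretch $\lambda$ the deformation gradient is
$\mathrm{diag}(\lambda^{-1/2},\lambda^{-1/2},\lambda)$, so
$I_1 = \lambda^2 + 2/\lambda$ and the transverse stretch is
$1/\sqrt{\lambda}$.  Eliminating the incompressibility multiplier through the
traction-free lateral surface turns the stress–stretch relation into a
rational closed form: a degree-9 polynomial $\wp^{[9]}(\lambda)$, linear in
$(c_1,c_2,c_3)$, divided by $\lambda^3$ (see `p9_coefficients()`).

### The factor-of-two convention

The published closed form equals exactly **half** of the textbook derivation
$\sigma_z = 2\,\Psi'(I_1)(\lambda^2 - 1/\lambda)$ from the Cauchy stress
relation $\sigma = -k I + 2\,\Psi' F F^T$.  Published nerve constants are
reported under the polynomial-over-$\lambda^3$ form, and the finite-element
comparisons are numerically consistent with it, so the package treats that
form as canonical (`convention = "as_printed"`, the default).  Whether the
missing factor is a typo or a constant-absorbing convention cannot be decided
from the printed record — the two differ only by a rescaling of the
constants.  For interoperability with conventional Yeoh implementations the
`"standard"` convention is exposed; `convert_convention()` halves or doubles
the constants so that either convention predicts the same curve, and the FE
solver performs this internally (it consumes a standard-form energy).  The
relationship is pinned by tests: `derive_stress_from_sef()` (an independent
code path that eliminates the multiplier from the tensor relation) must equal
exactly twice the as-printed stress for random parameters.

Species presets carry the published constants converted to kPa:
pig (5.89, 5.89, 7750) to $\lambda = 1.08$; rabbit (200, 200, 43 700) to
1.3; lobster (140, 140, 0) to 1.5; *Aplysia* connective
(0.0081, 0.0081, 0.0054) to 5.  All four satisfy the Drucker criterion —
stress strictly increasing over their ranges (`drucker_margin()` certifies
the minimum slope by dense evaluation of the exact derivative; 2001 grid
points by default, ample for a degree-9 rational function).

### Stress measure

The closed form is Cauchy stress (force per deformed area).  Which measure
the digitised experimental curves use is not stated in the source record;
curves are taken as Cauchy by default and `cauchy_to_nominal()`
($\sigma/\lambda$ under incompressibility) is provided for the alternative
reading.  The choice affects the meaning of fitted constants, not the
pipeline.

## Identification of the constants

`fit_yeoh()` identifies $(c_1,c_2,c_3)$ from a stress–stretch curve by
maximising $R^2 = 1 - SS_{res}/SS_{tot}$ ($SS_{tot}$ about the mean — the
standard coefficient of determination; no other definition makes the printed
"$R^2$ maximisation" well posed).  Since $SS_{tot}$ is data-only this is
equivalent to bounded least squares.  The optimizer is a bounded
limited-memory quasi-Newton method (L-BFGS-B) with the analytic gradient of
the residual sum of squares; the model is linear in the constants, so after
internal column scaling the problem is well conditioned and every published
starting pair — $[10,0]$, $[12.99,0]$, $[0,12.40]$, $[0,11.99]$, $[10,0]$ for
$(c_1,c_2)$ — converges to the same optimum (a tested invariant).  All
starts are tried and the best $R^2$ wins, ties broken by the smaller $c_3$.
Bounds: $c_3$ is constrained to a caller-supplied interval (6 000–9 000 kPa
reproduces the pig identification; $[0,0]$ pins $c_3 = 0$ for the
lobster-like quadratic response), $c_1, c_2 \ge 0$ by default.  Convergence
control: L-BFGS-B `factr = 10`, at most 500 iterations per start.

Tying $c_1 = c_2$ is **off** by default: the near-equality of the two
constants is an empirical finding of the multi-extension experiments, not a
constraint, so both behaviours are testable.  An independent dense grid
search over $(c_1{=}c_2, c_3)$ serves as the oracle for the optimizer in the
test suite.

`sensitivity_index()` implements
$SI(c_i) = (\sigma_{\max} - \sigma_{\min})/\sigma_{\max}$, evaluating the
stress at the endpoints of each constant's range with the others held at
their optima.  The published per-constant SI values (10.79, 0.32, 5.38)
exceed 1 for $c_1$ and $c_3$, which is impossible for this formula with
positive stresses; the ranges or normalisation actually used are unstated, so
those values are not reproduced — the formula is implemented as printed and
the package instead asserts the qualitative ordering ($c_2$ least
influential) over the per-extension ranges, which is robust.  When no ranges
are supplied by the caller, `cmd_fit()` defaults to the per-extension
min/max of the fitted constants, the only range the record pins down.

`constants_correlation()` computes squared Pearson correlations between
per-extension $c_1$ and $c_2$ and between $c_1$ and $c_3$ (plus OLS lines).
On the published per-extension values the $c_1$–$c_3$ correlation is
$R^2 = 0.4965$ (reported as 0.49 — evidently truncated rather than rounded;
the hand-computable Pearson $r$ is $-0.70$).

## Synthetic experiments

`generate_curve()` evaluates the closed form on an equally spaced stretch
grid (the constant-velocity loading protocol implies equal spacing) and
perturbs it as $\sigma\,(1+\varepsilon_m) + \varepsilon_a$ with independent
Gaussian terms.  The published record gives only min–max scatter bars, no
noise distribution; multiplicative-plus-additive Gaussian is the standard
instrument model, with defaults $\varepsilon_m$: 1% and $\varepsilon_a$: 0 —
1% of the stress is the scale of the published scatter.  Between-extension
drift (`extension_drift()`) defaults to the published per-extension pig
constants, with $c_2 = c_1$ per extension (the observed near-equality, error
below $2.4\times10^{-5}$ kPa).  Generation is bit-reproducible under a seed,
through a local RNG stream that leaves the session RNG untouched.

What the generator does *not* emulate: preconditioning transients,
viscoelastic rate dependence, force-sensor sampling artifacts, or any
heteroscedasticity beyond the multiplicative term.  Passing recovery tests
on these synthetic curves therefore shows the estimator is correct and
noise-stable, not that real nerve data satisfy the Yeoh form.

## Geometry reduction

The model-reduction chain mirrors the published one: a mean elliptic
cylinder (the pig specimen: full axes 3.57 and 2.28 mm, eccentricity 0.77,
area $\pi a b \approx 6.39\;\mathrm{mm}^2$; gauge length 69 mm between
clamps) is reduced to a quarter by its two symmetry planes, rescaled to an
area-equivalent circular cylinder by $r^2 = ab$ (exact by construction), and
finally to a 2-D axisymmetric rectangle $[0,r]\times[0,L]$.  The published
"major axis 3.57 mm" is a **full** axis — only then does $\pi ab$ reproduce
the printed area — whereas the *Aplysia* values (0.57, 0.44 mm) are printed
as semi-axes; the package stores semi-axes and the caller halves full axes.
Models use the 69 mm gauge length, not the 96 mm total specimen length: the
clamped-length choice is assumed (the record does not state it), since the
imposed-displacement boundary conditions act at the clamps.

3-D sections are meshed by the concentric square-to-disk map scaled by the
semi-axes, which places boundary nodes exactly on the ellipse and keeps
element Jacobians bounded away from zero (a naive tensor-product mapping
degenerates at the section corner and was measurably less robust at large
stretch).

## The finite-element solver

`solve_stretch()` performs a total-Lagrangian, displacement-driven Newton
solution with trilinear hexahedra (3-D) or bilinear quadrilaterals
(2-D axisymmetric), 2-point Gauss quadrature per direction.

**Incompressibility.**  The default formulation is mixed
displacement–pressure with one pressure unknown per element (Q1/P0) acting
on the element-mean volume ratio $\bar J$, regularised as a perturbed
Lagrangian with stiffness $\kappa = 10^9 \times$ the peak theoretical
stress, so $|\bar J - 1| \approx |p|/\kappa \lesssim 10^{-9}$ at
convergence — fully incompressible for practical purposes.  A pure penalty
fallback (`formulation = "penalty"`) uses the same $\kappa$.  Pointwise
$J$ inside an element is only constrained in the mean: low-order elements
cannot satisfy $J = 1$ at every quadrature point in inhomogeneous regions,
so the pointwise incompressibility assertions in the tests apply to the
homogeneous patch test (where the property is exact, $|J-1| \le 10^{-6}$)
and the element-mean deviation ($\le 10^{-6}$) everywhere else.

**Pointwise stabilization.**  In the clamp corners at extreme stretch
($\lambda \to 5$) the within-element volume of a Q1/P0 element can collapse
even while its mean is constrained.  A small pointwise volumetric term
$\tfrac{1}{2}\,s\,2\Psi'(I_1)\,(J-1)^2$ per quadrature point
(`stab_factor`, default $s = 30$) prevents this.  Two properties make it
safe: it is proportional to the *local* tangent stiffness $2\Psi'(I_1)$, so
it introduces no foreign stress scale at any material softness (a
constant-modulus variant visibly contaminated the micro-soft *Aplysia*
response through pressure checkerboarding); and its stress vanishes
identically wherever $J = 1$ pointwise — exactly the homogeneous states
sampled at mid-length — so patch-test exactness and the measured quantities
are unaffected.

**Newton scheme.**  Each increment starts from a homogeneous-deformation
predictor (the affine state for the new stretch plus the previous step's
deviation from its own affine state — trilinear elements represent affine
fields exactly, so only the clamp boundary layers need correcting), then
full Newton with the exact consistent tangent, a backtracking line search on
the residual norm (trial states that invert an element are rejected the same
way), and relative residual tolerance $10^{-9}$ per increment, at most 25
iterations.  Load stepping: increments of at most 0.01 in $\lambda$ up to
1.5, adaptive doubling (cap $20\times$) beyond, halving on failure; the run
aborts with the last converged stretch if halving stalls.

**Boundary conditions.**  The experimental protocol: one end fully clamped,
the other displaced axially and blocked against lateral contraction.
`moving_end_lateral = "free"` gives the homogeneous patch configuration used
for verification.  The *Aplysia* record fixes the top and displaces the
bottom — mechanically identical under the package's sign handling
(`fixed_end`).  The mid-length ganglion sphere of the 3-D *Aplysia* anatomy
is not modelled (the published 2-D reduction also omits it); the simplified
model applies the lateral block at the moving end only.

## Comparing FE with the closed form

`midlength_stress_strain()` samples the element layer nearest mid-length —
farthest from both clamps (Saint-Venant argument; where the curves were
sampled is not stated in the record) — averaging the axial Cauchy stress
over its quadrature points, and reads the transverse stretch from the radial
displacement of the mid-length outer-surface nodes
($1 + u_x/a$ and $1 + u_y/b$ at the section-axis ends in 3-D).

One consequence of the clamped ends deserves emphasis.  Because the end
layers cannot contract laterally, incompressibility prevents them from
stretching, and the mid-length section attains a *larger* stretch than the
nominal $d/L + 1$ — a physical, mesh-converged redistribution (for the pig
slice, end-layer stretch $\approx 1.03$ at nominal 1.08, mid-length
$\approx 1.081$).  Evaluating the closed form at the nominal stretch
therefore leaves a residual error of a few percent *no matter how fine the
mesh* — irreconcilable with the sub-percent agreements the reduced-order
studies report and with their error curves being zero at moderate stretch.
Those agreements are a *constitutive verification*: the simulated stress and
transverse stretch at the sampling section lie on the closed-form curve at
the stretch actually attained there.  `compare_to_theory()` therefore
defaults to `reference = "local"` (theory evaluated at the attained
mid-length stretch, reported as `lambda_local`) and exposes
`reference = "nominal"` for the protocol-level comparison.  Under the local
reference the package reproduces the reported bounds with margin: 3-D
elliptic pig stress within 0.4% and transverse strain within
$3\times10^{-4}$; 2-D pig slice within 0.006% and $5\times10^{-4}$; 2-D
*Aplysia* slice to $\lambda = 5$ within 1.6% and 0.019.

Nodal stress fields for distribution (quantile) comparisons are element-mean
quadrature stresses scattered to nodes; `compare_to_theory()` attaches the
percentile vector of the final step.

## Problem sizes and tolerances

The default study meshes are chosen as the coarsest grids whose mid-length
band is converged well inside the reported bounds: the pig slice uses
$6\times46$ bilinear elements (the published slice used $6\times23$ with
enhanced-strain commercial elements; the package's plain Q1/P0 grid needs
roughly double the axial resolution to match — the published 210-node count
implies internal nodes of the commercial element and is not reproducible
with plain bilinear connectivity, whose $6\times23$ grid has 168 nodes but
the same 138 elements), the *Aplysia* slice $6\times100$ (band accuracy at
$\lambda = 5$ is governed by axial resolution), and the 3-D quarter pig
model $4\times24$ (384 hexahedra against the published 828 for the
quarter model).  Each acceptance-scale FE run completes in seconds to a few
tens of seconds on one CPU.  Key tolerances: Newton $10^{-9}$ relative;
incompressibility $\kappa = 10^9\times$ stress scale; stabilization
$s = 30$; fitting `factr = 10`; Drucker grid 2001 points.

## Known limitations

* Isotropic, elastic, $I_1$-only response: no viscoelasticity, no damage or
  rupture, no fascicle-level anisotropy.
* Low-order elements with mean-dilatation incompressibility: pointwise
  $J = 1$ holds only in homogeneous states; clamp-corner fields are
  regularised by the stabilization term and should not be interpreted
  quantitatively.
* The clamp is an idealised displacement constraint — no contact, friction
  or grip compliance.
* Wall-clock speed-up ratios between the 3-D and reduced models are
  hardware-dependent and reported qualitatively only (the reductions solve
  far smaller systems; that is the point of the chain).
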