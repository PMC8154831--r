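---
title: "Methods: a multilayer biphasic model of human skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multilayer biphasic model of human skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, the numerical methods and the design
choices behind `skinphase`, in the spirit of a methods section: what is
computed, which knobs matter, and what the shipped tests do and do not
demonstrate. All quantities are in the mm–N–s–MPa unit system
(MPa·mm² = N), so the tabulated material constants are used verbatim and
nominal tensions integrate to N/mm.

## The constitutive model

Each layer — epidermis (Epi), papillary dermis (PD), reticular dermis
(RD), hypodermis, muscle — is a saturated biphasic mixture: an
incompressible solid skeleton plus mobile incompressible interstitial
fluid (theory of porous media). The solid free energy is exponential
(Rubin–Bodner type),

$$\Psi_s = \varphi_s^{ref}\,\frac{\mu_0}{2q}\left(e^{q g}-1\right),
\qquad g = g_m + g_{fe} + g_{fd},$$

with an isotropic matrix contribution
$g_m = m_1[\mathrm{tr}(F b_0 F^T) - 3] +
(m_1/m_2)[(J J_0)^{-2m_2} - 1]$ and two fiber contributions
$g_{f\bullet} = (m_{f\bullet}/m_{4\bullet})\,N^{-1}\sum_i
\langle \lambda^i_{f\bullet} - 1\rangle^{2 m_{4\bullet}}$, tension-only
through the Macaulay bracket. The fluid chemical potential is
$\mu_F = p - \Delta\pi$ with
$\Delta\pi(J) = \beta_0[(1-\varphi_s^{ref})/(J-\varphi_s^{ref})]^{\beta_1}$,
and the flux obeys Darcy's law with isotropic deformation-dependent
permeability $k(J) = k_0[(J-\varphi_s^{ref})/(1-\varphi_s^{ref})]^\kappa$.

### The material table

`builtin_table1()` holds the adopted per-layer constants. Two details
deserve comment.

*Digit grouping.* The printed source of several fiber rows is
typographically ambiguous (run-together digit strings). The adopted
grouping gives muscle zero fiber content (`m_fe = m_fd = 0`), consistent
with its zero fiber angle and zero fiber rate factor, and satisfies the
documented inter-layer trends (elastic fiber stiffness and permeability
grow from Epi to RD; the out-of-plane fiber angle shrinks). The
alternative grouping (`m_fe` = 2/5/110/240/500) was implemented and run
through the same uniaxial pipeline: it breaks the growth of the tangent
modulus with stretch in the papillary dermis and was rejected.

*Fiber angle.* The table value for RD is 7°; the accompanying text once
says "only 8°". The table value is used.

### Initial swelling

The mesh geometry is prescribed in the *swollen* reference state: each
layer is pre-swollen isotropically from a virtual zero-energy state by
$J_0^{1/3}$ so that at $F = I$ the layer is in equilibrium with a fluid
bath at zero chemical potential, i.e. the isotropic matrix stress
balances $p = \Delta\pi(1) = \beta_0$. This scalar balance is monotone
in $J_0$ and solved with `uniroot` to $10^{-12}$
(`solve_initial_swelling()`); the resulting residual stress at rest is
below $10^{-18}$ MPa in every layer. Because each layer is meshed in its
own swollen state, differing $J_0$ across layers induce no rest stress
or bending.

*Fibers carry no osmotic pre-tension.* Fiber stretches are measured from
the swollen reference, $\lambda_f = |F a|$, while the matrix term sees
the full pre-swell through $b_0$. The alternative — pre-stretching
fibers by $J_0^{1/3} \approx 1.3$ — was examined and rejected: on the
exponential fiber law it produces an enormous, non-isotropic pre-stress
that no scalar swelling ratio can equilibrate, contradicting the
requirement of a self-equilibrated swollen reference. This is the one
place where the package deliberately departs from treating the swelling
as a uniform multiplicative pre-deformation of *all* constituents.

### Dissipative fibers

The second fiber branch carries internal variables: per direction a
relaxed stretch $\lambda_r$ with branch stretch
$\lambda_{fd} = \lambda_f/\lambda_r$, evolving by

$$\dot\lambda_r = k_{fd}\, f_{fd}\, \lambda_r, \qquad
f_{fd} = \partial\Psi_s/\partial\lambda_{fd} \ge 0 .$$

$k_{fd}$ (mm² N⁻¹ s⁻¹) times the thermodynamic force $f_{fd}$ (MPa)
gives a rate in 1/s, as required by the tabulated units. The law
reduces to a purely elastic second branch for $k_{fd} = 0$ and relaxes
completely under a stretch hold ($\lambda_{fd} \to 1$, algebraically in
time because the driving force vanishes with
$\langle\lambda_{fd}-1\rangle^{2m_{4d}-1}$). Backward Euler per
direction (safeguarded scalar Newton, outer sweeps for the energetic
coupling across directions) integrates the law; a high-order ODE oracle
cross-checks it in the tests. A faster variant with the per-fiber
(undiluted by $1/N$) force was implemented and compared on the full
uniaxial pipeline; it softens the intermediate-stretch response too far
and was not adopted. With the adopted law the dissipative branch is
largely frozen during a 0.001/s ramp, which makes the simulated
intermediate-stretch tangent moduli of RD and PD stiffer than the
experimentally reported layer values; this is a known limitation
discussed below.

### Fiber direction set

`make_fiber_set(theta, N)` builds $N/2$ azimuthally uniform directions
at elevation $+\theta$ out of the tissue plane plus their mirror images,
so the in-plane behavior is isotropic (transversely isotropic structure
about the skin normal). $N = 16$ is the default: doubling to 64 changes
the uniaxial point response by well under 1%.

## Material-point driver

`run_point()` integrates homogeneous uniaxial histories with
traction-free lateral faces, solving the two lateral stretches by Newton
at every step. Two drainage idealizations bracket the fluid behavior:
*drained* ($\mu_F = 0$, $p = \Delta\pi(J)$ — the fully equilibrated
limit) and *undrained* ($J$ frozen — the instantaneous limit). The
drained driver doubles as the patch-test oracle for the finite-element
solver. `run_relaxation()` ramps at a given nominal strain rate to a
target tension and holds the length. Tangent stiffness
$E = (1/t)\,\partial T/\partial\lambda$ is extracted by a central
difference of window $\Delta\lambda = 0.01$; the small-strain anchor is
evaluated at $\lambda = 1.005$ (window $[1, 1.01]$, one-sided with
respect to 1) because the tension-only fibers make $T(\lambda)$
non-smooth exactly at 1.

## Finite elements

The coupled problem — momentum balance
$\mathrm{div}(\sigma_s - p I) = 0$ and fluid mass balance
$\dot J/J + \mathrm{div}\,q = 0$ — is discretized with mixed
interpolation: triquadratic displacement / trilinear chemical potential
on 27-node hexahedra (3-D), biquadratic / bilinear on 9-node
quadrilaterals (axisymmetric), full 3×3(×3) Gauss quadrature. Backward
Euler in time; full Newton on the monolithic residual with a
finite-difference material tangent evaluated at frozen end-of-step
internal variables (modular tangent), sparse LU (Eigen, COLAMD) for the
linear solves, solution extrapolation as predictor, and step bisection
on non-convergence. Newton tolerances are relative $10^{-8}$ on the
residual norms with tight absolute floors; a converged rest state is an
exact equilibrium (residuals $<10^{-12}$).

Follower pressure loads (suction) act on the deformed boundary; their
load stiffness is included by finite differences of the edge force.

### Uniaxial protocol

Quarter-symmetric 1 × 2.5 × 2 mm³ domain: symmetry at $x_1 = 0$ and at
the mid-width plane, prescribed axial displacement on the loaded face at
nominal strain rate 0.001/s, one pinned node against rigid motion, all
other faces traction-free. Drainage: zero chemical potential at the free
lateral face and the bottom; the top surface (stratum corneum) and the
loaded cross-sections are impermeable. The default mesh is 6 × 6 × 7 =
252 elements (one element layer for Epi and PD, five for RD); doubling
the resolution changes the total tension at $\lambda = 1.2$ by under
2%. Per-layer nominal tension is the volume average of the axial first
Piola stress over the layer divided by domain length and width, which by
discrete equilibrium sums exactly to the reaction tension.

The out-of-plane deflection metric (surface displacement at the
specimen center minus at 2 mm from the center) is evaluated *across the
width*: the modelled slice is uniform along the loading axis, and the
free lateral edge is where differential lateral contraction of the
layers curls the surface. A multilayer stack keeps a positive deflection
in the drained equilibrium; a single-layer model bends only transiently
(through the asymmetric drainage path) and returns to flat — the
layering, not the fluid, carries the equilibrium curling. Apparent
lateral stretches are width and thickness ratios of the mid-specimen
cross-section; the thickness gauge uses the lower half of the deepest
layer, mirroring how the deformed cross-section is gauged optically
(the choice of "lower half" moves the apparent thickness stretch by
about a percent and is exposed as a parameter).

### Suction protocol

Axisymmetric (r, z) domain; the probe face outside the opening is a
closed frictionless bilateral contact (zero vertical displacement, free
radial slip), the opening carries the follower suction pressure, the
axis is a symmetry line, bottom and far field are fixed and drained, the
top surface impermeable. The mesh is graded radially toward the probe
edge (edge mesh size capped at opening/6 so the dome is always
resolved). Default stacks: Epi 0.1 / PD 0.2 / RD 1.1 mm over 3 mm
hypodermis (2 mm probe), plus a 2 mm muscle base (8 mm probe); the 10 mm
emulation uses RD 1.7 mm over 3 mm hypodermis. Domain radii: 8, 16 and
12 mm. The suction magnitudes are **not** reported quantities; the
defaults (0.02 MPa for the 2 mm probe, 0.008 MPa for 8 mm) sit in the
standard operating range of aspiration devices and produce apex
displacements of the observed scale (~0.5 mm and ~1.5 mm). For the
10 mm protocol the pressure ramps at 5·10⁻⁴ MPa/s until the apex
reaches the device's maximum tissue elevation of 2.5 mm.

Fluid particle tracing integrates
$x_f(t+\Delta t) = x_f(t) + v_s\,\Delta t + \varphi_f^{-1} q\,\Delta t$
with $\varphi_f = 1 - \varphi_s^{ref}/J$ (incompressible solid
constituent), sampling fields piecewise-constant at the nearest deformed
Gauss point, and reports paths in both the spatial and the material
frame.

## Synthetic data and fitting

`generate_fixture_curves()` produces tension–stretch curves from the
material-point driver with additive Gaussian noise (seeded); it emulates
clean uniaxial gauge data on a uniform stretch grid and deliberately
does *not* emulate specimen-to-specimen variability, clamping artefacts
or measurement drift — parameter-recovery tests on it demonstrate the
identifiability machinery, not robustness to real experimental error.
`fit_parameters()` wraps bounded Levenberg–Marquardt least squares
(minpack.lm) around the point driver; on noise-free self-generated
targets it recovers $\{\mu_0, m_{fe}\}$ of RD to well within 5% from
±50% perturbed starts. The global multi-experiment inverse analysis is
out of scope.

## Problem sizes used by the shipped tests

Unit tests run on deliberately small meshes (tens of elements, seconds).
The acceptance suite runs the full 252-element uniaxial protocol
(~6–8 min) and the 10 mm suction protocol (~1–2 min), plus coarse-mesh
property runs (multilayer vs single-layer equilibrium deflection, 2 mm
vs 8 mm thickness trends, the infinite-permeability suction cycle, and
parameter recovery).

## Known limitations

* **In-plane isotropy.** No preferred in-plane fiber direction and an
  isotropic permeability tensor; anisotropic skin (cleavage lines) is
  outside the model.
* **Dissipation channels.** Only the fiber branch and the fluid flux
  dissipate; there is no matrix (distortional) viscosity, so fast shear
  histories are not captured.
* **Intermediate-stretch stiffness.** With the adopted fiber rate law
  the dissipative branch barely relaxes at 0.001/s, and the simulated
  mid-stretch tangent moduli of RD/PD overshoot reported layer values
  (the small-stretch anchors and all stiffness orderings are
  reproduced). No admissible rate factor reconciles all anchors
  simultaneously; the residual gap sits in the elastic fiber response at
  large stretch.
* **Sustained large-opening suction.** Driving the 10 mm model to
  2.5 mm apex elevation requires ~0.03–0.04 MPa; at such loads the
  osmotically soft volumetric response takes up interstitial fluid and
  the skin at the axis *thickens* by ~12%, whereas MRI observations of
  sustained aspiration show ~10% thinning. The early transient
  (apex < 1.7 mm) does thin. The small- and large-probe thickness-trend
  contrasts at instrument-typical pressures are reproduced.
* **Contact.** The probe is a bilateral frictionless constraint; no
  unilateral contact search, no 3-D suction, no remeshing.
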