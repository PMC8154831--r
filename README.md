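# skinphase

Multilayer biphasic mechanics of human skin in R.

Skin is a stack of mechanically distinct layers — epidermis (Epi),
papillary dermis (PD), reticular dermis (RD), hypodermis, muscle — each a
porous collagenous solid saturated by interstitial fluid. Measurements on
the same tissue disagree wildly between uniaxial tension, suction and
indentation unless the layering and the fluid are modelled explicitly.
`skinphase` implements a layered biphasic continuum model and the
finite-element machinery to drive it through the standard ex vivo and in
vivo protocols: uniaxial tension and relaxation of excised strips, and
probe aspiration (suction) of skin in vivo.

## Model

Each layer is a biphasic mixture (theory of porous media). The solid
skeleton carries an exponential Rubin–Bodner-type strain energy

    Psi_s = phi_s^ref * mu0/(2q) * (exp(q g) - 1),
    g = g_m + g_fe + g_fd

with an isotropic matrix term referred to the osmotically pre-swollen
reference (`b0 = J0^(2/3) I`)

    g_m = m1 [tr(F b0 F^T) - 3] + (m1/m2) [(J J0)^(-2 m2) - 1],

and two discrete fiber families distributed azimuthally at an
out-of-plane elevation ±theta — an elastic branch `g_fe` and a
dissipative branch `g_fd` with relaxed stretch internal variables — both
tension-only via Macaulay brackets

    g_fe = (m_fe/m_4e) (1/N) sum_i < lambda_fe^i - 1 >^(2 m_4e).

The interstitial fluid moves down gradients of its chemical potential
`mu_F = p - Delta_pi` by Darcy flow, with constitutive osmotic pressure
and deformation-dependent permeability

    Delta_pi(J) = beta0 ((1 - phi_s^ref)/(J - phi_s^ref))^beta1,
    k(J)        = k0 ((J - phi_s^ref)/(1 - phi_s^ref))^kappa.

All quantities use mm–N–s–MPa units. Per-layer constants ship in
`builtin_table1()`; the boundary-value problems are solved with a mixed
finite-element formulation (quadratic displacement, linear chemical
potential; 27-node hexahedra in 3-D, 9-node quadrilaterals
axisymmetric), backward Euler in time and Newton iteration on the
monolithic residual (Rcpp/Eigen kernels).

## Worked example

Swelling equilibrium and a drained uniaxial tension curve of the
reticular dermis at a material point:

```r
library(skinphase)
p <- builtin_table1()$RD
solve_initial_swelling(p)
#> <SwellingState> J0 = 2.3944390778  equilibrium residual = 1.735e-18 MPa

cv <- run_point(p, rate = 1e-3, lambda_max = 1.22)
round(1000 * sapply(c(1.005, 1.10, 1.20), function(l)
  tangent_stiffness(cv, l, thickness = p$thickness)), 1)
#> [1]  106.4 3446.9 6953.5     # tangent stiffness, kPa
```

`J0` is the volume ratio of the osmotic pre-swelling that equilibrates
the layer against its own swelling pressure (`beta0` = 2.49e-3 MPa for
RD); the three numbers are the thickness-normalised tangent stiffness
`E = (1/t) dT/dlambda` (kPa) at small, intermediate and large stretch —
the J-shaped stiffening typical of collagenous tissue.

The full protocols run on the finite-element solver:

```r
res <- run_uniaxial_monotonic()   # 252-element multilayer run, ~minutes
res$moduli                        # layer x anchor tangent moduli (MPa)
suc <- run_suction(opening = 8, protocol = "instantaneous")
suc$summary
```

A thin command-line wrapper is installed under `inst/exec/skinphase`
(subcommands `params`, `swell`, `point`, `uniaxial`, `relax`, `suction`,
`fixtures`, `fit`).

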