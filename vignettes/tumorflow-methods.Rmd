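---
title: "Interstitial fluid flow and nanodrug transport in a solid tumor: model and methods"
author: "tumorflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interstitial fluid flow and nanodrug transport: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tumorflow)
```

## The physical model

`tumorflow` treats a small solid tumor as three concentric regions of an
isotropic porous medium: an avascular **necrotic core** (radius
$R_{nt} = 0.5$ cm by default), a vascularized **viable rim**
($R_{vt} = 1$ cm) with no functional lymphatics, and surrounding
**healthy tissue** ($R_{ht} = 2$ cm) with both blood vasculature and
lymphatic drainage. The vasculature is not resolved geometrically; it
enters as homogenized source and sink densities per unit tissue volume.

### Steady interstitial fluid flow

Mass conservation for incompressible Darcy flow
$\mathbf v = -K \nabla P$ with a Starling filtration source and a lymphatic
sink gives, per region,

$$-K \nabla^2 P = \varphi_{VS} - \varphi_{LS}, \qquad
\varphi_{VS} = L_p \tfrac{S}{V}\big(P_V - P - \sigma_s(\pi_V - \pi_{IS})\big),
\qquad
\varphi_{LS} = L_{PL}\tfrac{S_L}{V}(P - P_L).$$

Both exchange terms are linear in $P$, so each region reduces to a modified
Helmholtz equation $\nabla^2 P = \beta^2 (P - P_{SS})$ with

* $\beta^2 = (L_p S/V + L_{PL} S_L/V)/K$ — zero in the necrotic core,
* $P_{EF} = P_V - \sigma_s(\pi_V - \pi_{IS})$, the pressure at which
  filtration stops,
* $P_{SS}$, the conductance-weighted average of $P_{EF}$ and $P_L$ — the
  far-field equilibrium pressure of the region,
* $\alpha = R\sqrt{\beta^2}$, the dimensionless flow-resistance parameter
  reported at the reference length $R = R_{vt} = 1$ cm.

The outer boundary carries a zero-flux (Neumann) condition; pressure and
the Darcy flux $K\,\partial P/\partial n$ are continuous across the
interfaces. Because $\beta^2 > 0$ outside the core, the pure-Neumann
problem is well posed without pinning a pressure value.

With the default physiology the viable rim is thick on the boundary-layer
scale ($\beta_v (R_{vt}-R_{nt}) \approx 18$), so the pressure across the
core and most of the rim plateaus at $P_{SS,\text{viable}}$ and falls to
$P_{SS,\text{healthy}}$ in a layer of width $1/\beta \approx 0.25$ mm at
the viable–healthy interface — which is also where the interstitial
velocity peaks.

### Solute transport

The interstitial nanodrug concentration obeys a transient
convection–diffusion–reaction equation. Grouped as the solvers assemble it:

$$\frac{\partial C}{\partial t}
 = \nabla\!\cdot\!(D_{EF}\nabla C) - \mathbf v\cdot\nabla C
 - \Big[\nabla\!\cdot\!\mathbf v
        + P\tfrac{S}{V}\,\frac{Pe}{e^{Pe}-1}
        + \varphi_{LS} + \tau_{deg}\Big] C .$$

* **Hindered diffusion**: $D_{EF} = \frac{2\xi}{3-\xi} D_{DIS}$ with the
  regional void fraction $\xi$ and the Stokes–Einstein free-fluid value
  $D_{DIS} = k_B T / (6\pi\mu n_r)$ for particle radius $n_r$.
* **Transvascular extraction**: with plasma concentration taken as zero
  (an intratumorally injected dose reaches the plasma too slowly to build
  one up), the transcapillary exchange is a first-order sink with
  coefficient $P\frac{S}{V}\,Pe/(e^{Pe}-1)$, where
  $Pe = \varphi_{VS}(1-\sigma_{rc})/(P\,S/V)$ depends on the local
  pressure. Where fluid filters strongly outward ($Pe \gg 0$, i.e. low
  IFP) the factor vanishes; on the plateau ($P \approx P_{EF}$,
  $Pe \approx 0$) it equals the permeability–area product; under
  resorption ($Pe \ll 0$) it tends to the solvent-drag limit
  $|\varphi_{VS}|(1-\sigma_{rc})$.
* **Lymphatic drainage** $\varphi_{LS} C$ (healthy region only) and
  first-order **degradation** $\tau_{deg} C$, which lumps nano-bio uptake
  (e.g. by tumor-associated macrophages).

The injection initial condition is a uniform concentration over the
necrotic core (default $C_0 = 4$ mg/cc; the carrier comparison uses
100 mg/cc), with interface nodes taking the inside value. A `ball` target
reproduces the small-sphere infusion used for verification.

## Parameters

Defaults (cm–s–mmHg internally; 1 mmHg = 133.322 Pa for reporting):

| symbol | necrotic | viable | healthy | units |
|---|---|---|---|---|
| $L_p$ | 2.8e-7 | 2.8e-7 | 3.6e-8 | cm/(mmHg s) |
| $K$ | 4.13e-8 | 4.13e-8 | 8.53e-9 | cm²/(mmHg s) |
| $S/V$ | 0 | 200 | 70 | 1/cm |
| $\sigma_s$ | – | 0.82 | 0.91 | – |
| $\pi_V$, $\pi_{IS}$ | – | 20, 15 | 20, 10 | mmHg |
| $P_V$ | – | 15.6 | 15.6 | mmHg |
| $P$ (solute) | – | 5.73e-9 | 0.73e-9 | cm/s |
| $\xi$ | 0.6 | 0.4 | 0.26 | – |

Lymphatic filtration $L_{PL} S_L/V = 1.1\times10^{-5}$ 1/(mmHg s) in
healthy tissue; $P_L = 0$ models absent functional lymphatic dynamics and
$P_L = -4$ mmHg the complete functional case (lymphatics act as a suction
pump, which drives healthy-tissue pressure negative). Solute defaults:
$\sigma_{rc} = 0.5$, $\tau_{deg} = 5.8\times10^{-6}$ 1/s,
$T = 310$ K, $\mu = 10^{-3}$ Pa s. Vascular-normalization presets replace
the viable-rim $K, L_p, S/V, \sigma_s$ (50% and 100% levels); carrier
presets carry tabulated per-tissue $D_{EF}$ and $\tau_{deg}$ for
doxorubicin, dextran, liposomal, PEG-gold and magnetic particles.

These values give $P_{EF,\text{viable}} = P_{SS,\text{viable}} =
11.5$ mmHg, $P_{SS,\text{healthy}}(P_L{=}0) = 1.2115$ mmHg and
$\alpha = 36.8 / 29.3 / 17.19$ at 0/50/100% normalization — the quantities
the acceptance script recomputes.

## Numerical methods and choices

**Closed-form radial oracle.** Under radial symmetry each region's general
solution is known: spherical ($\nu = 2$) $\{\sinh(\beta r)/r,
\cosh(\beta r)/r\}$, cylindrical/plane-disc ($\nu = 1$) modified Bessel
$\{I_0(\beta r), K_0(\beta r)\}$, and $\{1, r^{1-\nu}\ \text{or}\ \log r\}$
where $\beta = 0$. Regularity at the center, two matching conditions per
interface and the outer zero-flux condition form a 6×6 linear system. The
bases are rescaled by exponentials anchored at each region's own radii so
that all entries stay $O(1)$ even at $\beta r \approx 80$ (raw
$I_0$/$\sinh$ would still be representable here, but the scaled form keeps
the matching system well conditioned for arbitrary parameter sweeps). The
package defaults to $\nu = 1$ because the finite-element weak forms are
assembled on the plane disc without an axisymmetric weight; the headline
plateau pressures are insensitive to $\nu$ (the plateau equals
$P_{SS,\text{viable}}$ up to an exponentially small correction either
way), and the spherical oracle is available for the 3-D reading of the
geometry.

**Critical necrotic radius.** The package operationalizes the radius at
which the plateau starts to sag as the largest $R_{nt}$ (grid
0.05…$R_{vt}-0.01$ cm, step 0.01 cm) with
$P(0) \ge (1-\varepsilon) P_{EF,\text{viable}}$, $\varepsilon = 0.01$.
The 1% criterion is this package's choice of threshold; the underlying
transition is a boundary-layer effect and any small $\varepsilon$ gives
radii within a few grid steps.

**Meshes.** Structured polar triangulations: nodes on concentric rings,
with both material interfaces placed as exact ring radii so every element
lies wholly in one region (tagged by centroid radius, half-open bins).
Adjacent rings are stitched by an angular zig-zag merge that tolerates
different node counts per ring; orientation is normalized to
counter-clockwise. Ring (arc) and radial spacings are bounded by the
requested `h_max`; the stitch diagonals can reach about 1.4 `h_max`, so
`h_max` is the nominal resolution parameter of the refinement ladder
(0.2, 0.1, 0.05, 0.03, 0.01 cm; working mesh 0.03 cm) rather than a strict
bound on every edge. Radial spacing is graded (factor 1/3 over 0.1 cm)
toward the two interfaces, where the pressure has its boundary layers.
Quadratic elements add mid-edge nodes at edge midpoints (straight-edged
$P_2$). The generator is fully deterministic.

**FEM.** Standard Galerkin with region-wise constant coefficients,
assembled in the conservative form
$\int K\nabla P\cdot\nabla u + \int \sigma P u = \int \sigma P_{SS} u$
($\sigma = L_pS/V + L_{PL}S_L/V$), whose natural interface condition is
continuity of the Darcy flux $K\,\partial P/\partial n$ — the condition
the closed form also satisfies. (Assembling the unweighted per-region
strong form would instead impose continuity of $\nabla P$ and disagree
with the physics wherever $K$ jumps.) Quadrature is exact for each
element order (3-point for $P_1$, 7-point for $P_2$). The SPD system is
solved by sparse supernodal Cholesky; the residual is checked against the
solver tolerances (residual $10^{-4}$, absolute $10^{-6}$, relative
$10^{-3}$). Velocity is recovered by consistent-mass $L^2$ projection of
$-K\nabla P$, one solve per component.

**Transport.** The same elements carry the solute equation in
non-conservative (convective) form, exactly as grouped above: the reaction
coefficient uses the divergence of the *projected discrete* velocity by
default (an `analytic` mode substitutes $\varphi_{VS}-\varphi_{LS}$, equal
in the continuum, as a consistency check). The extraction and lymphatic
coefficients are evaluated pointwise from the solved pressure at the
quadrature points. Time stepping is backward Euler by default
(Crank–Nicolson optional) with a fixed step ($\Delta t = 60$ s default,
72 h horizon); the system matrix is LU-factorized once. The mass matrix is
row-sum lumped by default: with the sharp injection front this keeps the
scheme positivity-preserving in practice (the suite checks
$C \ge -10^{-9} C_0$), at no accuracy cost visible against the
Crank–Nicolson/consistent comparisons. No SUPG stabilization is applied:
element Peclet numbers $vh/2D$ stay near or below 1 on the default mesh
for the size-swept solutes, and the low-diffusivity carriers only meet
appreciable velocity at the rim after their concentration there is
negligible. The per-step ledger accumulates
$\Delta t\,\mathbf 1^{\top}R_{\bullet}C$ for each reaction block
(extraction, lymphatic, degradation) plus the advective/divergence term,
so `mass + losses` closes to solver precision by construction; the tests
assert closure at 0.5%.

**Peclet factor.** $Pe/(e^{Pe}-1)$ is evaluated with `expm1`, a three-term
Bernoulli series for $|Pe| < 10^{-6}$ (avoids 0/0 next to the necrotic
core where $\varphi_{VS}\to 0$), and asymptotic guards beyond $|Pe| = 500$.

**Alpha sweeps.** The resistance sweeps rescale $K$ in all three regions by
$(\alpha_{base}/\alpha_{target})^2$, which scales every regional $\beta$
uniformly and leaves all $P_{SS}$ untouched. This is one consistent
reading of "varying α"; scaling only the tumor regions or scaling
$L_pS/V$ instead are others, and they give different absolute pressures at
small α. The package therefore treats swept-α pressures as qualitative
(the monotone decline is asserted; the absolute values are not).

**Particle size.** The size sweep labels particles by diameter, so a
"10 nm" particle uses $n_r = 5$ nm in Stokes–Einstein. The degradation
sensitivity grid defaults to $\tau_{deg} \in \{5.8\times10^{-4},
5.8\times10^{-6}, 5.8\times10^{-8}\}$ 1/s around the baseline, crossed
with effective diffusivities an order of magnitude either side of the
10 nm default — the grid is configurable.

## What the scenario generator does and does not emulate

The scenario presets reproduce idealized study conditions: perfectly
concentric circular regions, homogeneous per-region vasculature
($S/V$ constant), static parameters, and a uniform instantaneous
injection. Passing tests therefore demonstrate correctness of the solvers
under these idealizations — not predictive accuracy for real tumors, which
have irregular geometry, heterogeneous and dynamic vasculature,
poroelastic deformation, time-varying uptake and imperfect injections.
Velocity *magnitudes* in particular inherit the homogenized parameters;
the package asserts their location and ordering (peak at the
viable–healthy interface, decline with α) rather than absolute values.

## Verification

* The closed form is verified against an independent conservative
  finite-volume radial solver with Richardson extrapolation to
  $10^{-6}$ relative accuracy, on the baseline and on randomized
  physiologies, in both symmetries.
* The FEM is verified against the closed form: patch test (constant
  $P_{SS}$ reproduced exactly on a homogeneous disc), center-pressure
  agreement across all presets, relative $L^\infty$ at the working mesh,
  and observed $L^2$ convergence rates across the refinement ladder for
  $P_1$ and $P_2$ elements; plus symmetry (rotation invariance, radial
  velocity direction) and the discrete maximum principle.
* Transport is verified against closed forms (exponential decay;
  free-space diffusion of a disc source via numerically integrated heat
  kernels), discrete conservation, scheme cross-checks (backward Euler vs
  Crank–Nicolson, projected vs analytic divergence), and the expected
  monotonicities in particle size, degradation rate and diffusivity.

The test suite runs the transport checks at $h = 0.1$ cm with
$\Delta t = 300$ s and 24 h horizons, and the convergence ladder up to
$h = 0.01$ cm — sizes chosen so the full suite completes in about a
minute on one CPU while still resolving every regime the assertions probe.

## Known limitations

* Geometry is a 2-D disc (plane-disc weak forms); the spherical
  interpretation is available only through the radial oracle. Headline
  pressures agree between the two, but off-axis 3-D effects are out of
  scope.
* No poroelasticity, no explicit capillary network, no angiogenesis or
  vessel collapse, no plasma pharmacokinetics ($C_{PL} = 0$), no bound/free
  drug compartments or release kinetics, and no heat transfer.
* Degradation is a constant first-order rate; real uptake varies in time
  and space.
* The structured mesh generator trades generality for determinism; it
  only meshes concentric-disc geometries.
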