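---
title: "Dual charge surfaces for free energies of water and aqueous electrolytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual charge surfaces for free energies of water and aqueous electrolytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecsmc)
```

## The problem

Rigid non-polarizable water models of the TIP4P/2005 family describe the
liquid phase of water remarkably well — density, viscosity, diffusivity,
surface tension — precisely because their fixed charges are *enhanced*
relative to the isolated molecule: the enhancement mimics, in a mean-field
way, the polarization of water in the condensed phase. The price is paid in
absolute free energies. The liquid is overbound, the excess chemical
potential of water comes out roughly 10% too negative at ambient
conditions, and because the saturated vapor pressure depends exponentially
on the excess chemical potential, it comes out several times too small.
Scaled-charge ion force fields (the 0.85 e convention) have the mirror
problem: they reproduce activities and transport in solution but
underestimate hydration free energies by 20–30%.

The remedy implemented here keeps the sampling force field untouched and
introduces a *second* charge set per species, the effective charge surface
(ECS). Configurations, densities, structure and all free-energy
*differences* are generated on the potential energy surface (PES:
TIP4P/2005 charges for water, scaled charges for ions). Only the single
fractional molecule or ion group that carries the coupling parameter
$\lambda$ of a continuous fractional component Monte Carlo (CFCMC)
simulation uses the ECS charges, so absolute excess chemical potentials are
evaluated on the ECS at no additional cost. For water the ECS is the PES
charge set multiplied by a single temperature-independent factor, 0.965;
for ions the ECS charges are $\pm 0.95$ e per unit valence
($\pm 1.90$ e for divalent ions).

## The free-energy correction

Two simulations of the pure solvent at the same $T$ and $P$ (and zero
molality) give the correction for species $i$:

$$\varepsilon_i(T) \;=\; \mu^{\mathrm{ex}}_{i,\mathrm{ECS},m=0}
 \;-\; \mu^{\mathrm{ex}}_{i,\mathrm{PES},m=0}.$$

$\varepsilon_i$ enters the isolated-molecule partition function as a
background energy. It does not depend on volume or coordinates, so it
cannot change the density, pressure, structure or transport properties —
it shifts chemical potentials and nothing else. The total chemical
potential is assembled additively,
$\mu_i = \mu_i^{\mathrm{id}} + \mu_{i,\mathrm{PES}}^{\mathrm{ex}} +
\varepsilon_i$ (`corrected_mu()`).

Over 300–500 K the correction for water is an almost perfectly linear
function of temperature and is stored as the two-parameter fit
$\varepsilon_w(T) = A_0 + A_1 T$ (`fit_epsilon_linear()`, ordinary least
squares by default, optionally weighted by the reported simulation error
bars). Because the enthalpy shift implied by a chemical-potential shift is
$\varepsilon - T\,\mathrm{d}\varepsilon/\mathrm{d}T$ (Gibbs–Helmholtz),
a linear $\varepsilon(T)$ shifts the heat of vaporization by exactly
$A_0$, which is what `heat_of_vaporization_ecs()` applies.

Water activities require no correction at all:

$$k_\mathrm{B}T \ln a_w \;=\;
 \left(\mu^{\mathrm{ex}}_{w,\mathrm{PES},m} -
       \mu^{\mathrm{ex}}_{w,\mathrm{PES},0}\right)
 + k_\mathrm{B}T \ln
   \frac{\langle\rho_{w,m}\rangle}{\langle\rho_{w,0}\rangle},$$

and since $\varepsilon_w$ is molality-independent at fixed $T$ it cancels
identically in the difference. `water_activity()` realises this, and the
test suite asserts the cancellation at machine precision.

## Vapor–liquid coexistence

For a pure (or effectively pure, salt being non-volatile) water vapor over
an incompressible liquid, the coexistence pressure satisfies

$$P_\mathrm{sat} \;=\;
  \frac{\rho_L\,k_\mathrm{B}T}{\phi_w(T, P_\mathrm{sat})}\,
  \exp\!\left(\frac{\mu^{\mathrm{ex}}}{k_\mathrm{B}T}\right),$$

with the vapor fugacity coefficient $\phi_w$ from the Peng–Robinson
equation of state (critical constants for water fixed at
$T_c = 647.096$ K, $P_c = 220.64$ bar, $\omega = 0.3443$; configurable).
`solve_psat()` iterates this fixed point starting from $\phi = 1$ with a
relative tolerance of $10^{-13}$; because $\phi$ depends only weakly on
$P$ below a few bar, plain (undamped) iteration converges in a handful of
steps, and a damping factor is available for pathological inputs. At the
returned point the residual
$|\mu^{\mathrm{ex}} - k_\mathrm{B}T\ln(\phi P/\rho_L k_\mathrm{B}T)|$ is
below $10^{-10}$ kJ/mol. Liquid properties are always taken at a 1 bar
reference regardless of $P_\mathrm{sat}$ — the incompressible-liquid
assumption.

Over an electrolyte solution the water chemical potential is shifted by
$k_\mathrm{B}T\ln a_w$ before solving (`coexistence_with_salt()`); with
$\phi \equiv 1$ this multiplies $P_\mathrm{sat}$ by exactly $a_w$.

A worked number: with the liquid density 55.32 mol/L, the experimental
excess chemical potential $-26.37$ kJ/mol gives
$P_\mathrm{sat} \approx 3.5$ kPa at 300 K, while the model value
$-30.0$ kJ/mol gives a pressure smaller by
$\exp(3.63/k_\mathrm{B}T) \approx 4.3$ — the factor-of-four
underestimation that motivates the correction:

```{r psat}
p_exp <- solve_psat(300, 55.32, -26.37, phi_fixed = 1)
p_mod <- solve_psat(300, 55.32, -30.00, phi_fixed = 1)
c(P_kPa = p_exp$P_sat * 100, ratio = p_exp$P_sat / p_mod$P_sat)
```

## The CFCMC engine

The engine is a compact NPT Monte Carlo code for rigid multi-site
molecules (Rcpp):

* **Interactions.** Site–site Lennard-Jones, truncated at $r_c$ with the
  analytic homogeneous tail correction, plus Ewald electrostatics
  (tinfoil boundary) with real-space screening $\alpha$ and the
  reciprocal-space cutoff derived from a single relative accuracy target
  (default $10^{-5}$; $\alpha = \sqrt{-\ln\delta}/r_c$). Intramolecular
  pairs of rigid bodies are fully excluded. Hard overlaps return $+\infty$
  energy — a rejectable configuration, not an error.
* **Moves.** Single-molecule translations, quaternion rotations, ln-volume
  moves, $\lambda$ displacements and whole-group reinsertions, all
  Metropolis-accepted. Maximum displacements adapt toward 30–50%
  acceptance during equilibration only and are frozen for production.
  Reciprocal-space sums are updated incrementally through structure-factor
  differences; the total energy is recomputed periodically and at the end
  of the run, with the residual drift reported (typically
  $<10^{-10}$ kJ/mol).
* **Coupling path.** The fractional group's Lennard-Jones interactions
  switch on through a Beutler soft-core form over $\lambda \in [0, 1/2]$
  ($\alpha_{sc} = 0.5$); its charges then scale linearly with
  $\lambda$ over $[1/2, 1]$. The group's effective charges *are*
  $\lambda_q q$, so in-group electrostatics scale quadratically — the
  physical consequence of scaling the charges themselves. At $\lambda = 0$
  the group is an ideal-gas particle set; at $\lambda = 1$ it is
  indistinguishable from a host molecule (both endpoints are asserted
  exactly in the tests).
* **Bias.** Wang–Landau weights on (by default) 41 $\lambda$ bins: the
  ln-modification factor starts at 1.0, is halved whenever the visit
  histogram is flat to 80%, and the bias is frozen once the factor drops
  below $10^{-4}$ (and always frozen in production). Bias weights are
  defined up to an additive constant; only differences matter.
* **Estimators.** The histogram estimator
  $\mu^{\mathrm{ex}} = -k_\mathrm{B}T \ln[p(\lambda\to 1)/p(\lambda\to 0)]$
  removes the bias from the visit counts and, by default, extrapolates
  $\ln p$ linearly from the two terminal bin centers to the interval
  edges, which removes most of the $O(\Delta\lambda)$ discretization bias.
  Uncertainties come from block averages over (default 5–10) production
  blocks. An independent Widom test-insertion estimator
  ($-k_\mathrm{B}T\ln[\langle V e^{-\beta\Delta U}\rangle/\langle V\rangle]$)
  is available for cross-checks; both estimators receive the same analytic
  tail contribution for the inserted group. The two estimators measure the
  same insertion free energy only when host composition and volume match,
  so the bundled cross-check runs CFCMC with $N-1$ hosts plus the
  fractional particle and ghost-inserts into a separate $N-1$-host run in
  the same box.
* **Randomness.** One named 64-bit generator, seeded from the mandatory
  run seed; identical configuration and seed reproduce the trajectory
  bit for bit.

## What the fixtures emulate — and what they do not

The test systems are chosen so that every sampled quantity has an
analytically or numerically independent expectation: ideal-gas NPT
(density law $P/k_\mathrm{B}T$ exactly), two LJ particles (pair-distance
density by quadrature), the rock-salt charge lattice (Madelung constant),
dipole-free random charge clusters (shell-summed direct Coulomb sum),
two-state Wang–Landau toys (enumerable weight difference), dilute LJ
fluids (second-virial limit and estimator cross-agreement), and synthetic
$(T, \mu_\mathrm{ECS}, \mu_\mathrm{PES})$ tables generated from known fit
constants plus seeded Gaussian noise. Passing these shows the sampling
machinery, the estimators and the thermodynamic layer are correct. It does
*not* by itself validate force-field accuracy for real water at
production scale: converged chemical potentials of bulk water with
hundreds of molecules and long runs are a cluster-scale exercise, which is
why the full reproduction campaign is generated as a manifest
(`run_reproduction_pipeline("full")`) with the published claims attached as
comparison targets, and executed only on request.

## Problem sizes used by the bundled reproductions

The desk-scale pipeline and the acceptance script run reduced but real
simulations, sized for a single CPU: 30 ideal-gas particles; 32-particle
LJ fluids at $\rho^* = 0.25$ with $4\times10^5$ bias and up to
$2\times10^6$ production moves; bulk water with 90 molecules
($\approx 7\times10^5$ moves) for the density and heat of vaporization;
and 64 water molecules with $5\times10^6$ total moves for the CFCMC
excess chemical potential, with the cutoff capped at 0.45 box edges and
the Lennard-Jones tail correction applied. At these sizes the water
density and per-molecule energy sit within a percent or two of the
large-system values, while the chemical potential estimator delivers a
standard error near 1.7 kJ/mol — so its checks are phrased as
statistical-consistency tests at the attained precision rather than
fixed percentage bands, which at this run length would probe the seed
rather than the code.

## Numerical choices and edge cases

* Units package-wide: kJ/mol, nm, e, K, bar; constants in
  `ecs_constants()`.
* ECS charge sets are generated from the PES by a single scalar
  (`scale_charges()`), never typed independently, and are
  temperature-independent by construction — there is deliberately no
  per-temperature charge hook.
* Fractional groups must be charge-neutral under both surfaces
  (`validate_species()`); no finite-size charge corrections are applied
  because no net charge is ever created.
* Ion–water cross Lennard-Jones parameters of published scaled-charge
  force fields are bespoke; they are accepted only through explicit
  pair-override tables, with Lorentz–Berthelot as the (warnable)
  fallback.
* Degenerate inputs fail loudly: non-positive charge-scaling factors,
  fits with fewer than two distinct temperatures, empty terminal
  $\lambda$ bins, activities outside $(0, 1]$, non-positive densities.
* The Peng–Robinson solver takes the largest real root above the covolume
  as the vapor branch and warns if no such root exists (supercritical
  inputs), then proceeds with the largest real root.

## Known limitations

Cubic boxes and minimum-image only; rigid bodies only; no polarizable
energies; single-component vapor (the salt is assumed non-volatile); the
Madrid-2019 family's bespoke cross terms must be supplied by the user;
and the in-suite simulations are deliberately small — they demonstrate
correctness of the method's machinery, not converged production values.
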