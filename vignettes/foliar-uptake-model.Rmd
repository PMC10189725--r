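---
title: "Modelling droplet-to-cuticle uptake of a lipophilic agrochemical"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling droplet-to-cuticle uptake of a lipophilic agrochemical}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

When a droplet of a particulate (suspension-concentrate) formulation dries
on a leaf, evaporation-driven flow pins the contact line and deposits most
of the solid in a coffee ring, while dissolved active ingredient partitions
into the lipidic cuticle beneath the contact area. `foliarflux` implements
the simplest viable transport model of this process:

* the droplet–cuticle contact is a disk of radius $r_{dep}$ held at the
  cuticular saturation concentration $c_{sat}^{cut}$ (the dissolving
  particles and convective mixing keep the interface equilibrated, and the
  ring deposit sustains it after dry-down);
* inside the cuticle — a homogeneous slab of thickness $z_{max}$ — the
  compound moves by Fickian diffusion with coefficient $D_{cut}$, both
  longitudinally and radially;
* nothing escapes through the other faces: zero flux into the air, into
  the sub-cuticular tissue (the "wax reservoir" condition appropriate for
  a highly lipophilic compound), and at the symmetry axis.

Non-dimensionalising lengths by $r_{dep}$, time by
$t_{ref} = r_{dep}^2 / D_{cut}$ and mass by
$m_{ref} = c_{sat}^{cut}\, r_{dep}^3$ leaves a single shape parameter,
the dimensionless cuticle thickness
$Z = z_{max}/r_{dep}$ (`z_ratio` throughout the package). Maize cuticles
under sub-millimetre droplets sit near $Z \approx 10^{-4}$; the package
treats the full range from $10^{-4}$ to $10^2$.

A separate desk calculation justifies treating the contact as uniformly
saturated: dissolving particles spaced $x_{sep}$ apart develop overlapping
aqueous diffusion zones after $t \sim x_{sep}^2 / D_{aq}$, about 3 s for
the measured 17.2 µm spacing — instantaneous on assay timescales
(`overlap_time()`). The `pathway_criterion()` group
$G = D_{cut} c_{sat}^{cut} / (D_{aq} c_{sat}^{aq})$ compares direct
particle–cuticle transfer against this dissolution–diffusion route; $G<1$
predicts the indirect route dominates. Its product-ratio form matches the
symbols involved but the original criterion is defined in prior
literature, so the function documents this caveat and reports the
classification, which is insensitive to monotone rescalings.

## Limiting regimes

Four closed forms (`cottrell_rate()`, `shoup_szabo_rate()`,
`crank_rate()`, `cylinder_rate()`) bracket the simulated uptake rate
$dM/dT$ and serve as its correctness oracles:

* **Cottrell**, $A_d/\sqrt{\pi T}$ with $A_d = \pi$: 1-D diffusion from a
  saturated plane; the short-time limit of everything.
* **Shoup–Szabo**: the empirical microdisk expression for diffusion from a
  disk into a semi-infinite medium, accurate to ~0.6 %; written here in
  the deposit scaling $T = t D/r_{dep}^2$ (the chronoamperometric variable
  is $\tau = 4T$). Its long-time limit is the steady disk rate 4. The edge
  term exceeds Cottrell by $\approx 1.77\sqrt{T}$, so the two agree within
  0.5 % only for $T \lesssim 8\times10^{-6}$.
* **Crank plane sheet**: saturated face, impermeable back; two
  co-convergent series, the image series fastest for $T < Z^2$ and the
  eigenfunction series for $T > Z^2$ (ties go to the first). Terms are
  summed until the next falls below $10^{-12}$ of the partial sum; at the
  crossover both series give flux density $0.16961/Z$ to machine
  precision, which the tests assert.
* **Cylinder**: once the slab below the disk saturates (nominally at
  $T \sim 0.5\,Z^2$, `transition_time()`; the rate there is
  $\approx 0.73\times$ Cottrell, a scale-invariant theta-series value),
  uptake continues only by radial diffusion from the saturated rim — a
  cylinder of unit radius and area $A_c = 2\pi Z$. Rather than adopt one
  of the several published coefficient sets for cylinder
  chronoamperometry, the package inverts the exact Laplace-domain solution
  $\bar f(s) = K_1(\sqrt s)/(\sqrt s\,K_0(\sqrt s))$ numerically
  (Gaver–Stehfest, $N=16$, evaluated with exponentially scaled Bessel
  functions). This is accurate to well under 1 % across at least
  $T \in [10^{-8}, 10^6]$ and is validated in the tests against an
  independent finite-difference solver of the exterior-of-cylinder
  problem.

For thin cuticles ($Z \le 0.05$) `composite_rate()` gives the whole curve
without simulation as the **sum** of the Crank and cylinder rates — a
planar-plus-edge decomposition with the same structure as Shoup–Szabo
(Cottrell term plus edge term). A pointwise maximum of the two limits was
considered and rejected: in the crossover window ($T$ a few $Z^2$) the rim
flux has not yet reached its saturated-cylinder form while the planar flux
is already collapsing, and the maximum runs tens of percent low there,
whereas the sum stays within about 5 % of the simulator for $Z = 0.01$
(worst errors +2.7 %/−4.2 % in the crossover; the short-time excess is
$2Z$ relative).

## The simulator

`simulate_uptake()` solves the dimensionless axisymmetric diffusion
equation with a conservative finite-volume discretisation on a
tensor-product grid:

* **Radial grid**: nodes exactly at $R=0$ and $R=1$; spacing `h_min`
  (default $\min(Z/4, 10^{-3})$) at the disk edge where the flux is
  singular, expanding geometrically (factor 1.15 by default, capped at
  1.25) toward the axis and the outer truncation
  $R_{max} = 1 + 6\sqrt{T_{end}}$, which the diffusion front cannot reach.
* **Depth grid**: uniform with at least `n_z` = 12 layers when that
  resolves the first reported time; for thick slabs it instead expands
  geometrically from the contact face with first spacing
  $\approx 0.4\sqrt{T_{start}}$, since a uniform grid fine enough for the
  early boundary layer would need millions of nodes at $Z = 10$.
* **Time stepping**: log-spaced schedule (60 steps per decade by default)
  started two decades before the first reported time so start-up error has
  decayed; variable-step BDF2 (a backward-implicit scheme, started with
  backward Euler) for second-order accuracy on the slowly varying
  log-time transients.
* **Linear solves**: sparse LU factorisation (Matrix); `step_implicit()`
  verifies a $10^{-10}$ relative residual. Any solver meeting that
  contract would do; Krylov iteration buys nothing at these sizes
  (typically $10^3$–$10^4$ unknowns).
* **Saturation deficit**: the marched variable is $1-C$, not $C$. Once the
  slab approaches saturation, $C$ sits within $\sim 10^{-12}$ of 1 and
  boundary fluxes formed from differences of $C$ lose every significant
  digit; the deficit keeps full relative precision, which matters when
  tracking the exponentially decaying plane-sheet tail.
* **Rates and mass balance**: the reported `rate` is the instantaneous
  finite-volume flux through the saturated boundary; a central-difference
  rate of $M$ on the log grid is kept as `rate_m`, and the run aborts if
  cumulative influx and $M(T)$ disagree by more than 1 % at any reported
  time. All fields are double precision.

`simulate_1d()` is the plane-sheet analogue (the whole face saturated, no
radial transport), used as the numerical counterpart of the Crank series.
One extra control matters there: a log schedule alone cannot track a pure
exponential decay, because late steps grow like $T$ while the decay time
stays $4Z^2/\pi^2$; the 1-D mode therefore caps the step at $0.005\,Z^2$
(and uses a 150-node depth grid), which brings it within 0.1 % of the
series out to $T = 10 Z^2$.

Measured against the oracles (and re-measured by the test suite and
`scripts/acceptance.R` on every run): the 2-D simulator at $Z=10$ tracks
Shoup–Szabo within 0.9 % over $T \in [10^{-4}, 10^2]$; the 1-D mode
tracks Crank within 0.1 %; the thin-cuticle long-time rate sits within
0.3 % of the cylinder solution.

## Scaling and inference

`dimensionalize()` / `nondimensionalize()` convert between the
dimensionless curve and laboratory units ($t = T\,t_{ref}$, array mass
$= n_{droplets}\, m_{ref}\, M$), treating the droplets of an array as
independent (they are applied ≥3 mm apart for exactly this reason). ppm is
read as mass per volume, g m⁻³ (mg L⁻¹), consistent with a cuticle
density near 1 g cm⁻³ — the convention that makes $m_{ref}$ dimensional.

`fit_uptake()` infers $(t_{ref}, m_{ref})$ — hence
$D_{cut} = r_{dep}^2/t_{ref}$ and $c_{sat}^{cut} = m_{ref}/r_{dep}^3$ —
by least squares of the leaf-extract masses against
$n\,m_{ref}\,M(t/t_{ref})$. Because the two scales act orthogonally (time
stretch and mass stretch), the master curve is simulated once per
geometry and only re-interpolated (monotone cubic in log–log; Cottrell
slope-½ extrapolation below the grid, a hard refusal above it).
Optimisation is in $(\log t_{ref}, \log m_{ref})$ — positivity for free —
by Levenberg–Marquardt, started from a coarse grid in $\log t_{ref}$
where the conditionally optimal $m_{ref}$ is closed-form; this start is
global enough that the local refinement never strands. Standard errors
come from the linearised covariance $s^2 (J^\top J)^{-1}$ with a
finite-difference Jacobian, and 95 % intervals are formed on the log
scale.

Weighting: the default is unweighted least squares, since real assay
noise structure is rarely known. When the noise **is** known to be
multiplicative with constant CV — as for the package's own synthetic
assays — `weights = "multiplicative"` performs one model-based
reweighting pass (refit with $1/\hat\mu_i^2$), the generalised
least-squares choice. The distinction is not cosmetic: under 10 %
multiplicative noise the unweighted fit's intervals jointly cover the
truth in only ~82 of 100 synthetic assays (the heavy late-time masses
dominate the pooled variance), while the reweighted fit covers in ≥90
with z-score spread ≈1.08. Weighting by *observed* masses instead of
fitted ones was rejected: the weights then correlate with the noise and
bias the mass scale downward.

## The synthetic assay generator

`gen_assay()` emulates the destructive droplet-array assay the fitting
module expects: 20 droplets of 0.2 µL at 375 ppm per leaf (1.5 µg
applied), one leaf per record, two batches of three replicates per time
point, twelve time points dense within the first hour and sparse to
24 h. The forward model is the package's own dimensionless curve; noise
is multiplicative lognormal with mean 1 and CV 0.10 by default (the
replicate scatter of such assays is proportional to signal; the original
study reports standard errors, not a noise law, so the CV is a chosen,
fixed convention). The noiseless compartments close exactly on the dose
(surface wash = dose − uptake), and a seed fixes the output bit-for-bit.

What the generator does **not** emulate — and hence what passing
recovery tests cannot show about real data: droplet evaporation and the
coffee-ring flow itself (only their end state enters, through the
saturated-disk boundary), any boundary change at dry-down, timing
uncertainty at short exposure times, incomplete extraction recovery,
between-plant or between-variety biological variability, and sub-cuticle
penetration. `gen_deposit()` similarly perturbs a deposit-observation
template lognormally per field while re-imposing the area-closure and
fraction invariants.

## Deposit arithmetic conventions

`deposit_metrics()` and friends use: per-particle mass = volume × solid
density (1 µm³ at 1 g cm⁻³ = 1 pg exactly); a square-lattice convention
for converting surface density to interparticle spacing (hexagonal
available; the convention is not determined by the data); ring area =
fraction × total area, so a small closure mismatch between independently
measured areas is absorbed rather than propagated; the ring surface
density is an input, not recomputed, because its published derivation
runs through the uptake assay itself.

## Problem sizes and reproducibility

The test suite and acceptance script size their simulations to run in a
few minutes on one core: the $Z=10$ validation uses ~360 reported times
on a ~6×10³-node grid; the thin-cuticle and maize-geometry ($Z =
1.1\times10^{-4}$) masters use ~10³-node grids over 6–7 decades of
dimensionless time; parameter-recovery studies use 100 seeded assays of
72 records each. Grid-refinement tests double `n_z`, halve `h_min` and
double the step density and require $M(T_{end})$ stable to 0.5 %. All
randomness flows through explicit seeds.

## Known limitations

The contact radius is constant (pinned) and the saturated-disk boundary
is held for all fitted times; systems that dry down long before
longitudinal saturation, depositing isolated particles with no
co-deposited film, would need a different boundary condition. The cuticle
is a homogeneous slab: cuticular pegs (locally deeper cuticle between
epidermal cells) add uptake volume the model ascribes to
$c_{sat}^{cut}$, inflating it. Converting $c_{sat}^{cut}$ to a partition
coefficient (`csat_to_kcw()`) requires an aqueous solubility the user
must supply. The Stehfest inversion, while ample here, loses accuracy
beyond ~$10^{-4}$ relative and would not suit oscillatory transforms.
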