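---
title: "Multimedia mass-balance modelling of nano- and microplastic fate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimedia mass-balance modelling of nano- and microplastic fate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasticfate)
```

## The model

`plasticfate` implements a multimedia "unit world" mass balance for nano-
and microplastic particles.  The environment is partitioned into
well-mixed compartments — air, freshwater and seawater with their
sediments, and natural, agricultural and industrial soils — over three
nested spatial scales (an industrialised region inside a continental
system inside a global system).  In every compartment the plastic exists
in exactly three particulate species forms:

* **free** — the pristine particle;
* **colloid heteroaggregate** — attached to a natural colloid (or fine
  aerosol in air);
* **coarse attached** — attached to coarse suspended particulate matter
  (SPM) in water, coarse aerosol in air, or immobile grains in soil and
  sediment.

The state vector `m` holds the plastic mass in each (compartment, form)
pair.  Every process is a first-order rate constant, so the model is the
linear compartmental system

$$\frac{dm}{dt} = A\,m + e,$$

with `A` a Metzler matrix (non-negative off-diagonals = transfer
constants, non-positive diagonals = total outflow per state, column-sum
deficit = pure removal) and `e` the emission vector, which loads the
*free* species only (releases are of pristine beads).  The steady state
is `m = -A^{-1} e`, solved by dense LU factorisation with one step of
iterative refinement; a system in which some emitted mass has no removal
path is reported as an explicit "no steady state" error rather than a
number.

### Process rate constants

The rate constants follow the standard multimedia-particle formulations;
every adopted constant is an overridable configuration value.

* **Settling/sedimentation.** Stokes' law
  `v = 2 g r^2 (rho_p - rho_m) / (9 mu)`, with two deliberate choices:
  (i) particles lighter than the medium do *not* settle — the velocity is
  clamped to zero, continuously in the density difference; (ii) by
  default the assembly applies a Schiller–Naumann drag correction
  (`C_d = 24/Re (1 + 0.15 Re^{0.687})`, fixed-point iterated), because
  the largest modelled beads (625 µm) are far outside the creeping-flow
  regime in air (Re ≈ 100; pure Stokes would predict ~50 m/s deposition
  velocities).  `drag_model: stokes` in the landscape file restores the
  uncorrected law.  `k_sed = v / depth`, into the partner sediment, same
  species form.
* **Heteroaggregation.** Pseudo-first-order attachment of the free
  species: `k_het = alpha_het × K_coll × n_host`, with the collision rate
  coefficient `K_coll` the sum of the Brownian
  (`2 k_B T (r_1+r_2)^2 / (3 mu r_1 r_2)`), laminar-shear
  (`4/3 G (r_1+r_2)^3`) and differential-settling
  (`pi (r_1+r_2)^2 |v_1 - v_2|`) kernels.  Natural-particle
  concentrations are treated as fixed landscape properties, attachment is
  irreversible, and the aggregate of one bead and one host is represented
  as the volume-equivalent sphere (`r^3 = r_b^3 + r_h^3`) with the
  volume-weighted mean density.  This 1:1 composition is what produces
  the emergent settling cutoff for buoyant beads: with SPM of radius
  3 µm and density 2500 kg/m³, a bead of polymer density `rho_p < rho_w`
  sinks once aggregated only if its radius is below
  `r* = 3 ((2500 - rho_w)/(rho_w - rho_p))^{1/3}` µm — about 10 µm at
  rho_p = 960, diverging as rho_p approaches the water density.
* **Atmospheric deposition.** Dry deposition velocity = gravitational
  terminal velocity in air plus a Brownian diffusion term `D/delta`
  across a laminar boundary layer (default 1 mm); wet deposition = rain
  rate × scavenging ratio (default 2×10⁵) / mixing height.  Both are
  apportioned over the underlying surfaces by area fraction, preserving
  the species form.
* **Soil–water exchange.** Mobile species (free, colloid-aggregated) run
  off with surface water, `k_runoff = f_runoff × rain / (depth × theta)`;
  the grain-attached form moves only with eroded solids,
  `k_erosion = v_erosion / depth`.  Mobile species also attach to soil
  grains at `alpha_het × k_att` (collision-limited default
  `k_att = 10⁻⁴ s⁻¹`), which is what builds up the immobile soil stock
  whose removal is dominated by fragmentation.
* **Sediment–water exchange.** Resuspension is closed against the
  natural-solids balance of the overlying water: gross SPM settling flux
  minus net accretion flux returns to the water column;
  `k_burial = v_accretion / depth` is a permanent sink.
* **Fragmentation/degradation.** Pure first-order removal (`k_frag +
  k_deg` per broad medium class); the lost mass is not tracked as smaller
  particles.  Air is always zero — atmospheric residence is far too
  short.
* **Advection.** Every air–air and water–water link contributes
  `k = Q / V_source` to all three forms.  The sea scales exchange in both
  directions (river through-flow plus ocean-current return), so the
  global ocean is a reservoir that feeds back, not a one-way sink.

### Solvers

Steady states use base `solve()` (LAPACK) with an equilibrated condition
estimate; condition numbers above 10¹⁵ raise the documented
`plasticfate_singular` error — exactly the situation created by zeroing
all removal constants for a buoyant bead above the settling cutoff.
Dynamic solutions use the closed form
`m(t) = m_inf + V e^{Lambda t} V^{-1} (m_0 - m_inf)` through the
eigendecomposition of `A` when `A` is invertible and well conditioned,
and otherwise `deSolve::lsoda` with the analytic Jacobian (= `A`); the
time constants of the full landscape span more than fifteen orders of
magnitude, so a stiff integrator is essential.  "Time to steady state"
is operationalised as the first time the observed compartment reaches
95% of its asymptotic mass (the threshold is an argument), located on a
logarithmic grid and refined by bisection to 1% relative precision.

### Concentrations

Masses convert to PECs per compartment and species: mass per volume in
air and water, mass per kg dry weight in soils and sediments (mass /
(volume × dry bulk density)).  Number concentrations divide by the mass
of one bead, `rho_p (4/3) pi r^3` — the tracked mass is plastic mass
only, so the same conversion applies to aggregated forms.  The total
particulate PEC is the exact elementwise sum of the three species.

## The landscape fixture

The packaged default landscape (`inst/extdata/landscape_default.yaml`)
follows the EUSES regulatory conventions the case study adopts: a
200 × 200 km industrialised region (3% freshwater at 3 m depth, 27/60/10%
natural/agricultural/industrial soil at 5/20/5 cm mixing depth, 3 cm
sediments, 700 mm/y rain of which 25% runs off, 285 K), nested in an
EU-sized continental system and a moderate-zone global system with air,
seawater, marine sediment and soil only.  There is no lake compartment.
Values the conventions do not fix — coastal and shelf sea geometry, the
air and ocean exchange flows (3 m/s wind; ~100-day regional-sea and
~3-year shelf residence; a 3.1×10⁶ m³/s ocean return current), and the
natural-particle loads (15/5/1 mg/L SPM in fresh/shelf/ocean water,
colloid and aerosol number concentrations) — are package defaults chosen
at realistic magnitudes and documented in the fixture file.  Only the
SPM class is fixed by the study itself (radius 3 µm, density
2500 kg/m³).

## The stochastic scenario

The microbead case study samples, per Monte Carlo iteration:

| input | distribution | source of the values |
|---|---|---|
| radius | Uniform(1, 625) µm | study range |
| polymer density | Uniform(854, 1302) kg/m³ | study range |
| attachment efficiency | log-Uniform(10⁻⁴, 1) | study range; log scale is this package's reading of a four-order-of-magnitude "probabilistic" range (a `scale: linear` switch reproduces the other reading) |
| k_frag (water, sediment, soil independently) | Triangular(1.6×10⁻⁹, 2.7×10⁻⁸, 1.3×10⁻⁷) s⁻¹ | study values |
| k_deg (per medium) | Triangular(3×10⁻¹¹, 3×10⁻¹⁰, 3×10⁻⁹) s⁻¹ | synthetic stand-in |
| STP efficiency | Triangular(0.85, 0.95, 0.99) | synthetic stand-in |
| sector tonnages | Triangular(low, best, high) t/y per sector/route/scale | synthetic reconstruction |

Triangular draws use the inverse CDF of uniform variates, so a fixed
seed reproduces the full input tables bit-identically.  Sewage-routed
mass is split by the sewage treatment plant: `1 − efficiency` to
freshwater with the effluent, `efficiency × 0.5` to agricultural soil
with applied sludge, the remainder leaving the system; tonnages convert
to kg/s with the Julian year.

**What the synthetic emission table does and does not emulate.** The
original sector inventory is a supporting-information table that is not
part of the sources packaged here.  The shipped table keeps its
structure — six sectors (PCCP, paints and coatings, soaps/detergents,
abrasives, agriculture, oil and gas), routes to air, direct freshwater,
sewage, industrial and agricultural soil, an industrially dominated
regional mix against a more balanced continental mix, and wide
low/best/high ranges dominated by the abrasives-to-air route — with
magnitudes set once to plausible EU values (regional best estimates of
order 1–40 t/y, continental 50× larger).  Consequently the emergent
*ratios between compartments* and the *mechanistic* sensitivities
(density, radius, fragmentation constants) are meaningful reproductions,
while sensitivities to individual emission terms depend directly on the
relative widths of these synthetic triangles and are only qualitatively
comparable.  Passing tests on this scenario therefore demonstrate the
engine and the mechanism rankings, not the original inventory.

## Monte Carlo, summaries, sensitivity

`run_monte_carlo()` draws all input tables up front under one seed, then
per iteration assembles the system (a particle-independent context is
precompiled per landscape), solves the steady state and stores
per-compartment mass and number PECs split by species.  Iterations whose
system has no steady state are recorded as failures with `NA` outputs —
never dropped — and more than 1% failures aborts the run by default.
Summaries are empirical percentiles (linear interpolation of order
statistics; conventionally the 50th with a 5th–95th range) and Spearman
rank correlations between each input and the total PEC of a target
compartment; an input with zero variance yields `NA`, not 0, because "no
association" is a different claim from "undefined".

The zero-removal counterfactual re-solves one sample with
`k_frag = k_deg = 0`.  For buoyant beads above the settling cutoff this
system is *exactly singular*: fragmentation/degradation is the only
parameterised removal from the connected water cycle, advection merely
circulates mass between the scales, and the ocean return flow prevents
the global ocean from acting as a sink.  The package reports the
documented no-steady-state error together with the dynamically
integrated mass at a finite horizon (default one million years), at
which point the global-ocean burden is already ~7 orders of magnitude
above the default steady state and still growing linearly.  Any finite
"zero-removal steady state" can only be the artefact of a tiny residual
removal, which is why none is fabricated here.

## Problem sizes and numerical choices

The default landscape has 20 compartments = 60 states; assembly takes
~4 ms and a steady solve ~1 ms, so the standard study size of
n = 10,000 iterations completes in well under a minute.  The test suite
uses the same n = 10,000 for the emergent-behaviour checks and small
n for the mechanical ones.  Tolerances: steady-state residual ≤ 10⁻¹⁰
of the emission norm; flux closure (emissions = removals at steady
state) ≤ 10⁻⁹ relative; dynamic/steady agreement at long times ≤ 0.1%;
matrix-exponential cross-checks at 10⁻⁸ on ≤ 9-state random
compartmental systems.  Roundoff-negative masses below 10⁻¹⁰ of the
maximum are clamped to zero; anything more negative is an error.  Ties
in Spearman ranks receive average ranks (`stats::cor`), and percentiles
use the default linear interpolation of order statistics (type 7).

## Known limitations

* **Pseudo-first-order aggregation.** SPM is never depleted by the
  beads.  The size dependence of sediment delivery among buoyant beads
  that the original study attributes to the SPM-to-bead *number ratio*
  is a depletion effect and therefore outside this model class: here the
  coefficient among delivering buoyant beads is negative (near the
  cutoff, the aggregate's excess density — and with it the settling rate
  — falls with radius).
* **The settling cutoff is density-dependent.** `r*` diverges as the
  polymer density approaches that of water, so "the largest buoyant bead
  that reaches the sediment" across a 10⁴-sample uniform density draw is
  an extreme-value statistic, seed-dependent and consistently above
  the ~10 µm representative cutoff; the sharp per-sample criterion
  `r < r*(rho)` itself is exact and is what the tests assert.
* **Direction of the freshwater–density association.** Denser beads
  settle out of the water column faster, so the freshwater PEC falls
  with density here (rho ≈ −0.8); the reported positive coefficient of
  the original study is reproducible in magnitude but not in sign under
  the stated mechanics.
* No homoaggregation, shape corrections (fibres, films), dissolution,
  biotic processes, sea spray or beaching; fragmentation is pure removal
  rather than a source of smaller size classes; emissions are constant
  in time; the landscape is not spatially explicit and properties are
  temperature-independent.

## Reproducing a run

```{r example, eval = FALSE}
landscape <- default_landscape()
scenario  <- default_scenario()
run <- run_monte_carlo(landscape, scenario, n = 10000, seed = 1)
percentile_summary(run)
spearman_sensitivity(run, "regional_freshwater_sediment")
autoplot(run)
```

`scripts/acceptance.R` wraps exactly this sequence and writes the
summary quantities as JSON; the README describes how to run it.
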