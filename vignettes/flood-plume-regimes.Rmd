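---
title: "Sediment-laden flood plumes: model, scenario and diagnostics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sediment-laden flood plumes: model, scenario and diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A flooding river discharges freshwater, suspended sediment matter (SSM) and
nutrients into a stratified coastal sea. Freshwater alone always forms a
buoyant (hypopycnal) surface plume. SSM adds to the bulk density of the
river water, and depending on its amount and grain size the plume can switch
regime:

* **hypopycnal** — river water stays lighter than seawater; SSM settles out
  quickly, the river–sea density contrast is reduced, the estuarine exchange
  circulation weakens, and the surface plume becomes *fresher* and more
  nutrient-retentive than it would be without SSM;
* **hyperpycnal / homopycnal** — with enough fine sediment the river water is
  as dense as or denser than seawater; it sinks or drives vigorous vertical
  mixing, leaving the surface *saltier* and (when river water is the nutrient
  source) nutrient-poorer, while water from below — including the sub-surface
  chlorophyll maximum — is brought up.

`floodplume` reproduces this mechanism at desk scale: a 2-D vertical-slice
(x–z) ocean model along the plume axis, coupled to Rubey settling of one
sediment class and a nitrogen-based NPZD ecosystem, driven by a synthetic
flood scenario, and analysed with plume-masked difference diagnostics against
a reference run without SSM (WOS). Everything is generated in code; no
external data are required.

## The dynamical core

The solver integrates the Boussinesq equations on a staggered
finite-volume slice grid (tracers at centres, `u` on x-faces, `w` on
z-faces; z positive up, layer 1 at the surface; flat bottom):

* **Equation of state.** Linear in temperature and salinity, plus the
  volume-weighted sediment contribution
  \(\rho = \rho_w(T,S) + (1-\rho_w/\rho_{sed})\,C\). The crossing
  concentration \(C^\*\) at which fresh river water matches ambient density
  is analytic (`crossing_concentration()`), which anchors the regime
  diagram's density-difference axis.
* **Momentum.** Upwind advection, constant eddy viscosities, buoyancy
  relative to the ambient profile, optional Coriolis coupling. The
  buoyancy restoring force on `w` is treated implicitly per face
  (`w' = (w + dt\,F)/(1 + dt^2 N^2)`, the backward-Euler solution of the
  local buoyancy oscillation), so unresolvable internal-wave frequencies are
  damped and the time step is not bound by `N dt <= 2`.
* **Pressure.** Rigid-lid projection onto the discretely divergence-free
  subspace. The volume-weighted Poisson operator is symmetric positive
  definite and factored once per run (sparse Cholesky); each projection is a
  pair of triangular solves, and the residual divergence is at round-off
  (~1e-14 1/s). Tides are neglected, so a rigid lid loses nothing and removes
  the surface-gravity-wave CFL limit. The sea-surface elevation is diagnosed
  from the surface pressure.
* **Tracers.** Unsplit flux-form upwind with a van Leer harmonic-mean limited
  correction: monotone, positivity-preserving at the operating CFL, exact for
  a uniform shift at CFL 1, and conservative to round-off. Explicit centred
  diffusion is fused into the same flux pass.
* **Vertical mixing.** Two parts. (i) A Richardson-number closure on tracer
  faces, `Kv = Kv_bg + Kv_shear/(1+5 Ri)^2` (Pacanowski–Philander form):
  mixing is carried by the *shear* of the exchange circulation, which is the
  pathway through which SSM-weakened circulation reduces the salt supply to
  the plume — the hypopycnal mechanism. A constant-coefficient closure
  cannot express it (SSM could then only ever add mixing). (ii) Convective
  adjustment wherever the column is statically unstable, with a
  displacement-dominant treatment (`convect_mix = 0.3`): 30% of each
  overturning event homogenises the pair, 70% swaps the parcels. The swap
  limit represents what a non-hydrostatic model resolves — river water
  plunging to its level of neutral buoyancy *without* entraining deep salt —
  and matters for marginal (near-crossing) SSM loads; pure homogenisation
  over-salinifies the surface there.
* **Boundaries.** River inflow enters the first column over the top two
  layers (2 m) with prescribed velocity and concentrations; the offshore face
  is open (zero-pressure ghost column) with a 6-column sponge relaxing
  tracers to the ambient profiles; lid and floor are impermeable free-slip.
* **Time stepping.** Explicit, adaptive: `stable_dt()` takes the minimum of
  the advective CFL (settling speed included), the explicit-diffusion bound
  and the horizontal internal-wave CFL, times a safety factor of 0.4, with a
  120 s cap and a discharge-dependent cap from the mouth-mixing diffusivity.
  The scheme is forward-backward (velocities first, tracers with the new
  velocities). Fully deterministic — there is no random number in the core.

### Sediment

One grain-size class per run (the sensitivity design varies one diameter per
case). The settling speed comes from Rubey's relation, which bridges Stokes'
law for fine grains and the inertial \(\sqrt{(2/3)\,g d (s-1)}\) limit for
coarse ones. Settling is a flux-capped downward upwind pass; the flux
through the sea floor accumulates in a deposition ledger and never returns
(no resuspension), and the ledger participates in the SSM mass-closure audit
(riverine input = water-column inventory + deposit + boundary/sponge export,
to round-off). Validity requires `C << rho_sed`; there is no flocculation or
hindered settling.

### Ecosystem

Nitrogen-currency NPZD with declared, literature-style forms:
Michaelis–Menten nitrate uptake with an Eppley temperature factor
`exp(0.0693 T)` and a Steele optimum-light factor (optimum 65 W/m²); Ivlev
grazing with a threshold; linear mortalities; detritus remineralisation;
detritus sinks through the same settling machinery and its sea-floor flux is
remineralised into the bottom cell, so total nitrogen is closed exactly.
The four tendencies sum to zero by construction. Light attenuates with
water and phytoplankton self-shading only — SSM shading is deliberately
excluded. Riverine phytoplankton, zooplankton and detritus are zero (river
water carries no marine plankton), riverine nitrate is 0.046 mol/m³ at the
standard setting. `Vmax = 0.4`/day (at 0 °C) makes a bloom take roughly five
days or more to form, the timescale the scenario assumes; chlorophyll is
reported as 1.59 µg chl.a per µmol N (Redfield C:N with C:chl = 50 g/g).

Because nothing in the physics feels the biological fields, one physical
integration can carry several independent biological "stacks", one per
riverine-nutrient multiplier. A sweep over nutrient input therefore costs
one run per (SSM load, diameter) cell, and the reference run serves every
multiplier at once.

## The synthetic scenario

The generator emulates the structural features the analysis assumes — it is
the package's data source, not a fixture:

* **Hydrograph.** Constant base flow 62.46 m³/s (an annual mean) with a
  compact raised-cosine flood pulse: peak 3000 m³/s at t = 36 h, 12 h rising
  limb, 24 h falling limb, run window 120 h (more than three days past the
  peak). The pulse is exactly base flow outside its support and its volume
  has a closed form.
* **Riverine concentrations.** Nutrient input `0.046 × nutrient_mult`
  mol/m³. SSM follows a rating curve `C = a Q^b` (b = 1.2) scaled by the SSM
  multiplier, parameterised by its value at peak flow, 8.2 kg/m³. That value
  is a documented *calibration*: it puts the river–sea density crossing
  between 4 and 6 times the standard load at peak discharge — the structure
  the regime diagram requires — and gives a roughly symmetric ±25 kg/m³
  density-difference axis. It is not an observed value.
* **Initial ocean.** Warm fresh mixed layer over colder saltier water (tanh
  pycnocline at 6 m), nutrient-depleted surface over a nutrient-rich
  sub-surface (nutricline at 8 m), and a Gaussian sub-surface chlorophyll
  maximum just below the pycnocline (8 m, 3 µM N ≈ 4.8 µg/L chl.a). The
  column must be statically stable or the generator refuses it.
* **Slice mapping.** The slice represents the along-axis direction with an
  effective river width of 18 km (the bay width): that choice absorbs the
  lateral spreading a slice cannot represent and keeps the flood's freshwater
  volume per unit width small enough that the plume stays inside the 15 km
  domain. Near-field dilution at the mouth — the lift-off jet no 250 m grid
  can resolve — is parameterised as extra vertical diffusivity over the
  first two columns, `Kv = 0.02 u_in h`, scaling with the inflow speed.
  Without it the near-mouth pool is pure river water and the regime
  transition happens far below the density-crossing multiplier.
* **Case grid.** The Cartesian product of SSM multipliers (0–10×),
  diameters, and nutrient multipliers (0–10×), plus one reference (WOS) per
  distinct nutrient multiplier; a grid shaped like the full study
  (6 × 5 × 5) yields 155 cases. The marked typical cases are
  (4×, 0.05 mm, 1×) for hypopycnal and (10×, 0.01 mm, 1×) for hyperpycnal.
* **Spinup.** Two days under constant base flow from the analytic profiles
  (scaled down from the full study's 60 days; acceptance is judged on
  quasi-steadiness, not duration). One spinup is shared by every case of a
  sweep.

Everything is a pure function of the configuration: identical configurations
give bitwise-identical forcings and trajectories.

## Diagnostics

The plume is the set of surface cells (top two layers, ≈ 2 m) with salinity
≤ 28 (the threshold value itself is inside). Two masking conventions exist:
per-case masks (each run masked by its own salinity) and a fixed reference
mask. The default is the *reference* mask, because a hyperpycnal case can
sink its entire surface lens — its own mask then vanishes exactly when the
response peaks, leaving the difference series undefined; the fixed mask of
the matched reference run keeps it measurable. Plume means are
volume-weighted; empty-mask times are missing values, excluded from
extremum searches.

`difference_series()` joins a case and its reference at matched output times
and forms ΔS, ΔN, ΔP, reporting each difference's extremum (value and time
of maximum magnitude) and, separately, the differences at the time the
reference plume is largest. `flood_response()` condenses one case into the
regime quantities: the ΔS extremum and its lag behind the discharge peak,
ΔN and ΔP evaluated *at that moment* (the nutrient and plankton fields'
own extremum times are contaminated at desk scale by slow late-window bloom
drift, so the structural signs are read off when the SSM–physical
interaction is strongest), and the three-day decay fraction — a plume that
has dissipated by then has trivially decayed to zero.

`build_regime_map()` assembles the ΔS-at-extremum heat map over the
(SSM multiplier × diameter) sweep, labels each cell hypopycnal / neutral /
hyperpycnal (±0.01 psu neutrality band to absorb numerical noise), and
reports the per-diameter transition interval — the bracketing multipliers
where the sign flips. `river_density_difference()` provides the
diameter-independent density-difference axis.

## Numerical and design notes

* Problem sizes: 60 × 12 cells (15 km × 20 m, 1 m surface layers), hourly
  outputs, ~5000–11000 adaptive steps per 120 h run, a few tens of seconds
  per case; the full sweep (18 SSM cases + reference, three nutrient stacks)
  runs in roughly a quarter of an hour.
* Budgets are audited by integrating exactly the fluxes the code applies
  (river inflow, open-boundary outflow, sponge exchange, deposition);
  closure residuals are at round-off and any positivity clipping is logged
  and must stay below 1e-12 of inventory.
* The per-variable extremum convention, the reference-mask default, and the
  displacement-dominant convective treatment are the three places where two
  defensible readings existed; the alternatives remain available
  (`mask_source = "per-case"`, `convect_mix = 1`) and are exercised in the
  tests.

## What passing tests do and do not show

The generator produces one idealised flood in one idealised stratified
basin. Passing tests demonstrate the *mechanism*: the sign structure
(hypopycnal cases freshen and enrich the plume, hyperpycnal cases salinify
and deplete it, plankton gains in both while the interaction acts), the
roughly order-of-magnitude asymmetry between the regimes, the timing
ordering (hyperpycnal response at the peak, hypopycnal lagging), the decay
of the interaction within days, and exact conservation throughout. They do
not show quantitative skill for a real bay: a 2-D slice cannot dilute SSM or
the freshwater anomaly laterally, so the scaled difference magnitudes run
several-fold stronger than a full 3-D hindcast's plume means, and
wind, tides, rotation of the real flow, resuspension and sediment light
shading are all absent by design.

```{r example}
library(floodplume)
cfg <- fp_config()
sweep <- run_sweep(cfg, case_grid(c(1, 4, 10), c(0.01e-3, 0.05e-3), 1))
autoplot(sweep$regime_map)
flood_response(sweep$runs$series[[which(sweep$runs$ssm_mult == 4 &
                                        sweep$runs$diameter == 0.05e-3)]],
               cfg$river$t_peak)
```
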