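# floodplume

Desk-scale simulation and analysis of what suspended sediment matter (SSM)
does to a flooding river plume in a stratified coastal sea — and to the
surface salinity, nutrients and phytoplankton inside it.

During a flood, river water carries enough mineral sediment to change its
bulk density appreciably. With coarse grains or moderate loads the sediment
settles out fast, the river–sea density contrast shrinks, the estuarine
exchange circulation weakens, and the surface plume ends up *fresher* and
more nutrient-retentive than it would be without sediment (a **hypopycnal**
response). With fine grains or heavy loads the river water becomes as dense
as or denser than seawater: it plunges or drives vigorous vertical mixing,
the surface plume ends up *saltier* and nutrient-poorer, and water from the
sub-surface — including the chlorophyll maximum — is brought up (a
**hyperpycnal / homopycnal** response). The package reproduces this regime
switch and measures it the way such studies do: every case is differenced
against a reference run *without* SSM (WOS) inside a plume mask (top ~2 m,
salinity ≤ 28), and a sensitivity sweep over SSM load × particle diameter
is condensed into a regime map.

The pieces, all in R with no external data:

* a 2-D (x–z) non-hydrostatic Boussinesq slice solver with rigid-lid
  pressure projection, limited-upwind tracer transport, a
  Richardson-number vertical mixing closure, convective adjustment, and an
  SSM-aware equation of state
  `ρ = ρ_w(T,S) + (1 − ρ_w/ρ_sed)·C`;
* Rubey (1933) settling,
  `w_s = F·sqrt(g d (s−1))`,
  `F = sqrt(2/3 + 36ν²/(g d³(s−1))) − sqrt(36ν²/(g d³(s−1)))`,
  with terminal deposition into an audited mass ledger (no resuspension);
* a nitrogen-based NPZD ecosystem (Michaelis–Menten uptake, Eppley
  temperature factor, Steele light curve with optimum 65 W/m², Ivlev
  grazing) with an exactly closed nitrogen budget;
* a synthetic scenario generator: raised-cosine flood hydrograph over a
  62.46 m³/s base flow, sediment rating curve, stratified initial ocean
  with a sub-surface chlorophyll maximum, spinup, and the sensitivity case
  grid (a full-study-shaped grid reproduces 155 cases);
* diagnostics: plume masks, volume-weighted plume means, difference series
  with extremum and timing analysis (`flood_response()`), regime
  classification, the river–sea density-difference axis, and regime maps
  with per-diameter transition intervals;
* orchestration: deterministic `run_case()` / `run_sweep()` with shared
  spinup, one physical integration serving several riverine-nutrient
  multipliers, CSV/JSON artefacts and a manifest making sweeps resumable.

## A worked example

Run the two marked sensitivity cases — the typical hypopycnal case
(SSM 4× standard, 0.05 mm grains) and the typical hyperpycnal case
(10×, 0.01 mm) — against the shared no-SSM reference, and summarise:

```r
library(floodplume)

cfg  <- fp_config()                      # the scaled study configuration
spin <- spinup(cfg)                      # 2 days of base flow, shared
wos  <- run_case(cfg, NULL,               spinup_state = spin)
hypo <- run_case(cfg, hypopycnal_case(),  spinup_state = spin)
hyper<- run_case(cfg, hyperpycnal_case(), spinup_state = spin)

pp <- do.call(fp_plume_params, cfg$diagnostics)
flood_response(difference_series(hypo, wos, pp), cfg$river$t_peak)
#> # A tibble: 1 × 11
#>   nutrient_mult dS_ext  t_ext lag_h dN_at_Sext dP_at_Sext   dN_ext dN_t_ext
#>           <dbl>  <dbl>  <dbl> <dbl>      <dbl>      <dbl>    <dbl>    <dbl>
#> 1             1  -1.37 201600    20   0.000788   0.000573 -0.00199   273600
#>    dP_ext dP_t_ext decay_frac_3d
#>     <dbl>    <dbl>         <dbl>
#> 1 0.00100   252000             0

flood_response(difference_series(hyper, wos, pp), cfg$river$t_peak)
#> # A tibble: 1 × 11
#>   nutrient_mult dS_ext  t_ext lag_h dN_at_Sext dP_at_Sext  dN_ext dN_t_ext
#>           <dbl>  <dbl>  <dbl> <dbl>      <dbl>      <dbl>   <dbl>    <dbl>
#> 1             1   10.6 151200     6    -0.0155   0.000418 -0.0155   151200
#>     dP_ext dP_t_ext decay_frac_3d
#>      <dbl>    <dbl>         <dbl>
#> 1 -0.00774   295200             0
```

Reading this: the hypopycnal case freshens the plume (ΔS = −1.37 psu,
peaking 20 h after the flood peak) while holding more nutrients at the
surface (ΔN > 0 at that moment); the hyperpycnal case salinifies it
(ΔS = +10.6 psu, at the flood peak + 6 h) while stripping surface nutrients
(ΔN < 0); phytoplankton is slightly enriched in both while the interaction
acts; and both anomalies have decayed to nothing three days after the peak.
The responses differ by roughly an order of magnitude, hyperpycnal the
stronger — the regime asymmetry the analysis is about.

A sweep builds the regime map (blue = intensified hypopycnal, brown =
hyperpycnal, with the per-diameter transition interval in the attributes):

```r
sweep <- run_sweep(cfg, case_grid(c(1, 2, 4, 6, 8, 10),
                                  c(0.01, 0.02, 0.05) * 1e-3, 1))
autoplot(sweep$regime_map)
glance(sweep$regime_map)
```

`autoplot()` methods exist for hydrographs, difference series and regime
maps; `tidy()`/`glance()` follow the usual conventions.

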