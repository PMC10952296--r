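# spacsim

Soil–plant–atmosphere continuum simulation with plant hydraulics, water
storage and irreversible xylem damage.

`spacsim` is for ecohydrologists and land-surface modellers who want to ask:
*how much does the representation of plant hydraulics change what a model
says about drought?* It implements five model variants that differ **only**
in the plant water-transport scheme, so paired runs on identical forcing,
soil and photosynthesis isolate the hydraulic representation itself:

| variant | plant hydraulics |
|---|---|
| `baseline` | none — empirical soil stress factor `fs = exp(-q |ψs|^p)` with Leuning stomatal conductance `gs = g0 + a1 fs Anpot / ((ci − Γ)(1 + D/D0))` |
| `H` | steady-state two-node scheme: ψx, ψl solve `k̄s→x(ψs − ψx) = k̄x→l(ψx − ψl) = T(ψs, ψl, M)` with exponential vulnerability curves `k = kmax exp(−q |ψ|^p)` and Tuzet-style stomata `gs = g0 + a1 fs Anpot fl / (ci − Γ)`, `fl = exp(−al |ψs − ψl|^γl)` |
| `HC` | adds xylem and leaf water storage: `dVx/dt = Js→x − Jx→l`, `dVl/dt = Jx→l − T`, linear pressure–volume curves `ψ = c (1 − V/Vmax)`, stiff adaptive integration |
| `H-d`, `HC-d` | irreversible damage: each tissue age cohort keeps the conductance implied by the *minimum* potential it ever experienced; recovery only through tissue turnover |

Around the core: Farquhar C3 photosynthesis coupled to stomatal conductance
through the intercellular CO2 fixed point, a layered bucket soil column
(van Genuchten–Mualem retention, radial soil-to-root conductance), a
synthetic "average warm and sunny day" forcing generator for dry-down
(E1) and drought-relief (E2) experiments, and diagnostics: stress-onset and
90%→50% decline timing, water-use efficiency, diurnal composites,
Penman–Monteith surface-conductance inversion with 200-Pa VPD binning.

All user-facing functions take data frames and return tibbles;
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` functions are
provided. The methods vignette (`vignettes/plant-hydraulics.Rmd`) documents
the model equations, numerical choices and default study conditions.

## Worked example

A 40-day synthetic dry-down from saturated soil, comparing the empirical
baseline with both hydraulic variants:

```r
library(spacsim)
ex <- run_e1(variants = c("baseline", "H", "HC"), n_days = 40, seed = 1)
glance(ex)[, c("variant", "gpp_mean", "transp_total_mm", "wue_predrought")]
#> # A tibble: 3 × 4
#>   variant  gpp_mean transp_total_mm wue_predrought
#>   <chr>       <dbl>           <dbl>          <dbl>
#> 1 baseline     18.4            368.           2.01
#> 2 H            18.9            461.           1.45
#> 3 HC           19.1            480.           1.45
```

`gpp_mean` is gross primary productivity (μmol CO2 m⁻² s⁻¹, daily mean
over the run), `transp_total_mm` the cumulative transpiration, and
`wue_predrought` the mean daily GPP-to-transpiration ratio over the first
five days: the storage variant (`HC`) transpires more than the steady
variant (`H`) in the morning — refilled stores hold the leaf water
potential up while light still limits photosynthesis — so it buys water
without carbon and its water-use efficiency is at or below `H`'s.
Over the full 250-day dry-down (`n_days = 250`) the baseline's GPP
collapses fastest once soil stress begins (its 90%→50% decline takes
about 17 days against 21–22 for the hydraulic variants), and the storage
variant reaches soil-water stress a day or two earlier than the steady
one because of that lower water-use efficiency.

Drought relief with and without irreversible damage:

```r
e2 <- run_e2(variants = c("HC", "HC-d"), seed = 1)
e2$meta$relief_day          # day the dry-down reached fs = 0.2 and the soil was re-saturated
plot_variants(e2, "GPP")    # HC-d recovers more slowly after relief
```

Useful single-purpose functions: `calibrate_fl()` (closed-form calibration
of the stomatal down-regulation curve to two anchor conditions),
`solve_steady()` (one steady-state hydraulic solve), `step_capacitance()`
(one hour of the storage ODEs), `advance_cohorts()` /
`effective_conductivity()` (damage bookkeeping),
`invert_penman_monteith()` and `bin_gs_vpd()` (surface-conductance
diagnostics). A thin command-line wrapper lives at `inst/cli/spacsim.R`
(`Rscript spacsim.R e1 --variant H,HC --out runs/`).

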