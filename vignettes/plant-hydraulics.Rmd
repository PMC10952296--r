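---
title: "Modelling plant hydraulics, water storage and xylem damage with spacsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling plant hydraulics, water storage and xylem damage with spacsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacsim)
```

## The problem

How much does an explicit representation of plant hydraulics change what a
land-surface simulation says about drought? `spacsim` implements a hierarchy
of five model variants that differ **only** in how the plant's water
transport is represented, so that paired runs isolate the hydraulic
representation itself:

* `baseline` — no plant hydraulics. Water stress acts only through an
  empirical factor $f_s = \exp(-q\,|\psi_s|^p)$ applied to potential
  assimilation, with Leuning stomatal conductance
  $g_s = g_0 + a_1 f_s A_{n,pot} / ((c_i - \Gamma)(1 + D/D_0))$.
* `H` — steady-state two-node hydraulics. Xylem and leaf water potentials
  $(\psi_x, \psi_l)$ solve the flux-continuity system
  $\bar k_{s\to x}(\psi_s - \psi_x) = \bar k_{x\to l}(\psi_x - \psi_l) =
  T(\psi_s, \psi_l, M)$, where the segment conductances are geometric means
  of their endpoint conductances, each endpoint following an exponential
  vulnerability curve $k = k_{max}\exp(-q\,|\psi|^{p})$. Stomata follow a
  Tuzet-style law, $g_s = g_0 + a_1 f_s A_{n,pot} f_l / (c_i - \Gamma)$,
  where $f_l = \exp(-a_l\,|\psi_s - \psi_l|^{\gamma_l})$ replaces the
  Leuning VPD term with a response to the actual soil-to-leaf potential
  drop.
* `HC` — adds xylem and leaf water storage. Storages $(V_x, V_l)$ obey
  $dV_x/dt = J_{s\to x} - J_{x\to l}$ and $dV_l/dt = J_{x\to l} - T$, with
  linear pressure–volume curves $\psi = c\,(1 - V/V_{max})$ mapping storage
  to potential. Stores refill at night and buffer daytime demand.
* `H-d`, `HC-d` — irreversible damage. Tissue conductance is kept at the
  value implied by the **minimum** potential each age cohort has ever
  experienced; conductance recovers only when turnover replaces damaged
  cohorts with new tissue (born undamaged and full of water).

Everything around the hydraulic core — Farquhar C3 photosynthesis, the
layered bucket soil column, the forcing generator, the diagnostics — is
shared by all variants.

## Model structure and assumptions

**Gas exchange.** Potential net assimilation is the minimum of the
Rubisco- and RuBP-limited rates minus dark respiration, with peaked
Arrhenius temperature responses and a non-rectangular hyperbola light
response. The intercellular CO2 concentration solves the diffusion fixed
point $A_n = g_s (c_a - c_i)$ by bracketed bisection (residual < 1e-8);
$g_s$ is denominated as a CO2 conductance and the water-vapour conductance
is $1.6\,g_s$. Realized assimilation uses the non-stomatal convention
$A_n = f_s A_{n,pot}$ (the two decoupled stomatal variants, `tuzet_no_fs`
and `tuzet_light_only`, drop $f_s$ and use
$f_l^* = \exp(-a_s |\psi_l|^{\gamma_s})$). Canopy fluxes scale linearly
with leaf area index (a big-leaf canopy without self-shading or a leaf
energy balance: leaf temperature equals air temperature). These
simplifications are shared by every variant, so inter-variant differences
— the object of study — are unaffected, but absolute flux magnitudes
should not be over-interpreted.

**The $f_l$ calibration.** The two parameters of the down-regulation
factor are fixed in closed form by two anchor conditions: a 1.0 MPa
soil-to-leaf potential drop halves stomatal conductance, and a 0.2 MPa
drop reduces it by 10%. With $L_i = -\log(1 - r_i)$,
$\gamma_l = \log(L_1/L_2)/\log(d_1/d_2)$ and $a_l = L_1 / d_1^{\gamma_l}$,
giving $a_l = \ln 2 \approx 0.693$ and $\gamma_l \approx 1.1705$.

```{r}
calibrate_fl(c(1.0, 0.5), c(0.2, 0.1))
```

**Soil.** A bucket column with van Genuchten–Mualem retention (a
Clapp–Hornberger dialect is available behind `retention`), free drainage
at the base, infiltration filling layers top-down, and per-layer root
uptake. The root-zone potential is the retention curve applied to the
root-fraction-weighted water content, $\psi_s = P(\sum_i w_i \theta_i)$ —
the weighted-content reading; weighting per-layer potentials instead is
available via `root_weighted_psi(per_layer = TRUE)`. The soil-to-root
conductance follows the radial root geometry,
$k_r = k_s(\psi_s)\, 2\pi R_l / \ln(r_c/r_r) \cdot 10^6/(\rho g)$.

**Numerics of the steady solve.** The vulnerability curves make the
hydraulic supply curve non-monotone, so the two-equation system can have
several equilibria during drought, and in deep drought no equilibrium at
all (the residual stomatal-conductance demand floor $g_0$ can exceed what
the collapsed soil-to-root pathway supplies). The solver therefore defines
its solution explicitly: *the highest leaf potential at which both
flux-conservation residuals are within 1% of the local transpiration
rate* — the branch reached by continuity from wet conditions, at the
model's own accuracy standard. Within a simulation the previous hour's
solution seeds a Powell dog-leg trust-region iteration (finite-difference
Jacobians), so the run follows its branch by continuity; a cold solve is
located by a vectorized scan that minimizes $|r_1| + |r_2|$ over $\psi_x$
for each candidate $\psi_l$ (with sign-change detection on the
supply–demand gap so steep isolated roots are not missed), bisects the
upper edge of the solution band, and then polishes with the dog-leg,
accepting the polished root when it stays on the same branch. When no solution band exists — the infeasible
drought-stress regime — a seeded 100-start constrained minimization of
$|r_1| + |r_2|$ subject to $\psi_s \ge \psi_x \ge \psi_l$ takes over and
the hour is flagged; the run continues from the best compromise, and the
soil is debited by the soil-side flux. Flagged hours are counted in
`meta$fallback_count`.

**Numerics of the storage ODEs.** Within each forcing hour the An-gs-ci
coupling is tabulated once on a grid of leaf potentials (161 points over
8 MPa below $\psi_s$) and interpolated; both the steady solver and the ODE
right-hand side consume the same demand curve, which is what makes the
vanishing-capacitance limit of `HC` land on the `H` solution. The ODEs are
integrated with `deSolve` (default `lsoda`, rtol 1e-6, atol 1e-12 m) —
time-adaptive and stiff-capable, which matters because the leaf store's
relaxation time (minutes) is far shorter than the xylem store's (hours);
an embedded Runge–Kutta 2(3) pair is available via
`spac_control(ode_method = "ode23")`. Augmented cumulative states carry
the uptake, transpiration and assimilation integrals, so the hourly water
balance $\Delta V_x + \Delta V_l = \int (J_{s\to x} - T)\,dt$ closes to
solver precision (< 1e-9 m) and the soil is debited by exactly the water
extracted. Storage depletion is guarded by smooth ramps that shut outflow
as a store approaches empty, rather than by hard clipping, keeping the
right-hand side continuous. Soil water potential is held fixed within the
hour and recoupled at the forcing step; at the default soil volume a full
hour of peak transpiration moves $\psi_s$ by well under 0.01 MPa, so
sub-hourly recoupling changes nothing visible (the interval is
configurable).

**Damage cohorts.** Tissue age is discretized into daily classes (10
years for sapwood, 1 year for leaves by default). Each class carries a
running minimum of the potential it has experienced; effective conductance
is the density-weighted vulnerability sum evaluated at those minima
(further depressed by the current potential when it undercuts the memory,
never raised). Daily turnover removes the oldest tissue first — before the
ageing shift, so dying cohorts cannot taint the memory of their successors
— and recruitment inserts undamaged tissue at age zero. With the step
equal to the class width, ageing is an exact one-class shift. Minimum
tracking is suspended while the canopy is leafless (toggleable via
`spac_control(track_dormant = TRUE)`), to avoid spurious permanent damage
accumulating through dormant periods when the hydraulic system is inert.

**Dynamic vegetation.** Two carbon pools (leaves, living sapwood), fixed
allocation fractions of NPP ($= (1 - r_a)\,$GPP), first-order turnover, a
daily step, and LAI $=$ SLA $\times$ leaf carbon. This is a deliberately
minimal scheme: fine roots, reserves, phenology and — importantly —
damage-responsive allocation are absent, which is known to overstate
post-drought legacies.

## The synthetic experiments

`synthetic_forcing_archive()` generates a multi-year hourly archive with a
seasonal cycle, AR(1) day-to-day anomalies, diurnal temperature/humidity
cycles, clear-sky radiation under random cloudiness, and intermittent
rain. `make_percentile_day()` composes the "average warm and sunny day":
per-hour 75th percentiles of temperature and shortwave radiation over the
three most active months, relative humidity at the 10th (high VPD) or
90th (low VPD) percentile, medians for everything else, and VPD recomputed
as $D = (1 - RH)\,e_{sat}(T_a)$ (Tetens).

* **E1 (dry-down):** the day is repeated 250 times with no rain from a
  saturated soil; vegetation is static. Run with
  `run_e1(variants = c("baseline", "H", "HC"))`.
* **E2 (dry-down and relief):** the dry-down runs until the baseline
  convention stress factor first reaches $f_s \le 0.2$ — determined once,
  from a baseline probe run, so every variant sees the same drought length
  — then a rainfall event saturates the whole column and the run continues
  for 100 days with dynamic vegetation. Run with
  `run_e2(variants = c("HC", "HC-d"))`.

**Default study conditions.** The shipped trait set describes an evergreen
broadleaf forest with substantial stem water storage — the setting in which
storage effects are most visible: height 20 m, xylem area fraction
4e-3 m² m⁻² and conduit water fraction 0.5 (so $V_{x,max} = 40$ mm of
water), $c_x = -8$ MPa (a stem capacitance of 5 mm MPa⁻¹), LAI 3 with
LMA 0.15 kg m⁻² and LDMC 0.30 ($V_{l,max} \approx 1$ mm), xylem P50 at
−3 MPa and leaf P50 at −2 MPa ($p = 2$ exponents), and maximum
conductances of 4e-7 (xylem) and 8e-7 (leaf) m s⁻¹ MPa⁻¹, giving a
roughly 1 MPa midday soil-to-leaf drop at peak demand. The soil is a
1.5 m loam (van Genuchten $\theta_r = 0.06$, $\theta_s = 0.45$,
$\alpha = 367$ MPa⁻¹, $n = 1.56$, $K_s = 2.9\times10^{-6}$ m s⁻¹) with
roots concentrated near the surface. The empirical stress factor uses
$p = 2$ with its midpoint at −0.8 MPa, a typical operating range for a
loam between field capacity and wilting; this choice matters because it
sets where the baseline's soil-only stress acts relative to the hydraulic
variants' supply limitation. All of these are choices a site
parameterization would normally pin down; they are fixed once here as the
package's default study conditions.

What the generator does **not** emulate: weather variability (E1/E2
deliberately repeat one day), covariation of radiation and VPD with
synoptic events, rainfall seasonality, canopy energy balance feedbacks on
leaf temperature, and site-specific trait combinations. Passing the
signature tests on these conditions shows the mechanisms are implemented
and interact as described — not that the magnitudes match any particular
ecosystem.

## What the paired experiments show

On the default conditions (all of these are asserted by the test suite,
and none are hard-coded — they emerge from the coupled dynamics):

* The baseline's productivity collapses fastest once soil stress begins;
  both hydraulic variants stretch the 90%-to-50% GPP decline by throttling
  transpiration earlier and spending soil water more slowly.
* The storage variant transpires more than the steady variant through the
  morning (night-refilled stores keep $\psi_l$ high while light is still
  the limiting factor), buying transpiration without carbon — so its
  pre-drought water-use efficiency is lower and it reaches soil-water
  stress earlier.
* Both hydraulic variants depress late-afternoon assimilation relative to
  the baseline, because the accumulated potential drop keeps stomata more
  closed than the Leuning VPD term alone would.
* During a first dry-down the damage variant's daytime conductance tracks
  the no-damage variant's (the running minimum is set by the current day),
  but only the no-damage variant recovers conductance overnight.
* After relief, the damage variant's GPP, transpiration and LAI stay below
  the no-damage variant's day by day while the damaged xylem is still in
  place. Later, its lower leaf area delays the onset of the *next*
  drought — both effects the damage mechanism predicts, which is why the
  day-by-day ordering is asserted on the immediate post-relief window.

## Worked example

```{r, eval = FALSE}
library(spacsim)

# a 40-day dry-down on the default conditions
ex <- run_e1(variants = c("baseline", "H", "HC"), n_days = 40, seed = 1)
glance(ex)
plot_variants(ex, "GPP")
plot_diurnal(ex, "GPP", days = 2:6)

# drought relief with and without irreversible damage
e2 <- run_e2(variants = c("HC", "HC-d"), seed = 1)
tidy(e2, "daily") |>
  dplyr::filter(day > e2$meta$relief_day) |>
  dplyr::group_by(variant) |>
  dplyr::summarise(gpp_post = mean(GPP))
```

## Known limitations

* The steady-state variants can enter an infeasible regime in deep
  drought (supply below the $g_0$ demand floor); hours are then flagged
  and solved as constrained compromises. The capacitance variants degrade
  gracefully instead, which is one of the reasons to prefer them.
* The big-leaf canopy without energy balance overstates absolute fluxes
  at high LAI; comparisons across variants are unaffected.
* Post-drought legacies are overstated by construction: allocation does
  not respond to xylem damage, so the model does not prioritize rebuilding
  conducting tissue.
* Gravitational potential is neglected throughout; linear pressure–volume
  curves are used for parsimony.
* No hydraulic redistribution: water may not flow from the xylem back to
  the soil (leaf-to-xylem backflow, i.e. night refill, is allowed).
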