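Package: spacsim
Title: Soil-Plant-Atmosphere Continuum Simulation with Plant Hydraulics,
    Water Storage and Xylem Damage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates water and carbon exchange of a vegetated land surface
    with a hierarchy of plant-hydraulics representations: an empirical
    soil-moisture stress baseline, a steady-state two-node (xylem and leaf)
    hydraulic model, a capacitance model that tracks xylem and leaf water
    storage with a stiff ODE integrator, and irreversible-damage counterparts
    in which conducting tissue keeps the conductivity it had at the lowest
    water potential it ever experienced, recovering only through tissue
    turnover. Includes a layered bucket soil-water balance, Farquhar C3
    photosynthesis coupled to Leuning and Tuzet-style stomatal conductance,
    synthetic percentile-day forcing for dry-down and drought-relief
    experiments, and flux diagnostics (stress-onset timing, water-use
    efficiency, diurnal composites, Penman-Monteith surface-conductance
    inversion).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
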