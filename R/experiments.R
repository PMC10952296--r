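#' Default experiment ingredients
#'
#' Convenience constructors for the default scenario: a loamy three-layer
#' soil column and the synthetic percentile "warm and sunny" day used by
#' the dry-down experiments. `e1_day()` composes the day from a seeded
#' synthetic archive: temperature and radiation at their per-hour 75th
#' percentiles over the three most active months, relative humidity at the
#' 10th (`"e1a"`, high VPD) or 90th (`"e1b"`, low VPD) percentile.
#'
#' @param theta Initial water content (defaults to saturation).
#' @return `default_soil()`: a [soil_column()]; `e1_day()`: a 24-row
#'   forcing tibble.
#' @export
default_soil <- function(theta = NULL) {
  ret <- vg_retention(theta_r = 0.06, theta_s = 0.45, alpha = 367,
                      n = 1.56, ks_sat = 2.9e-6)
  if (is.null(theta)) theta <- ret$theta_s
  soil_column(depths = c(0.4, 0.5, 0.6), theta = theta,
              root_frac = c(0.5, 0.3, 0.2), retention = ret,
              Rl = 6000, rc = 0.05, rr = 5e-4)
}

#' @rdname default_soil
#' @param scenario `"e1a"`/`"e2a"` (high VPD) or `"e1b"`/`"e2b"` (low VPD).
#' @param seed Seed of the synthetic forcing archive.
#' @param months Most-active months used for the percentile day.
#' @export
e1_day <- function(scenario = c("e1a", "e1b", "e2a", "e2b"), seed = 1,
                   months = 6:8) {
  scenario <- match.arg(scenario)
  rh_pct <- if (scenario %in% c("e1a", "e2a")) 0.10 else 0.90
  archive <- synthetic_forcing_archive(years = 3, seed = seed)
  make_percentile_day(archive, months = months, rh_percentile = rh_pct)
}

#' Dry-down experiment (E1)
#'
#' Repeats a percentile "warm and sunny" day for `n_days` with no rainfall,
#' starting from a fully saturated soil, and runs the requested model
#' variants on identical forcing and initial state with static vegetation.
#' Intended to expose how the hydraulic representations differ as drought
#' develops, without weather variability as a confounder.
#'
#' @param traits A [plant_traits()] object.
#' @param soil A [soil_column()] (saturated by default).
#' @param params A [gas_params()] object.
#' @param variants Model variants to run.
#' @param scenario `"e1a"` (high VPD) or `"e1b"` (low VPD).
#' @param n_days Dry-down length \[days\] (default 250).
#' @param day Optional 24-row forcing day overriding the synthetic one.
#' @param seed Seed (synthetic day construction and fallback solver).
#' @param control A [spac_control()] list.
#' @return An object of class `spac_experiment`: a named list of
#'   [run_spac()] results plus a `meta` element.
#' @export
run_e1 <- function(traits = plant_traits(), soil = default_soil(),
                   params = gas_params(),
                   variants = c("baseline", "H", "HC"),
                   scenario = c("e1a", "e1b"), n_days = 250,
                   day = NULL, seed = 1, control = spac_control()) {
  scenario <- match.arg(scenario)
  if (is.null(day)) day <- e1_day(scenario, seed = seed)
  forcing <- repeat_forcing(day, n_days)
  soil <- saturate_soil(soil)
  runs <- purrr::map(setNames(variants, variants), function(v) {
    run_spac(forcing, traits, soil, params, variant = v,
             dynamic_veg = FALSE, seed = seed, control = control)
  })
  structure(c(runs, list(meta = list(experiment = "E1", scenario = scenario,
                                     n_days = n_days, seed = seed))),
            class = "spac_experiment")
}

#' Dry-down and relief experiment (E2)
#'
#' A dry-down identical to E1 until the baseline-convention soil stress
#' factor first reaches `fs <= fs_stop` (determined once, from a
#' baseline-variant probe run, so every variant experiences the same
#' drought length), followed by a rainfall event that saturates the whole
#' soil column, after which the run continues for `post_days` with dynamic
#' vegetation enabled.
#'
#' @inheritParams run_e1
#' @param variants Variants to run (default the storage model with and
#'   without irreversible damage).
#' @param scenario `"e2a"` (high VPD) or `"e2b"` (low VPD).
#' @param fs_stop Stress threshold ending the dry-down (default 0.2).
#' @param post_days Days simulated after relief (default 100).
#' @param max_days Cap on the dry-down length; an error is raised if the
#'   stress threshold is never reached.
#' @param pools A [carbon_pools()] object (dynamic vegetation state).
#' @return A `spac_experiment` list; `meta$relief_hour` records the relief
#'   time.
#' @export
run_e2 <- function(traits = plant_traits(), soil = default_soil(),
                   params = gas_params(), variants = c("HC", "HC-d"),
                   scenario = c("e2a", "e2b"), fs_stop = 0.2,
                   post_days = 100, max_days = 400, day = NULL, seed = 1,
                   pools = NULL, control = spac_control()) {
  scenario <- match.arg(scenario)
  if (is.null(day)) day <- e1_day(scenario, seed = seed)
  soil <- saturate_soil(soil)

  # probe: baseline dry-down defines the drought length for all variants
  probe_forcing <- repeat_forcing(day, max_days)
  probe_ctl <- utils::modifyList(control, list(stop_fs = fs_stop))
  probe <- run_spac(probe_forcing, traits, soil, params, variant = "baseline",
                    seed = seed, control = probe_ctl)
  if (is.na(probe$meta$stop_hour)) {
    stop("soil stress factor never reached fs = ", fs_stop, " within ",
         max_days, " days", call. = FALSE)
  }
  relief_hour <- probe$meta$stop_hour + 1L
  n_days <- ceiling(relief_hour / 24) + post_days
  forcing <- repeat_forcing(day, n_days)
  run_ctl <- utils::modifyList(control, list(relief_hour = relief_hour))

  if (is.null(pools)) pools <- carbon_pools(cleaf = traits$lai / 10, sla = 10)
  runs <- purrr::map(setNames(variants, variants), function(v) {
    run_spac(forcing, traits, soil, params, variant = v,
             dynamic_veg = TRUE, pools = pools, seed = seed,
             control = run_ctl)
  })
  structure(c(runs, list(meta = list(experiment = "E2", scenario = scenario,
                                     relief_hour = relief_hour,
                                     relief_day = ceiling(relief_hour / 24),
                                     n_days = n_days, seed = seed))),
            class = "spac_experiment")
}

#' Run a variant on forcing read from file
#'
#' Multiyear (or arbitrary) simulation of any variant on a supplied hourly
#' forcing CSV. Restart-safe: the returned object's `state` element can be
#' passed as `init` to continue a run, and two chained runs reproduce one
#' continuous run exactly.
#'
#' @param forcing_path Path to an hourly forcing CSV (see
#'   [read_forcing_csv()]).
#' @inheritParams run_spac
#' @param column_map Optional column mapping for the CSV reader.
#' @return A [run_spac()] result.
#' @export
run_generic <- function(forcing_path, traits = plant_traits(),
                        soil = default_soil(), params = gas_params(),
                        variant = "H", column_map = NULL, stomata = NULL,
                        dynamic_veg = FALSE, seed = 1, init = NULL,
                        control = spac_control()) {
  forcing <- read_forcing_csv(forcing_path, column_map)
  run_spac(forcing, traits, soil, params, variant = variant,
           stomata = stomata, dynamic_veg = dynamic_veg, seed = seed,
           init = init, control = control)
}

#' @export
print.spac_experiment <- function(x, ...) {
  vs <- setdiff(names(x), "meta")
  cat("<spac_experiment> ", x$meta$experiment, " (", x$meta$scenario, "): ",
      paste(vs, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Diagnostics -----------------------------------------------------------------

#' Time for productivity to decline from 90% to 50% of its initial rate
#'
#' The initial rate is the mean of the first `baseline_days` days; the
#' crossing times of 0.9 and 0.5 of that rate are linearly interpolated
#' (first crossing) and their difference returned, in days.
#'
#' @param gpp_daily Daily GPP series starting before drought onset.
#' @param baseline_days Days averaged into the initial rate (default 5).
#' @return Decline time \[days\], or `NA` with a warning if the series
#'   never reaches 50% of the initial rate.
#' @export
#' @examples
#' g <- 10 * exp(-(0:100) / 20)
#' metric_decline_time(g, baseline_days = 1)  # ~11.76 d
metric_decline_time <- function(gpp_daily, baseline_days = 5) {
  if (length(gpp_daily) <= baseline_days) {
    warning("series shorter than the baseline window; decline time undefined",
            call. = FALSE)
    return(NA_real_)
  }
  g0 <- mean(gpp_daily[seq_len(baseline_days)])
  cross <- function(level) {
    target <- level * g0
    below <- which(gpp_daily <= target)
    if (!length(below)) return(NA_real_)
    k <- below[1]
    if (k == 1) return(1)
    # linear interpolation between day k-1 and day k
    (k - 1) + (gpp_daily[k - 1] - target) / (gpp_daily[k - 1] - gpp_daily[k])
  }
  t90 <- cross(0.9)
  t50 <- cross(0.5)
  if (is.na(t50) || is.na(t90)) {
    warning("series never crossed the decline thresholds; decline time undefined",
            call. = FALSE)
    return(NA_real_)
  }
  t50 - t90
}

#' Day of soil-water stress onset
#'
#' First day on which the soil stress factor falls below a threshold
#' (default 0.9): the operational definition of "stress onset" used when
#' comparing how fast variants deplete the soil.
#'
#' @param fs_daily Daily series of the (minimum) soil stress factor.
#' @param threshold Stress threshold (default 0.9).
#' @return Day index of first crossing, or `NA` if never crossed.
#' @export
metric_stress_onset <- function(fs_daily, threshold = 0.9) {
  k <- which(fs_daily < threshold)
  if (!length(k)) return(NA_integer_)
  k[1]
}

#' Water-use efficiency over a window
#'
#' Mean of daily GPP / daily transpiration over the window; days with zero
#' transpiration are excluded with a warning.
#'
#' @param gpp_daily Daily GPP.
#' @param transp_daily Daily transpiration (same length, any consistent
#'   unit).
#' @param window Indices of the days to average (default all).
#' @return Mean WUE in (GPP units) per (transpiration unit).
#' @export
metric_wue <- function(gpp_daily, transp_daily, window = seq_along(gpp_daily)) {
  stopifnot(length(gpp_daily) == length(transp_daily))
  g <- gpp_daily[window]
  tr <- transp_daily[window]
  ok <- tr > 0
  if (any(!ok)) warning("excluding ", sum(!ok), " zero-transpiration day(s)",
                        call. = FALSE)
  if (!any(ok)) return(NA_real_)
  mean(g[ok] / tr[ok])
}

#' Diurnal composite of an hourly series
#'
#' Per-hour-of-day mean over all complete days, optionally normalized by
#' the composite maximum.
#'
#' @param x Hourly values (chronological, starting at hour 0).
#' @param normalize Divide by the composite maximum.
#' @return A 24-vector (hours 0-23).
#' @export
diurnal_composite <- function(x, normalize = FALSE) {
  nd <- length(x) %/% 24
  if (nd < 1) stop("need at least one complete day", call. = FALSE)
  m <- matrix(x[seq_len(24 * nd)], nrow = 24)
  comp <- rowMeans(m)
  if (normalize) comp <- comp / max(comp)
  comp
}

# Penman-Monteith -------------------------------------------------------------

.slope_esat <- function(ta) {
  # d esat / d Ta of the Tetens formula [Pa K-1]
  esat(ta) * 17.27 * 237.3 / (ta + 237.3)^2
}

.psychrometric <- function(ta, patm) {
  .const$cp * patm / (0.622 * .const$lambda_v)
}

#' Forward Penman-Monteith latent heat flux
#'
#' `lambdaE = (Delta (Rn - G) + rho_a cp D Ga) / (Delta + gamma (1 +
#' Ga / Gs))`; used as the forward model in inversion round-trip checks
#' and for constructing surface-conductance diagnostics.
#'
#' @param rn Net radiation \[W m-2\].
#' @param g_soil Ground heat flux \[W m-2\].
#' @param d Vapour pressure deficit \[Pa\].
#' @param ga Aerodynamic conductance \[m s-1\].
#' @param gs Surface conductance \[m s-1\].
#' @param ta Air temperature \[degC\].
#' @param patm Atmospheric pressure \[Pa\].
#' @return Latent heat flux \[W m-2\].
#' @export
penman_monteith <- function(rn, g_soil, d, ga, gs, ta, patm = 101325) {
  delta <- .slope_esat(ta)
  gamma <- .psychrometric(ta, patm)
  rho_a <- patm / (.const$R_air * (ta + 273.15))
  (delta * (rn - g_soil) + rho_a * .const$cp * d * ga) /
    (delta + gamma * (1 + ga / gs))
}

#' Invert the Penman-Monteith equation for surface conductance
#'
#' `Gs = gamma lambdaE Ga / (Delta (Rn - G) + rho_a cp D Ga -
#' lambdaE (Delta + gamma))`, assuming neutral atmospheric conditions.
#' Surface conductance lumps stomatal and soil vapour pathways; it is the
#' standard bulk diagnostic for comparing modelled and observed stomatal
#' behaviour against atmospheric demand.
#'
#' @param le Latent heat flux \[W m-2\].
#' @inheritParams penman_monteith
#' @return Surface conductance \[m s-1\]; `NA` where the inversion
#'   denominator is non-physical (<= 0).
#' @export
#' @examples
#' le <- penman_monteith(500, 50, 1500, ga = 0.05, gs = 0.01, ta = 25)
#' invert_penman_monteith(le, 500, 50, 1500, ga = 0.05, ta = 25)
invert_penman_monteith <- function(le, rn, g_soil, d, ga, ta, patm = 101325) {
  stopifnot(all(ga > 0))
  delta <- .slope_esat(ta)
  gamma <- .psychrometric(ta, patm)
  rho_a <- patm / (.const$R_air * (ta + 273.15))
  denom <- delta * (rn - g_soil) + rho_a * .const$cp * d * ga -
    le * (delta + gamma)
  out <- ifelse(denom > 0, gamma * le * ga / denom, NA_real_)
  ifelse(le == 0, 0, out)
}

#' Bin surface conductance by vapour pressure deficit
#'
#' Half-open bins `[k w, (k+1) w)` of width `bin_width` Pa; empty bins are
#' omitted.
#'
#' @param gs Surface conductance series.
#' @param d Aligned VPD series \[Pa\].
#' @param bin_width Bin width \[Pa\] (default 200).
#' @return A tibble with `bin_center`, `gs_mean` and `n`.
#' @export
bin_gs_vpd <- function(gs, d, bin_width = 200) {
  stopifnot(length(gs) == length(d), bin_width > 0)
  ok <- is.finite(gs) & is.finite(d)
  tibble::tibble(bin = floor(d[ok] / bin_width), gs = gs[ok]) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(gs_mean = mean(.data$gs), n = dplyr::n(), .groups = "drop") |>
    dplyr::transmute(bin_center = (.data$bin + 0.5) * bin_width,
                     gs_mean = .data$gs_mean, n = .data$n) |>
    dplyr::arrange(.data$bin_center)
}
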