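#' Control settings for the simulator
#'
#' @param rtol,atol Tolerances of the storage ODE integrator.
#' @param ode_method `deSolve` method for the storage ODEs (default
#'   `"lsoda"`, time-adaptive and stiff; `"ode23"` selects the embedded
#'   Runge-Kutta 2(3) pair).
#' @param demand_n,demand_span Grid size and depth \[MPa\] of the
#'   leaf-potential demand tabulation (see [demand_function()]).
#' @param fallback_starts Random starts of the constrained fallback solver.
#' @param track_dormant Keep recording minimum potentials when LAI is zero
#'   (off by default, to avoid spurious damage during dormancy).
#' @param xylem_max_age,leaf_max_age Oldest cohort ages \[days\].
#' @param relief_hour Optional hour index at which the soil is reset to
#'   saturation (drought-relief experiments).
#' @param stop_fs Optional threshold: the run stops at the first hour the
#'   soil stress factor falls to or below this value.
#' @return A named list of settings.
#' @export
spac_control <- function(rtol = 1e-6, atol = 1e-12, ode_method = "lsoda",
                         demand_n = 161, demand_span = 8,
                         fallback_starts = 100, track_dormant = FALSE,
                         xylem_max_age = 3650, leaf_max_age = 365,
                         relief_hour = NA, stop_fs = NA) {
  list(rtol = rtol, atol = atol, ode_method = ode_method,
       demand_n = demand_n, demand_span = demand_span,
       fallback_starts = fallback_starts, track_dormant = track_dormant,
       xylem_max_age = xylem_max_age, leaf_max_age = leaf_max_age,
       relief_hour = relief_hour, stop_fs = stop_fs)
}

.variant_info <- function(variant) {
  list(
    hydraulics = variant != "baseline",
    storage = variant %in% c("HC", "HC-d"),
    damage = variant %in% c("H-d", "HC-d")
  )
}

#' Run the soil-plant-atmosphere simulator
#'
#' Hourly simulation of coupled water and carbon exchange for one of five
#' model variants: `"baseline"` (empirical soil-moisture stress factor with
#' Leuning stomatal conductance, no explicit plant hydraulics), `"H"`
#' (steady-state two-node hydraulics), `"HC"` (hydraulics with xylem and
#' leaf water storage), and their irreversible-damage counterparts `"H-d"`
#' and `"HC-d"` in which tissue conductance follows the minimum potential
#' each age cohort has experienced. All variants share the soil column,
#' photosynthesis scheme and forcing, so differences between runs isolate
#' the hydraulic representation.
#'
#' @param forcing Hourly forcing tibble (see [forcing_record()]).
#' @param traits A [plant_traits()] object.
#' @param soil A [soil_column()].
#' @param params A [gas_params()] object.
#' @param variant One of `"baseline"`, `"H"`, `"HC"`, `"H-d"`, `"HC-d"`.
#' @param stomata Stomatal model tag; defaults to `"leuning"` for the
#'   baseline and `"tuzet"` otherwise. The baseline always uses Leuning (a
#'   different request is ignored with a warning).
#' @param dynamic_veg Evolve the carbon pools (daily step) and derive LAI
#'   from leaf carbon.
#' @param pools A [carbon_pools()] object (used when `dynamic_veg`).
#' @param seed Integer seed controlling the fallback solver starts.
#' @param init Optional checkpoint (the `state` element of a previous run)
#'   to continue from.
#' @param control A [spac_control()] list.
#' @return An object of class `spac_run`: a list with `hourly` and `daily`
#'   tibbles, `meta`, and the final `state` (restart checkpoint).
#' @export
run_spac <- function(forcing, traits, soil, params = gas_params(),
                     variant = c("baseline", "H", "HC", "H-d", "HC-d"),
                     stomata = NULL, dynamic_veg = FALSE,
                     pools = carbon_pools(cleaf = traits$lai / 10,
                                          sla = 10 / 1),
                     seed = 1, init = NULL, control = spac_control()) {
  variant <- match.arg(variant)
  vi <- .variant_info(variant)
  if (is.null(stomata)) stomata <- if (vi$hydraulics) "tuzet" else "leuning"
  if (!vi$hydraulics && stomata != "leuning") {
    warning("baseline variant ignores hydraulic stomatal settings; using leuning",
            call. = FALSE)
    stomata <- "leuning"
  }
  forcing <- validate_forcing(forcing)
  ctl <- utils::modifyList(spac_control(), control)
  n <- nrow(forcing)
  nl <- nrow(soil$layers)

  # unpack state ------------------------------------------------------------
  caps <- storage_capacities(traits)
  if (!is.null(init)) {
    soil <- init$soil
    vx <- init$vx; vl <- init$vl
    guess <- init$guess
    coh_x <- init$cohorts_x; coh_l <- init$cohorts_l
    pools <- init$pools
    lai_prev <- init$lai
  } else {
    vx <- caps$vxmax; vl <- caps$vlmax  # storages start full (saturated soil)
    guess <- NULL
    coh_x <- if (vi$damage) init_cohorts(ctl$xylem_max_age, ctl$xylem_max_age,
                                         tissue = "xylem") else NULL
    coh_l <- if (vi$damage) init_cohorts(ctl$leaf_max_age, ctl$leaf_max_age,
                                         tissue = "leaf") else NULL
    lai_prev <- if (dynamic_veg) lai_from_leaf_carbon(pools) else traits$lai
  }

  # preallocate outputs -----------------------------------------------------
  num <- function() rep(NA_real_, n)
  o <- list(psis = num(), psix = num(), psil = num(), vx = num(), vl = num(),
            kx_eff = num(), kl_eff = num(), kr = num(), fs = num(), fl = num(),
            gs = num(), ci = num(), an = num(), gpp = num(), t = num(),
            jsx = num(), jxl = num(), lai = num(), fallback = logical(n))
  theta_mat <- matrix(NA_real_, n, nl)

  ta <- forcing$Ta; sw <- forcing$SWdown; d <- forcing$D
  patm <- forcing$Patm; ca <- forcing$ca; precip <- forcing$precip

  kx_closure <- NULL; kl_closure <- NULL
  rebuild_damage <- TRUE
  day_gpp <- 0
  stop_hour <- NA_integer_
  fallback_count <- 0L

  for (i in seq_len(n)) {
    if (!is.na(ctl$relief_hour) && i == ctl$relief_hour) {
      soil <- saturate_soil(soil)
    }
    lai <- lai_prev
    psis <- root_weighted_psi(soil)
    fs <- fs_factor(psis, params$p, params$q)
    frow <- list(Ta = ta[i], SWdown = sw[i], D = d[i], Patm = patm[i], ca = ca[i])

    if (vi$damage && rebuild_damage) {
      kx_closure <- .effective_curve(coh_x, traits$kxmax, traits$qx, traits$px)
      kl_closure <- .effective_curve(coh_l, traits$klmax, traits$ql, traits$pl)
      rebuild_damage <- FALSE
    }
    kx_fun <- if (vi$damage) kx_closure else NULL
    kl_fun <- if (vi$damage) kl_closure else NULL

    if (!vi$hydraulics) {
      # empirical baseline: no plant water potentials
      sol <- .solve_ci_vec(ta[i], par_from_sw(sw[i]), ca[i], d[i], fs, 1,
                           params, "leuning")
      tt <- transp_flux(sol$gs, d[i], patm[i], lai)
      o$fs[i] <- fs; o$gs[i] <- sol$gs; o$ci[i] <- sol$ci; o$an[i] <- sol$an
      o$gpp[i] <- max(sol$an, 0) * lai; o$t[i] <- tt; o$fl[i] <- 1
      uptake <- tt
    } else if (lai <= 0) {
      # leafless: no transpiration; xylem potential follows the soil
      o$psix[i] <- psis; o$psil[i] <- psis
      o$fs[i] <- fs; o$fl[i] <- 1; o$gpp[i] <- 0; o$t[i] <- 0
      uptake <- 0
      if (vi$storage) { o$vx[i] <- vx; o$vl[i] <- vl }
    } else {
      kr <- soil_root_conductance(soil, psis)
      dem <- demand_function(psis, frow, traits, params, stomata, lai = lai,
                             n = ctl$demand_n, span = ctl$demand_span)
      if (!vi$storage) {
        st <- solve_steady(psis, frow, traits, params, kr, model = stomata,
                           guess = guess, demand = dem,
                           kx_fun = kx_fun, kl_fun = kl_fun, lai = lai,
                           control = list(fallback_starts = ctl$fallback_starts,
                                          seed = seed + i))
        guess <- c(st$psix, st$psil)
        if (identical(st$method, "fallback")) fallback_count <- fallback_count + 1L
        o$fallback[i] <- identical(st$method, "fallback")
        psix <- st$psix; psil <- st$psil
        o$t[i] <- st$T; o$jsx[i] <- st$Jsx; o$jxl[i] <- st$Jxl
        o$gs[i] <- st$gs; o$ci[i] <- st$ci; o$an[i] <- st$an
        o$fl[i] <- st$fl
        o$gpp[i] <- max(st$an, 0) * lai
        # the soil is debited by the soil-side flux; it equals T whenever
        # the solve converged and is the physical extraction when flagged
        uptake <- max(st$Jsx, 0)
      } else {
        # rescale leaf storage if LAI changed (dynamic vegetation)
        caps_i <- storage_capacities(traits, lai)
        st <- step_capacitance(vx, vl, psis, dem, traits, kr, dt = 3600,
                               kx_fun = kx_fun, kl_fun = kl_fun, lai = lai,
                               rtol = ctl$rtol, atol = ctl$atol,
                               method = ctl$ode_method)
        vx <- st$vx; vl <- st$vl
        psix <- st$psix; psil <- st$psil
        o$t[i] <- st$T; o$jsx[i] <- st$Jsx; o$jxl[i] <- st$Jxl
        o$an[i] <- st$an; o$fl[i] <- dem$flfun(psil)
        o$gs[i] <- dem$gsfun(psil); o$ci[i] <- dem$cifun(psil)
        o$gpp[i] <- max(st$an, 0) * lai
        o$vx[i] <- vx; o$vl[i] <- vl
        uptake <- st$Jsx
      }
      o$psix[i] <- psix; o$psil[i] <- psil
      o$fs[i] <- fs
      o$kx_eff[i] <- if (vi$damage) kx_closure(min(psix, 0)) else xylem_vuln(psix, traits)
      o$kl_eff[i] <- if (vi$damage) kl_closure(min(psil, 0)) else leaf_vuln(psil, traits)
      o$kr[i] <- kr

      # damage memory (suspended when leafless unless asked otherwise)
      if (vi$damage && (lai > 0 || ctl$track_dormant)) {
        coh_x <- update_min_potential(coh_x, min(psix, 0))
        coh_l <- update_min_potential(coh_l, min(psil, 0))
        rebuild_damage <- TRUE
      }
    }
    o$psis[i] <- psis
    o$lai[i] <- lai
    soil <- step_soil_water(soil, uptake = max(uptake, 0), precip = precip[i],
                            dt = 3600)
    theta_mat[i, ] <- soil$layers$theta
    day_gpp <- day_gpp + o$gpp[i]

    # daily vegetation / cohort step ---------------------------------------
    if (i %% 24 == 0) {
      gpp_kgc <- day_gpp / 24 * 86400 * 1e-6 * 0.012  # umol m-2 s-1 -> kg C m-2 d-1
      if (dynamic_veg) {
        cs <- step_carbon(pools, gpp_kgc, dt = 1)
        pools <- cs$pools
        new_lai <- lai_from_leaf_carbon(pools)
        if (vi$storage && new_lai > 0 && lai_prev > 0) {
          # keep relative leaf water content across the capacity change
          vl <- vl * storage_capacities(traits, new_lai)$vlmax /
            storage_capacities(traits, lai_prev)$vlmax
        }
        lai_prev <- new_lai
        if (vi$damage) {
          coh_x <- advance_cohorts(coh_x, cs$lambda_sap, cs$mu_sap, dt = 1)
          coh_l <- advance_cohorts(coh_l, cs$lambda_leaf, cs$mu_leaf, dt = 1)
          rebuild_damage <- TRUE
        }
      }
      day_gpp <- 0
    }

    if (!is.na(ctl$stop_fs) && fs <= ctl$stop_fs) {
      stop_hour <- i
      break
    }
  }

  keep <- if (is.na(stop_hour)) seq_len(n) else seq_len(stop_hour)
  hourly <- tibble::tibble(
    time = forcing$time[keep], Ta = ta[keep], SWdown = sw[keep], D = d[keep],
    precip = precip[keep],
    psis = o$psis[keep], psix = o$psix[keep], psil = o$psil[keep],
    Vx = o$vx[keep], Vl = o$vl[keep],
    kx_eff = o$kx_eff[keep], kl_eff = o$kl_eff[keep], kr = o$kr[keep],
    fs = o$fs[keep], fl = o$fl[keep], gs = o$gs[keep], ci = o$ci[keep],
    An = o$an[keep], GPP = o$gpp[keep], T = o$t[keep],
    Jsx = o$jsx[keep], Jxl = o$jxl[keep], LAI = o$lai[keep],
    fallback = o$fallback[keep]
  )
  th <- theta_mat[keep, , drop = FALSE]
  colnames(th) <- paste0("theta_", seq_len(nl))
  hourly <- dplyr::bind_cols(hourly, tibble::as_tibble(th))

  daily <- hourly |>
    dplyr::mutate(day = (dplyr::row_number() - 1) %/% 24 + 1) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      GPP = mean(.data$GPP),
      T_mm = sum(.data$T) * 3600 * 1000,
      psis = min(.data$psis),
      psil_min = suppressWarnings(min(.data$psil)),
      kx_eff_min = suppressWarnings(min(.data$kx_eff)),
      fs_min = min(.data$fs),
      LAI = mean(.data$LAI),
      n_hours = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(WUE = ifelse(.data$T_mm > 0, .data$GPP / .data$T_mm, NA_real_))

  structure(
    list(
      hourly = hourly, daily = daily,
      meta = list(variant = variant, stomata = stomata, seed = seed,
                  dynamic_veg = dynamic_veg, n_hours = length(keep),
                  relief_hour = ctl$relief_hour, stop_hour = stop_hour,
                  fallback_count = fallback_count),
      state = list(soil = soil, vx = vx, vl = vl, guess = guess,
                   cohorts_x = coh_x, cohorts_l = coh_l, pools = pools,
                   lai = lai_prev)
    ),
    class = "spac_run"
  )
}

#' @export
print.spac_run <- function(x, ...) {
  cat("<spac_run> variant=", x$meta$variant, " (", x$meta$stomata, "), ",
      x$meta$n_hours, " hours, ", nrow(x$daily), " days",
      if (x$meta$fallback_count > 0) paste0(", ", x$meta$fallback_count,
                                            " fallback solves"),
      "\n", sep = "")
  invisible(x)
}
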