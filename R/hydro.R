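#' Plant hydraulic traits
#'
#' Trait container for one vegetation type: maximum xylem and leaf
#' conductances with their vulnerability-curve shapes, plant geometry
#' (height, xylem cross-sectional area per ground area), storage traits
#' (xylem water-holding capacity, leaf mass per area, leaf dry-matter
#' content, minimum potentials at zero storage) and leaf area index.
#' Defaults describe an evergreen broadleaf forest with substantial stem
#' water storage (see the package vignette for the reasoning).
#'
#' @param kxmax Maximum xylem conductance at zero potential
#'   \[m s-1 MPa-1\]; alternatively supply `kx_tissue` (tissue-level
#'   conductivity, \[kg m-1 s-1 MPa-1\]) and it is scaled with
#'   [conductance_scaling()].
#' @param qx,px Xylem vulnerability shape: `kx = kxmax exp(-qx |psi|^px)`.
#' @param klmax,ql,pl Leaf conductance equivalents.
#' @param h Plant height \[m\].
#' @param ax Xylem cross-sectional area per ground area \[m2 m-2\].
#' @param nx Water-holding capacity of xylem conduits \[-\], in (0, 1\].
#' @param lma Leaf mass per area \[kg m-2\].
#' @param ldmc Leaf dry-matter content \[g g-1\], in (0, 1).
#' @param cx,cl Minimum xylem and leaf water potentials at zero storage
#'   \[MPa, < 0\].
#' @param lai Leaf area index \[m2 m-2\].
#' @param kx_tissue Optional tissue-level xylem conductivity used to derive
#'   `kxmax` when the latter is `NULL`.
#' @return An object of class `plant_traits`.
#' @export
#' @examples
#' tr <- plant_traits()
#' storage_capacities(tr)
plant_traits <- function(kxmax = 4e-7, qx = log(2) / 9, px = 2,
                         klmax = 8e-7, ql = log(2) / 4, pl = 2,
                         h = 20, ax = 4e-3, nx = 0.5,
                         lma = 0.15, ldmc = 0.30,
                         cx = -8, cl = -4, lai = 3,
                         kx_tissue = NULL) {
  if (is.null(kxmax)) {
    if (is.null(kx_tissue)) stop("supply `kxmax` or `kx_tissue`", call. = FALSE)
    kxmax <- conductance_scaling(kx_tissue, h, ax)
  }
  stopifnot(kxmax > 0, klmax > 0, qx > 0, px > 0, ql > 0, pl > 0,
            h > 0, ax > 0, nx > 0, nx <= 1, lma > 0,
            ldmc > 0, ldmc < 1, cx < 0, cl < 0, lai >= 0)
  structure(
    list(kxmax = kxmax, qx = qx, px = px, klmax = klmax, ql = ql, pl = pl,
         h = h, ax = ax, nx = nx, lma = lma, ldmc = ldmc,
         cx = cx, cl = cl, lai = lai),
    class = "plant_traits"
  )
}

#' @export
print.plant_traits <- function(x, ...) {
  cap <- storage_capacities(x)
  cat("<plant_traits> kxmax=", signif(x$kxmax, 3), " klmax=", signif(x$klmax, 3),
      " m s-1 MPa-1; h=", x$h, " m; LAI=", x$lai,
      "; Vxmax=", signif(cap$vxmax, 3), " m; Vlmax=", signif(cap$vlmax, 3),
      " m\n", sep = "")
  invisible(x)
}

#' Scale tissue xylem conductivity to a ground-area conductance
#'
#' `kxmax = k'x * Ax / (h * rho_w)`: conductance falls with path length
#' (height) and rises with conducting area per ground area.
#'
#' @param kx_tissue Tissue conductivity \[kg m-1 s-1 MPa-1\].
#' @param h Plant height \[m\].
#' @param ax Xylem cross-sectional area per ground area \[m2 m-2\].
#' @return Maximum xylem conductance \[m s-1 MPa-1\].
#' @export
#' @examples
#' conductance_scaling(1, h = 20, ax = 2e-3)  # 1e-7
conductance_scaling <- function(kx_tissue, h, ax) {
  stopifnot(h > 0, ax > 0)
  kx_tissue * ax / (h * .const$rho_w)
}

.vuln <- function(psi, kmax, q, p) {
  kmax * exp(-q * abs(pmin(psi, 0))^p)
}

#' Xylem vulnerability curve
#'
#' `kx = kxmax exp(-qx |psi_x|^px)`, strictly decreasing in tension.
#'
#' @param psix Xylem water potential \[MPa, <= 0\].
#' @param traits A [plant_traits()] object.
#' @return Xylem conductance \[m s-1 MPa-1\].
#' @export
xylem_vuln <- function(psix, traits) .vuln(psix, traits$kxmax, traits$qx, traits$px)

#' Leaf vulnerability curve
#'
#' @param psil Leaf water potential \[MPa, <= 0\].
#' @inheritParams xylem_vuln
#' @return Leaf conductance \[m s-1 MPa-1\].
#' @export
leaf_vuln <- function(psil, traits) .vuln(psil, traits$klmax, traits$ql, traits$pl)

#' Maximum xylem and leaf water storage
#'
#' `Vxmax = h * Ax * nx` and
#' `Vlmax = LAI * LMA * (1 - LDMC) / LDMC / rho_w`, both in m of water per
#' m2 of ground.
#'
#' @param traits A [plant_traits()] object.
#' @param lai Optional leaf area index overriding `traits$lai` (dynamic
#'   vegetation).
#' @return A list with `vxmax` and `vlmax` \[m\].
#' @export
storage_capacities <- function(traits, lai = traits$lai) {
  list(
    vxmax = traits$h * traits$ax * traits$nx,
    vlmax = lai * traits$lma * (1 - traits$ldmc) / traits$ldmc / .const$rho_w
  )
}

#' Linear pressure-volume curve
#'
#' `psi = c (1 - V / Vmax)`: zero at full storage, `c` (the minimum
#' potential) at zero storage. Invertible; see [pv_volume()].
#'
#' @param v Stored water \[m\].
#' @param vmax Storage capacity \[m\], > 0.
#' @param c_min Minimum potential at zero storage \[MPa, < 0\].
#' @return Water potential \[MPa\].
#' @export
pv_psi <- function(v, vmax, c_min) {
  if (any(vmax <= 0)) stop("Vmax must be positive (leafless states are handled upstream)",
                           call. = FALSE)
  stopifnot(all(c_min < 0))
  c_min * (1 - v / vmax)
}

#' Invert the linear pressure-volume curve
#'
#' @param psi Water potential \[MPa\].
#' @inheritParams pv_psi
#' @return Stored water \[m\].
#' @export
pv_volume <- function(psi, vmax, c_min) {
  if (any(vmax <= 0)) stop("Vmax must be positive", call. = FALSE)
  vmax * (1 - psi / c_min)
}

# Demand curves -------------------------------------------------------------

#' Transpiration demand as a function of leaf water potential
#'
#' For fixed meteorological forcing and soil water potential, tabulates the
#' coupled An-gs-ci solution on a grid of leaf water potentials and returns
#' interpolators for transpiration, realized assimilation, conductance,
#' intercellular CO2 and the down-regulation factor. Both the steady-state
#' solver and the capacitance ODE right-hand side consume these curves, so
#' the stomatal response is evaluated identically in the two variants.
#'
#' @param psis Soil water potential \[MPa\].
#' @param frow A single forcing row (list or one-row tibble with `Ta`,
#'   `SWdown`, `D`, `Patm`, `ca`).
#' @param traits A [plant_traits()] object.
#' @param params A [gas_params()] object.
#' @param model Stomatal model tag (see [solve_ci()]).
#' @param lai Leaf area index; defaults to `traits$lai`.
#' @param n Grid size.
#' @param span Width of the leaf-potential grid below `psis` \[MPa\].
#' @return A list of functions `Tfun`, `Anfun`, `gsfun`, `cifun`, `flfun`
#'   of leaf water potential, plus the `fs` used and the grid range.
#' @export
demand_function <- function(psis, frow, traits, params = gas_params(),
                            model = "tuzet", lai = traits$lai,
                            n = 161, span = 8) {
  fs <- fs_factor(psis, params$p, params$q)
  lo <- min(psis - span, traits$cl - 1)
  grid <- seq(lo, psis, length.out = n)
  fl <- switch(model,
    tuzet = fl_factor(psis, grid, params$al, params$gamma_l),
    tuzet_no_fs = fl_star(grid, params$as, params$gamma_s),
    tuzet_light_only = fl_star(grid, params$as, params$gamma_s),
    leuning = rep(1, n)
  )
  par <- par_from_sw(frow$SWdown)
  sol <- .solve_ci_vec(frow$Ta, par, frow$ca, frow$D, fs, fl, params, model)
  tr <- transp_flux(sol$gs, frow$D, frow$Patm, lai)
  list(
    Tfun = approxfun(grid, tr, rule = 2),
    Anfun = approxfun(grid, sol$an, rule = 2),
    gsfun = approxfun(grid, sol$gs, rule = 2),
    cifun = approxfun(grid, sol$ci, rule = 2),
    flfun = approxfun(grid, fl, rule = 2),
    fs = fs, range = c(lo, psis), lai = lai
  )
}

# Steady-state two-node solve -----------------------------------------------

#' Solve the steady-state plant hydraulic system
#'
#' Finds xylem and leaf water potentials such that the soil-to-xylem flux,
#' the xylem-to-leaf flux and the transpiration demand coincide:
#' `ksx(psi_x) (psi_s - psi_x) = kxl(psi_x, psi_l) (psi_x - psi_l) =
#' T(psi_l)`, where `ksx` is the geometric mean of the soil-to-root and
#' xylem conductances and `kxl` the geometric mean of the xylem and leaf
#' conductances, both evaluated at the unknown potentials. Convergence
#' requires both flux-conservation residuals to be within 1% of the
#' transpiration rate.
#'
#' The vulnerability curves make the system's supply curve non-monotone,
#' so several equilibria can coexist during drought. In a time series
#' (when `guess` is supplied) a Powell dog-leg iteration from the previous
#' solution keeps the run on its branch by continuity. Otherwise the
#' solution is defined as the highest leaf potential at which the
#' equations hold to the 1% standard -- located by a vectorized scan of
#' the constrained box with supply-demand crossing detection, then
#' polished by the dog-leg. When no solution exists at all (deep drought:
#' the residual-conductance demand floor exceeds what the collapsed
#' soil-to-root pathway can carry), a constrained multi-start minimization
#' of `|r1| + |r2|` subject to `psi_s >= psi_x >= psi_l` (default 100
#' seeded random starts) returns the best compromise and the state is
#' flagged (`converged = FALSE`).
#'
#' @param psis Soil water potential \[MPa, <= 0\].
#' @param frow One forcing row (see [demand_function()]).
#' @param traits A [plant_traits()] object.
#' @param params A [gas_params()] object.
#' @param kr Soil-to-root conductance \[m s-1 MPa-1\] from
#'   [soil_root_conductance()].
#' @param model Stomatal model tag.
#' @param guess Optional warm start `c(psix, psil)`.
#' @param demand Optional precomputed [demand_function()] output.
#' @param kx_fun,kl_fun Optional conductance curves overriding the trait
#'   vulnerability curves (used by the damage variants).
#' @param lai Leaf area index.
#' @param control List: `fallback_starts` (default 100), `seed` for the
#'   fallback start sampling, `max_iter`.
#' @return A list with `psix`, `psil`, `T`, `Jsx`, `Jxl`, `kx`, `kl`,
#'   `an`, `gs`, `ci`, `fl`, `fs`, `residual` (max flux residual relative
#'   to T), `converged` and `method` (`"dogleg"` or `"fallback"`).
#' @export
solve_steady <- function(psis, frow, traits, params = gas_params(), kr,
                         model = "tuzet", guess = NULL, demand = NULL,
                         kx_fun = NULL, kl_fun = NULL, lai = traits$lai,
                         control = list()) {
  stopifnot(psis <= 1e-9, kr >= 0)
  ctl <- utils::modifyList(list(fallback_starts = 100, seed = 1, max_iter = 80),
                           control)
  if (is.null(demand)) {
    demand <- demand_function(psis, frow, traits, params, model, lai = lai)
  }
  if (is.null(kx_fun)) kx_fun <- function(psi) xylem_vuln(psi, traits)
  if (is.null(kl_fun)) kl_fun <- function(psi) leaf_vuln(psi, traits)

  t_eq <- demand$Tfun(psis)
  out_state <- function(psix, psil, method, residual, converged) {
    tt <- demand$Tfun(psil)
    kx <- kx_fun(psix); kl <- kl_fun(psil)
    list(psix = psix, psil = psil, T = tt,
         Jsx = sqrt(kr * kx) * (psis - psix),
         Jxl = sqrt(kx * kl) * (psix - psil),
         kx = kx, kl = kl, kr = kr,
         an = demand$Anfun(psil), gs = demand$gsfun(psil),
         ci = demand$cifun(psil), fl = demand$flfun(psil), fs = demand$fs,
         residual = residual, converged = converged, method = method)
  }

  # zero-demand equilibrium (dark with g0 = 0, or leafless)
  if (t_eq <= 1e-16 || kr <= 0 || lai <= 0) {
    return(out_state(psis, psis, "equilibrium", 0, TRUE))
  }

  resfun <- function(x) {
    psix <- min(x[1], 0); psil <- min(x[2], psix)
    tt <- demand$Tfun(psil)
    kx <- kx_fun(psix)
    c(sqrt(kr * kx) * (psis - psix) - tt,
      sqrt(kx * kl_fun(psil)) * (psix - psil) - tt)
  }

  tol_quick <- function(x) max(0.01 * demand$Tfun(min(x[2], x[1])), 1e-15)
  # warm start: in a time series the physical solution follows the branch it
  # was on (continuity), so the previous hour's potentials seed a dog-leg
  # attempt before any global analysis
  if (!is.null(guess)) {
    sol <- dogleg_solve(resfun, pmin(guess, c(psis, psis)),
                        max_iter = ctl$max_iter)
    resid <- max(abs(resfun(sol$x)))
    if (is.finite(resid) && resid < tol_quick(sol$x)) {
      psix <- min(sol$x[1], 0); psil <- min(sol$x[2], psix)
      return(out_state(psix, psil, "dogleg",
                       resid / max(demand$Tfun(psil), 1e-300), TRUE))
    }
  }

  # globalization: for each candidate leaf potential, minimize the residual
  # sum |r1| + |r2| over the xylem potential (a coarse scan followed by a
  # vectorized golden-section refinement; the sum is piecewise smooth and
  # unimodal around its minima). Leaf potentials whose minimized residual
  # is within 1% of the local flux are 1%-converged solutions; the topmost
  # such band is the branch reached by continuity from wet conditions, and
  # its interior minimum seeds the dog-leg polish.
  s1_of <- function(px) sqrt(kr * kx_fun(px)) * (psis - px)
  s2_of <- function(px, pl) sqrt(kx_fun(px) * kl_fun(pl)) * (px - pl)
  val_at <- function(pl) {
    n_ <- length(pl)
    tt <- demand$Tfun(pl)
    fres <- function(px) abs(s1_of(px) - tt) + abs(s2_of(px, pl) - tt)
    m_ <- 41
    tg <- seq(0, 1, length.out = m_)
    fv <- matrix(NA_real_, n_, m_)
    for (jj in seq_len(m_)) {
      fv[, jj] <- fres(pl + (psis - pl) * tg[jj])
    }
    jmin <- max.col(-fv, ties.method = "first")
    a <- pl + (psis - pl) * tg[pmax(jmin - 1, 1)]
    b <- pl + (psis - pl) * tg[pmin(jmin + 1, m_)]
    phi <- (sqrt(5) - 1) / 2
    for (it in 1:30) {
      x1 <- b - phi * (b - a)
      x2 <- a + phi * (b - a)
      take1 <- fres(x1) < fres(x2)
      b <- ifelse(take1, x2, b)
      a <- ifelse(take1, a, x1)
    }
    px <- 0.5 * (a + b)
    list(val = fres(px), px = px)
  }
  nl_ <- 201
  pls <- seq(demand$range[1], psis, length.out = nl_)
  va <- val_at(pls)
  rel <- va$val / pmax(demand$Tfun(pls), 1e-12)
  in_band <- rel <= 0.01
  # steep isolated roots can hide between grid points; the sign of the
  # supply-demand gap at the segment-continuity potential exposes them
  pxc <- {
    lo <- pls
    hi <- rep(psis, nl_)
    for (it in 1:45) {
      mid <- 0.5 * (lo + hi)
      up <- s1_of(mid) - s2_of(mid, pls) > 0
      lo <- ifelse(up, mid, lo)
      hi <- ifelse(up, hi, mid)
    }
    0.5 * (lo + hi)
  }
  gapc <- s1_of(pxc) - demand$Tfun(pls)
  crossing <- which(sign(gapc[-nl_]) * sign(gapc[-1]) < 0)
  cont_gap <- function(pl) {
    lo <- pl; hi <- psis
    for (it in 1:45) {
      mid <- 0.5 * (lo + hi)
      if (s1_of(mid) - s2_of(mid, pl) > 0) lo <- mid else hi <- mid
    }
    s1_of(0.5 * (lo + hi)) - demand$Tfun(pl)
  }

  rel_at <- function(pl) val_at(pl)$val / max(demand$Tfun(pl), 1e-12)
  tol_of <- function(x) max(0.01 * demand$Tfun(min(x[2], x[1])), 1e-15)

  j_band <- if (any(in_band)) max(which(in_band)) else 0L
  j_cross <- if (length(crossing)) max(crossing) else 0L
  anchor <- NULL
  if (j_cross > j_band) {
    # bisect the gap sign change to land inside the hidden band
    a <- pls[j_cross]; b <- pls[j_cross + 1]
    sa <- sign(gapc[j_cross])
    for (it in 1:25) {
      mid <- 0.5 * (a + b)
      if (sign(cont_gap(mid)) == sa) a <- mid else b <- mid
    }
    if (rel_at(0.5 * (a + b)) <= 0.01) {
      anchor <- 0.5 * (a + b)
      upper <- pls[j_cross + 1]
    }
  } else if (j_band > 0L) {
    anchor <- pls[j_band]
    upper <- if (j_band < nl_) pls[j_band + 1] else psis
  }

  if (!is.null(anchor)) {
    # the solution is the highest leaf potential at which both equations
    # hold to within 1% of the local flux (the model's accuracy standard),
    # on the branch reached by continuity from wet conditions
    a <- anchor; b <- upper
    for (it in 1:15) {
      mid <- 0.5 * (a + b)
      if (rel_at(mid) <= 0.01) a <- mid else b <- mid
    }
    pl_star <- a
    x <- c(val_at(pl_star)$px, pl_star)
    # dog-leg polish onto the exact root, accepted when it stays on the
    # same branch (flux essentially unchanged)
    sol <- dogleg_solve(resfun, x, max_iter = ctl$max_iter)
    if (is.finite(sol$fnorm)) {
      resid_p <- max(abs(resfun(sol$x)))
      same_flux <- abs(demand$Tfun(min(sol$x[2], sol$x[1])) -
                         demand$Tfun(pl_star)) <=
        0.0025 * max(demand$Tfun(pl_star), 1e-300)
      if (resid_p < tol_of(sol$x) && same_flux) x <- sol$x
    }
    resid <- max(abs(resfun(x)))
    if (resid < tol_of(x)) {
      psix <- min(x[1], 0); psil <- min(x[2], psix)
      return(out_state(psix, psil, "dogleg",
                       resid / max(demand$Tfun(psil), 1e-300), TRUE))
    }
  }
  scan_pt <- {
    j <- which.min(va$val)                       # closest approach
    c(va$px[j], pls[j])
  }

  # seeded constrained multi-start; the scan point, the supply-maximizing
  # xylem potential and (when available) the previous solution join the
  # start set
  xs <- pls[which.max(sqrt(kr * kx_fun(pls)) * (psis - pls))]
  extra <- rbind(scan_pt, c(xs, xs - 1), c(xs, xs - 3))
  if (!is.null(guess)) extra <- rbind(pmin(guess, psis), extra)
  fb <- fallback_multistart(resfun, psis, n_starts = ctl$fallback_starts,
                            seed = ctl$seed, extra_starts = extra)
  resid <- max(abs(resfun(fb$x)))
  psix <- min(fb$x[1], 0); psil <- min(fb$x[2], psix)
  tt <- demand$Tfun(psil)
  out_state(psix, psil, "fallback", resid / max(tt, 1e-300),
            resid < max(0.01 * tt, 1e-15))
}

# Capacitance ODE system ------------------------------------------------------

# smooth 0..1 ramp used to shut fluxes down as a store empties
.ramp <- function(x) pmin(pmax(x, 0), 1)

#' Right-hand side of the plant water storage ODEs
#'
#' `dVx/dt = Js->x - Jx->l` and `dVl/dt = Jx->l - T`, with potentials from
#' the linear pressure-volume curves, `Js->x = max(0, ksx (psi_s - psi_x))`
#' (water may not move from the xylem back to the soil), a bidirectional
#' xylem-to-leaf flux (night-time leaf refill is allowed), and the
#' transpiration demand evaluated at the current leaf potential.
#'
#' @param vx,vl Xylem and leaf water storage \[m\].
#' @param psis Soil water potential \[MPa\].
#' @param demand A [demand_function()] list.
#' @param traits A [plant_traits()] object.
#' @param kr Soil-to-root conductance \[m s-1 MPa-1\].
#' @param kx_fun,kl_fun Optional conductance curves (damage variants).
#' @param caps Storage capacities from [storage_capacities()].
#' @return A list with `dvx`, `dvl`, the fluxes `Jsx`, `Jxl`, `T` and the
#'   potentials `psix`, `psil`.
#' @export
rhs_capacitance <- function(vx, vl, psis, demand, traits, kr,
                            kx_fun = NULL, kl_fun = NULL,
                            caps = storage_capacities(traits, demand$lai)) {
  if (is.null(kx_fun)) kx_fun <- function(psi) xylem_vuln(psi, traits)
  if (is.null(kl_fun)) kl_fun <- function(psi) leaf_vuln(psi, traits)
  psix <- pv_psi(vx, caps$vxmax, traits$cx)
  psil <- pv_psi(vl, caps$vlmax, traits$cl)
  kx <- kx_fun(psix); kl <- kl_fun(psil)
  jsx <- max(0, sqrt(kr * kx) * (psis - psix))
  jxl <- sqrt(kx * kl) * (psix - psil)
  # empty-store guards: outflow shuts down smoothly as a store drains
  if (jxl > 0) jxl <- jxl * .ramp(vx / (1e-3 * caps$vxmax))
  tt <- demand$Tfun(psil) * .ramp(vl / (0.01 * caps$vlmax))
  list(dvx = jsx - jxl, dvl = jxl - tt,
       Jsx = jsx, Jxl = jxl, T = tt, psix = psix, psil = psil)
}

#' Integrate the storage ODEs over one forcing step
#'
#' Advances `(Vx, Vl)` over `dt` seconds with a time-adaptive stiff
#' integrator (default `lsoda`; any `deSolve` method tag or
#' `deSolve::rkMethod()` name may be supplied, e.g. `"ode23"` for the
#' embedded Runge-Kutta 2(3) pair). The integration also accumulates the
#' soil uptake, transpiration and assimilation integrals, so the hourly
#' water balance `dVx + dVl = int(Js->x - T) dt` holds to solver precision
#' and the soil column can be debited by exactly the water extracted.
#'
#' @param vx,vl Initial storages \[m\].
#' @param psis Soil water potential \[MPa\] (held fixed over the step).
#' @param demand A [demand_function()] list.
#' @param traits A [plant_traits()] object.
#' @param kr Soil-to-root conductance \[m s-1 MPa-1\].
#' @param dt Step length \[s\].
#' @param kx_fun,kl_fun Optional conductance curves (damage variants).
#' @param lai Leaf area index.
#' @param rtol,atol Relative and state tolerances.
#' @param method `deSolve` integration method.
#' @return A list with final `vx`, `vl`, `psix`, `psil`, step-mean fluxes
#'   `T`, `Jsx`, `Jxl` \[m s-1\], step-mean assimilation `an`
#'   \[umol m-2 s-1\], and `balance` (water-balance defect over the step,
#'   \[m\]).
#' @export
step_capacitance <- function(vx, vl, psis, demand, traits, kr, dt = 3600,
                             kx_fun = NULL, kl_fun = NULL, lai = demand$lai,
                             rtol = 1e-6, atol = 1e-12, method = "lsoda") {
  caps <- storage_capacities(traits, lai)
  if (is.null(kx_fun)) kx_fun <- function(psi) xylem_vuln(psi, traits)
  if (is.null(kl_fun)) kl_fun <- function(psi) leaf_vuln(psi, traits)
  deriv <- function(t, y, parms) {
    r <- rhs_capacitance(y[1], y[2], psis, demand, traits, kr,
                         kx_fun, kl_fun, caps)
    an <- demand$Anfun(r$psil)
    list(c(r$dvx, r$dvl, r$Jsx, r$T, an, r$Jxl))
  }
  y0 <- c(vx = vx, vl = vl, cJ = 0, cT = 0, cA = 0, cX = 0)
  sol <- deSolve::ode(y0, times = c(0, dt), func = deriv, parms = NULL,
                      method = method, rtol = rtol,
                      atol = c(atol, atol, 1e-10, 1e-10, 1e-4, 1e-10))
  if (attr(sol, "istate")[1] < 0) {
    stop("capacitance integration failed; state: vx=", vx, " vl=", vl,
         " psis=", psis, call. = FALSE)
  }
  yf <- sol[nrow(sol), -1]
  balance <- (yf[["vx"]] - vx) + (yf[["vl"]] - vl) - (yf[["cJ"]] - yf[["cT"]])
  list(
    vx = yf[["vx"]], vl = yf[["vl"]],
    psix = pv_psi(yf[["vx"]], caps$vxmax, traits$cx),
    psil = pv_psi(yf[["vl"]], caps$vlmax, traits$cl),
    T = yf[["cT"]] / dt, Jsx = yf[["cJ"]] / dt, Jxl = yf[["cX"]] / dt,
    an = yf[["cA"]] / dt, balance = balance
  )
}
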