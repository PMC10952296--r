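#' Gas-exchange and stomatal parameters
#'
#' Parameter container for leaf photosynthesis (Farquhar C3 with peaked
#' Arrhenius temperature responses), the empirical soil-water stress factor
#' `fs = exp(-q |psi_s|^p)`, the hydraulic down-regulation factor
#' `fl = exp(-al |psi_s - psi_l|^gamma_l)` and the stomatal conductance
#' models. By default `(al, gamma_l)` are calibrated with [calibrate_fl()]
#' so that a 1.0 MPa soil-to-leaf potential drop halves stomatal
#' conductance and a 0.2 MPa drop reduces it by 10%.
#'
#' @param vcmax25 Maximum carboxylation rate at 25 degC \[umol m-2 s-1\].
#' @param jmax25 Maximum electron transport rate at 25 degC \[umol m-2 s-1\].
#' @param rd25 Dark respiration at 25 degC \[umol m-2 s-1\].
#' @param g0 Residual stomatal conductance \[mol CO2 m-2 s-1\].
#' @param a1 Stomatal sensitivity to photosynthesis \[-\].
#' @param d0 VPD sensitivity of the Leuning model \[Pa\].
#' @param p,q Shape of the soil-water stress sigmoid `fs`.
#' @param al,gamma_l Shape of the soil-to-leaf down-regulation `fl`;
#'   defaults calibrated to the 1.0 MPa / 50% and 0.2 MPa / 10% anchors.
#' @param a1_star,as,gamma_s Parameters of the decoupled variants
#'   (`fl* = exp(-as |psi_l|^gamma_s)`).
#' @param a1_light Sensitivity of the light-only decoupled variant
#'   \[mol CO2 umol-1\].
#' @param theta_j,alpha_j Curvature and quantum yield of the electron
#'   transport light response.
#' @param oi Intercellular O2 \[mmol mol-1\].
#' @return An object of class `gas_params`.
#' @export
#' @examples
#' gas_params()$al   # ln 2
gas_params <- function(vcmax25 = 60, jmax25 = 110, rd25 = 0.9,
                       g0 = 0.01, a1 = 5, d0 = 1500,
                       p = 2, q = log(2) / 0.8^2,
                       al = NULL, gamma_l = NULL,
                       a1_star = a1, as = NULL, gamma_s = NULL,
                       a1_light = 0.03,
                       theta_j = 0.7, alpha_j = 0.3, oi = 210) {
  if (is.null(al) || is.null(gamma_l)) {
    cal <- calibrate_fl(c(1.0, 0.5), c(0.2, 0.1))
    if (is.null(al)) al <- cal$al
    if (is.null(gamma_l)) gamma_l <- cal$gamma_l
  }
  if (is.null(as)) as <- al
  if (is.null(gamma_s)) gamma_s <- gamma_l
  stopifnot(g0 >= 0, a1 > 0, d0 > 0, p > 0, q > 0, al > 0, gamma_l > 0)
  structure(
    list(vcmax25 = vcmax25, jmax25 = jmax25, rd25 = rd25,
         g0 = g0, a1 = a1, d0 = d0, p = p, q = q,
         al = al, gamma_l = gamma_l, a1_star = a1_star, as = as,
         gamma_s = gamma_s, a1_light = a1_light,
         theta_j = theta_j, alpha_j = alpha_j, oi = oi),
    class = "gas_params"
  )
}

# Temperature responses --------------------------------------------------

.arrhenius <- function(k25, ha, tk) {
  k25 * exp(ha * (tk - 298.15) / (298.15 * .const$R_gas * tk))
}

.peaked <- function(k25, ha, tk, hd = 2e5, ds = 640) {
  f25 <- 1 + exp((298.15 * ds - hd) / (298.15 * .const$R_gas))
  ft <- 1 + exp((tk * ds - hd) / (tk * .const$R_gas))
  .arrhenius(k25, ha, tk) * f25 / ft
}

#' CO2 compensation point at leaf temperature
#'
#' @param ta Leaf (= air) temperature \[degC\].
#' @return Gamma* \[umol mol-1\].
#' @export
gamma_star <- function(ta) .arrhenius(42.75, 37830, ta + 273.15)

#' Dark respiration at leaf temperature
#'
#' @param ta Leaf temperature \[degC\].
#' @param params A [gas_params()] object.
#' @return Rd \[umol m-2 s-1\].
#' @export
dark_respiration <- function(ta, params = gas_params()) {
  .arrhenius(params$rd25, 46390, ta + 273.15)
}

#' Potential (unstressed) net assimilation, Farquhar C3
#'
#' `Anpot = min(Ac, Aj) - Rd` with the Rubisco-limited rate
#' `Ac = Vcmax (ci - Gamma*) / (ci + Kc (1 + O / Ko))`, the RuBP-limited
#' rate `Aj = J/4 (ci - Gamma*) / (ci + 2 Gamma*)`, a non-rectangular
#' hyperbola light response for J, and peaked Arrhenius temperature
#' responses for Vcmax and Jmax. Leaf temperature is taken equal to air
#' temperature (no leaf energy balance).
#'
#' @param ci Intercellular CO2 \[umol mol-1\], > 0.
#' @param ta Air temperature \[degC\].
#' @param par Photosynthetically active radiation \[umol m-2 s-1\].
#' @param params A [gas_params()] object.
#' @return Net potential assimilation \[umol CO2 m-2 s-1\]; equals `-Rd` in
#'   the dark or at the compensation point.
#' @export
#' @examples
#' farquhar_anpot(280, ta = 25, par = 1500)
farquhar_anpot <- function(ci, ta, par, params = gas_params()) {
  stopifnot(all(ci > 0), all(par >= 0))
  tk <- ta + 273.15
  vcmax <- .peaked(params$vcmax25, 65330, tk)
  jmax <- .peaked(params$jmax25, 43540, tk, ds = 647)
  rd <- .arrhenius(params$rd25, 46390, tk)
  kc <- .arrhenius(404.9, 79430, tk)               # [umol mol-1]
  ko <- .arrhenius(278.4, 36380, tk)               # [mmol mol-1]
  gs_ <- gamma_star(ta)
  q2 <- params$alpha_j * par
  j <- (q2 + jmax - sqrt((q2 + jmax)^2 - 4 * params$theta_j * q2 * jmax)) /
    (2 * params$theta_j)
  ac <- vcmax * (ci - gs_) / (ci + kc * (1 + params$oi / ko))
  aj <- j / 4 * (ci - gs_) / (ci + 2 * gs_)
  pmin(ac, aj) - rd
}

# Stress factors ----------------------------------------------------------

#' Empirical soil-water stress factor
#'
#' `fs = exp(-q |psi_s|^p)`: 1 in wet soil, declining sigmoidally as the
#' root-weighted soil water potential falls. Applied multiplicatively to
#' potential assimilation in every model variant.
#'
#' @param psis Soil water potential \[MPa, <= 0\].
#' @param p,q Shape parameters (> 0).
#' @return `fs` in (0, 1\].
#' @export
#' @examples
#' fs_factor(-1, p = 1, q = 1)  # exp(-1)
fs_factor <- function(psis, p = 2, q = log(2) / 0.8^2) {
  stopifnot(p > 0, q > 0)
  if (any(psis > 1e-9)) stop("`psis` must be <= 0", call. = FALSE)
  exp(-q * abs(pmin(psis, 0))^p)
}

#' Hydraulic stomatal down-regulation factor
#'
#' `fl = exp(-al |psi_s - psi_l|^gamma_l)`: 1 at zero soil-to-leaf
#' potential drop, falling as the drop widens. With the default
#' calibration a 1.0 MPa drop gives `fl = 0.5` and a 0.2 MPa drop gives
#' `fl = 0.9`.
#'
#' @param psis,psil Soil and leaf water potential \[MPa\].
#' @param al,gamma_l Shape parameters (> 0); defaults from
#'   [calibrate_fl()].
#' @return `fl` in (0, 1\].
#' @export
fl_factor <- function(psis, psil,
                      al = log(2),
                      gamma_l = log(log(0.9) / log(0.5)) / log(0.2)) {
  stopifnot(al > 0, gamma_l > 0)
  exp(-al * abs(psis - psil)^gamma_l)
}

#' Leaf-potential-only down-regulation factor (decoupled variants)
#'
#' `fl* = exp(-as |psi_l|^gamma_s)`, used by the stomatal variants that
#' are decoupled from soil water potential.
#'
#' @param psil Leaf water potential \[MPa\].
#' @param as,gamma_s Shape parameters.
#' @return `fl*` in (0, 1\].
#' @export
fl_star <- function(psil, as = log(2),
                    gamma_s = log(log(0.9) / log(0.5)) / log(0.2)) {
  exp(-as * abs(pmin(psil, 0))^gamma_s)
}

#' Calibrate the fl down-regulation curve to two anchor points
#'
#' Solves `exp(-al d^gamma) = 1 - r` at two (drop, reduction) anchors in
#' closed form: with `L_i = -log(1 - r_i)`,
#' `gamma_l = log(L1 / L2) / log(d1 / d2)` and `al = L1 / d1^gamma_l`.
#'
#' @param anchor1,anchor2 Numeric pairs `c(drop_MPa, reduction)` with
#'   distinct drops and reductions in (0, 1).
#' @return A list with `al` and `gamma_l`; both anchors are reproduced to
#'   better than 1e-10 relative error.
#' @export
#' @examples
#' calibrate_fl(c(1.0, 0.5), c(0.2, 0.1))
calibrate_fl <- function(anchor1 = c(1.0, 0.5), anchor2 = c(0.2, 0.1)) {
  d <- c(anchor1[1], anchor2[1])
  r <- c(anchor1[2], anchor2[2])
  if (any(r <= 0) || any(r >= 1)) stop("reductions must lie in (0, 1)", call. = FALSE)
  if (any(d <= 0) || d[1] == d[2]) stop("drops must be positive and distinct", call. = FALSE)
  if (sign(d[1] - d[2]) != sign(r[1] - r[2])) {
    stop("anchors are inconsistent: the larger drop must give the larger reduction",
         call. = FALSE)
  }
  L <- -log(1 - r)
  gamma_l <- log(L[1] / L[2]) / log(d[1] / d[2])
  al <- L[1] / d[1]^gamma_l
  for (i in 1:2) {
    got <- 1 - exp(-al * d[i]^gamma_l)
    if (abs(got - r[i]) > 1e-10 * r[i]) {
      stop("calibration failed to reproduce anchors", call. = FALSE)
    }
  }
  list(al = al, gamma_l = gamma_l)
}

# Stomatal conductance ----------------------------------------------------

#' Leuning stomatal conductance
#'
#' `gs = g0 + a1 fs Anpot / ((ci - Gamma)(1 + D / D0))`, floored at `g0`.
#' Conductance is denominated for CO2; the water vapour conductance is
#' `1.6 gs`.
#'
#' @param anpot Potential net assimilation \[umol m-2 s-1\].
#' @param fs Soil-water stress factor in (0, 1\].
#' @param ci Intercellular CO2 \[umol mol-1\].
#' @param gamma CO2 compensation point \[umol mol-1\].
#' @param d Vapour pressure deficit \[Pa\].
#' @param params A [gas_params()] object.
#' @return Stomatal conductance \[mol CO2 m-2 s-1\].
#' @export
gs_leuning <- function(anpot, fs, ci, gamma, d, params = gas_params()) {
  stopifnot(all(d >= 0))
  supply <- ifelse(ci > gamma,
                   params$a1 * fs * anpot / ((ci - gamma) * (1 + d / params$d0)),
                   0)
  params$g0 + pmax(supply, 0)
}

#' Tuzet-style stomatal conductance with hydraulic down-regulation
#'
#' Three modes: `"full"` uses both the soil stress factor and the
#' soil-to-leaf drop, `gs = g0 + a1 fs Anpot fl / (ci - Gamma)`; `"no_fs"`
#' removes the non-stomatal limitation, `gs = g0 + a1* Anpot fl* /
#' (ci - Gamma)`; `"light_only"` also drops the CO2 term,
#' `gs = g0 + a1_light Anpot fl*`. The caller supplies the appropriate
#' `fl` (from [fl_factor()] or [fl_star()]).
#'
#' @inheritParams gs_leuning
#' @param fl Hydraulic down-regulation factor in (0, 1\].
#' @param mode One of `"full"`, `"no_fs"`, `"light_only"`.
#' @return Stomatal conductance \[mol CO2 m-2 s-1\].
#' @export
gs_tuzet <- function(anpot, fs, fl, ci, gamma, params = gas_params(),
                     mode = c("full", "no_fs", "light_only")) {
  mode <- match.arg(mode)
  supply <- switch(mode,
    full = ifelse(ci > gamma, params$a1 * fs * anpot * fl / (ci - gamma), 0),
    no_fs = ifelse(ci > gamma, params$a1_star * anpot * fl / (ci - gamma), 0),
    light_only = params$a1_light * anpot * fl
  )
  params$g0 + pmax(supply, 0)
}

# An-gs-ci coupling --------------------------------------------------------

.gs_of <- function(anpot, ci, gamma, d, fs, fl, params, model) {
  switch(model,
    leuning = gs_leuning(anpot, fs, ci, gamma, d, params),
    tuzet = gs_tuzet(anpot, fs, fl, ci, gamma, params, "full"),
    tuzet_no_fs = gs_tuzet(anpot, fs, fl, ci, gamma, params, "no_fs"),
    tuzet_light_only = gs_tuzet(anpot, fs, fl, ci, gamma, params, "light_only"),
    stop("unknown stomatal model: ", model, call. = FALSE)
  )
}

.an_realized <- function(anpot, fs, model) {
  # the decoupled variants remove the non-stomatal limitation
  if (model %in% c("tuzet_no_fs", "tuzet_light_only")) anpot else fs * anpot
}

# Vectorized bisection on the diffusion fixed point
# f(ci) = An(ci) - gs(ci) * (ca - ci), increasing in ci.
.solve_ci_vec <- function(ta, par, ca, d, fs, fl, params, model, iters = 60L) {
  n <- max(length(ta), length(par), length(ca), length(d), length(fs), length(fl))
  ta <- rep_len(ta, n); par <- rep_len(par, n); ca <- rep_len(ca, n)
  d <- rep_len(d, n); fs <- rep_len(fs, n); fl <- rep_len(fl, n)
  gs_ <- gamma_star(ta)
  resid <- function(ci) {
    anpot <- farquhar_anpot(ci, ta, par, params)
    an <- .an_realized(anpot, fs, model)
    g <- .gs_of(anpot, ci, gs_, d, fs, fl, params, model)
    an - g * (ca - ci)
  }
  lo <- gs_ + 1e-9
  hi <- ca + 2000 + 200 / max(params$g0, 1e-4)
  for (k in seq_len(iters)) {
    mid <- 0.5 * (lo + hi)
    up <- resid(mid) > 0
    hi <- ifelse(up, mid, hi)
    lo <- ifelse(up, lo, mid)
  }
  ci <- 0.5 * (lo + hi)
  anpot <- farquhar_anpot(ci, ta, par, params)
  an <- .an_realized(anpot, fs, model)
  g <- .gs_of(anpot, ci, gs_, d, fs, fl, params, model)
  # degenerate case: g0 = 0 and no carbon gain -> stomata fully shut, no
  # diffusion constraint; report ci = ca with zero conductance
  shut <- g <= 0 & an < 0
  if (any(shut)) {
    ci[shut] <- ca[shut]
    anpot[shut] <- farquhar_anpot(ca[shut], ta[shut], par[shut], params)
    an[shut] <- .an_realized(anpot[shut], fs[shut], model)
    g[shut] <- 0
  }
  list(ci = ci, anpot = anpot, an = an, gs = g)
}

#' Solve the An-gs-ci diffusion fixed point
#'
#' Finds the intercellular CO2 concentration at which the realized net
#' assimilation equals the diffusive supply `gs (ca - ci)` (with `gs` a
#' CO2 conductance), for any of the stomatal models. The realized
#' assimilation is `fs * Anpot` (non-stomatal convention) except in the
#' decoupled variants, where it is `Anpot`. The fixed point is bracketed
#' and bisected; the residual at the reported root is below 1e-8.
#'
#' @param ta Air temperature \[degC\].
#' @param par PAR \[umol m-2 s-1\].
#' @param ca Atmospheric CO2 \[umol mol-1\], > 0.
#' @param d Vapour pressure deficit \[Pa\].
#' @param fs Soil stress factor (default 1).
#' @param fl Hydraulic down-regulation factor (default 1).
#' @param params A [gas_params()] object.
#' @param model Stomatal model tag: `"leuning"`, `"tuzet"`,
#'   `"tuzet_no_fs"` or `"tuzet_light_only"`.
#' @return A tibble with `ci` \[umol mol-1\], `anpot`, `an`
#'   \[umol m-2 s-1\] and `gs` \[mol CO2 m-2 s-1\].
#' @export
#' @examples
#' solve_ci(ta = 25, par = 1500, ca = 400, d = 1000)
solve_ci <- function(ta, par, ca, d, fs = 1, fl = 1,
                     params = gas_params(),
                     model = c("leuning", "tuzet", "tuzet_no_fs",
                               "tuzet_light_only")) {
  model <- match.arg(model)
  stopifnot(all(ca > 0))
  sol <- .solve_ci_vec(ta, par, ca, d, fs, fl, params, model)
  res <- ifelse(sol$gs <= 0, 0, sol$an - sol$gs * (ca - sol$ci))
  if (any(abs(res) > 1e-6)) {
    stop("ci solve did not converge; residual = ", max(abs(res)), call. = FALSE)
  }
  tibble::as_tibble(sol)
}

#' Canopy transpiration from stomatal conductance
#'
#' `T = 1.6 gs (D / Patm) Mw / rho_w * LAI`: leaf-level water vapour flux
#' (water conductance is 1.6 times the CO2 conductance) scaled linearly to
#' ground area by leaf area index.
#'
#' @param gs Stomatal conductance \[mol CO2 m-2 leaf s-1\].
#' @param d Vapour pressure deficit \[Pa\].
#' @param patm Atmospheric pressure \[Pa\].
#' @param lai Leaf area index \[m2 m-2\].
#' @return Transpiration \[m s-1, per ground area\].
#' @export
#' @examples
#' transp_flux(0.2, d = 1000, patm = 101325, lai = 1)  # ~5.7e-8 m s-1
transp_flux <- function(gs, d, patm, lai = 1) {
  stopifnot(all(patm > 0), all(d >= 0))
  1.6 * gs * (d / patm) * .const$Mw / .const$rho_w * lai
}
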