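#' Van Genuchten-Mualem retention model
#'
#' Parameter container for the van Genuchten (1980) retention curve with
#' the Mualem conductivity model. `alpha` is expressed per MPa so that all
#' potentials in the package are negative MPa.
#'
#' @param theta_r,theta_s Residual and saturated volumetric water content
#'   \[m3 m-3\].
#' @param alpha Inverse air-entry scale \[MPa-1\].
#' @param n Pore-size distribution shape (> 1); `m = 1 - 1/n`.
#' @param ks_sat Saturated hydraulic conductivity \[m s-1\].
#' @return An object of class `c("vg_retention", "retention")`.
#' @export
#' @examples
#' vg_retention(0.06, 0.45, alpha = 367, n = 1.56, ks_sat = 2.9e-6)
vg_retention <- function(theta_r, theta_s, alpha, n, ks_sat) {
  stopifnot(theta_s > theta_r, theta_r >= 0, alpha > 0, n > 1, ks_sat > 0)
  structure(
    list(theta_r = theta_r, theta_s = theta_s, alpha = alpha, n = n,
         m = 1 - 1 / n, ks_sat = ks_sat),
    class = c("vg_retention", "retention")
  )
}

#' Clapp-Hornberger retention model
#'
#' Power-law retention and conductivity dialect: `psi = psi_sat * (theta /
#' theta_s)^(-b)` and `k = ks_sat * (theta / theta_s)^(2 b + 3)`.
#'
#' @param theta_s Saturated water content \[m3 m-3\].
#' @param psi_sat Air-entry (saturated) potential \[MPa, < 0, close to 0\].
#' @param b Pore-size index.
#' @param ks_sat Saturated conductivity \[m s-1\].
#' @param theta_r Residual water content (default 0).
#' @return An object of class `c("ch_retention", "retention")`.
#' @export
ch_retention <- function(theta_s, psi_sat = -1e-3, b = 5, ks_sat = 2.9e-6,
                         theta_r = 0) {
  stopifnot(theta_s > theta_r, psi_sat < 0, b > 0, ks_sat > 0)
  structure(
    list(theta_r = theta_r, theta_s = theta_s, psi_sat = psi_sat, b = b,
         ks_sat = ks_sat),
    class = c("ch_retention", "retention")
  )
}

.clamp_theta <- function(theta, ret, warn = TRUE) {
  lo <- ret$theta_r + 1e-12
  hi <- ret$theta_s
  if (warn && any(theta < lo - 1e-9 | theta > hi + 1e-9)) {
    warning("theta outside [theta_r, theta_s]; clamped", call. = FALSE)
  }
  pmin(pmax(theta, lo), hi)
}

#' Soil water potential from water content
#'
#' Applies the retention curve; potentials are negative MPa (0 at
#' saturation).
#'
#' @param theta Volumetric water content \[m3 m-3\].
#' @param ret A retention object from [vg_retention()] or [ch_retention()].
#' @param warn Warn when `theta` is clamped to its bounds.
#' @return Water potential \[MPa, <= 0\], strictly increasing in `theta`.
#' @export
retention_psi <- function(theta, ret, warn = TRUE) UseMethod("retention_psi", ret)

#' @export
retention_psi.vg_retention <- function(theta, ret, warn = TRUE) {
  theta <- .clamp_theta(theta, ret, warn)
  se <- (theta - ret$theta_r) / (ret$theta_s - ret$theta_r)
  -(1 / ret$alpha) * (pmax(se, 1e-12)^(-1 / ret$m) - 1)^(1 / ret$n)
}

#' @export
retention_psi.ch_retention <- function(theta, ret, warn = TRUE) {
  theta <- .clamp_theta(theta, ret, warn)
  pmin(ret$psi_sat * (theta / ret$theta_s)^(-ret$b), 0)
}

#' Water content from potential (retention inverse)
#'
#' @param psi Water potential \[MPa, <= 0\].
#' @inheritParams retention_psi
#' @return Volumetric water content \[m3 m-3\].
#' @export
retention_theta <- function(psi, ret) UseMethod("retention_theta", ret)

#' @export
retention_theta.vg_retention <- function(psi, ret) {
  se <- (1 + (ret$alpha * pmax(-psi, 0))^ret$n)^(-ret$m)
  ret$theta_r + se * (ret$theta_s - ret$theta_r)
}

#' @export
retention_theta.ch_retention <- function(psi, ret) {
  pmin(ret$theta_s * (pmin(psi, ret$psi_sat) / ret$psi_sat)^(-1 / ret$b),
       ret$theta_s)
}

#' Unsaturated hydraulic conductivity from water content
#'
#' Mualem form for van Genuchten, power law for Clapp-Hornberger.
#'
#' @inheritParams retention_psi
#' @return Conductivity \[m s-1\], increasing in `theta`, `ks_sat` at
#'   saturation.
#' @export
unsat_conductivity <- function(theta, ret, warn = TRUE) UseMethod("unsat_conductivity", ret)

#' @export
unsat_conductivity.vg_retention <- function(theta, ret, warn = TRUE) {
  theta <- .clamp_theta(theta, ret, warn)
  se <- pmin(pmax((theta - ret$theta_r) / (ret$theta_s - ret$theta_r), 1e-12), 1)
  ret$ks_sat * sqrt(se) * (1 - (1 - se^(1 / ret$m))^ret$m)^2
}

#' @export
unsat_conductivity.ch_retention <- function(theta, ret, warn = TRUE) {
  theta <- .clamp_theta(theta, ret, warn)
  ret$ks_sat * (theta / ret$theta_s)^(2 * ret$b + 3)
}

#' Layered soil column
#'
#' A bucket soil column: ordered layers with thickness, water content and
#' fine-root fraction, a shared retention model, and the root geometry of
#' the soil-to-root conductance (root length index, soil-cylinder radius,
#' root radius).
#'
#' @param depths Layer thicknesses \[m\].
#' @param theta Initial volumetric water content per layer (recycled).
#' @param root_frac Fine-root fraction per layer; must sum to 1.
#' @param retention A retention object shared by all layers.
#' @param Rl Root length index \[m root m-2 ground\].
#' @param rc Radius of the soil cylinder accessed by a root \[m\].
#' @param rr Root radius \[m\]; must satisfy `rc > rr > 0`.
#' @return An object of class `soil_column`.
#' @export
#' @examples
#' soil_column(c(0.3, 0.3, 0.4), theta = 0.45,
#'             retention = vg_retention(0.06, 0.45, 367, 1.56, 2.9e-6))
soil_column <- function(depths, theta, root_frac = rep(1 / length(depths), length(depths)),
                        retention, Rl = 6000, rc = 0.05, rr = 5e-4) {
  stopifnot(length(depths) >= 1, all(depths > 0))
  if (abs(sum(root_frac) - 1) > 1e-10) stop("root fractions must sum to 1", call. = FALSE)
  if (!(rc > rr && rr > 0)) stop("need rc > rr > 0", call. = FALSE)
  if (Rl <= 0) stop("Rl must be positive", call. = FALSE)
  if (!inherits(retention, "retention")) stop("invalid retention model", call. = FALSE)
  theta <- rep_len(theta, length(depths))
  theta <- .clamp_theta(theta, retention, warn = TRUE)
  structure(
    list(layers = tibble::tibble(depth = depths, theta = theta, w = root_frac),
         retention = retention, Rl = Rl, rc = rc, rr = rr),
    class = "soil_column"
  )
}

#' @export
print.soil_column <- function(x, ...) {
  cat("<soil_column> ", nrow(x$layers), " layers, total depth ",
      sum(x$layers$depth), " m, retention: ", class(x$retention)[1], "\n", sep = "")
  print(x$layers)
  invisible(x)
}

#' Total water stored in a soil column
#'
#' @param column A [soil_column()].
#' @return Stored water \[m\].
#' @export
soil_water_storage <- function(column) {
  sum(column$layers$theta * column$layers$depth)
}

#' Root-weighted soil water potential
#'
#' The retention curve applied to the root-fraction-weighted water content,
#' `psi_s = P(sum_i w_i theta_i)`.
#'
#' @param column A [soil_column()].
#' @param per_layer If `TRUE`, weight per-layer potentials instead of
#'   weighting water content first (alternative reading; default `FALSE`).
#' @return Soil water potential \[MPa, <= 0\].
#' @export
root_weighted_psi <- function(column, per_layer = FALSE) {
  ly <- column$layers
  if (per_layer) {
    sum(ly$w * retention_psi(ly$theta, column$retention, warn = FALSE))
  } else {
    retention_psi(sum(ly$w * ly$theta), column$retention, warn = FALSE)
  }
}

#' Soil-to-root conductance
#'
#' Radial conductance from the bulk soil to the root surface,
#' `kr = ks(psi_s) * 2 pi Rl / ln(rc / rr) * 1e6 / (rho g)`, with the last
#' factor converting a head-based conductivity to a per-MPa conductance.
#' Vanishes as the soil dries.
#'
#' @param column A [soil_column()].
#' @param psis Soil water potential \[MPa\]; defaults to
#'   [root_weighted_psi()].
#' @return Conductance \[m s-1 MPa-1\].
#' @export
soil_root_conductance <- function(column, psis = root_weighted_psi(column)) {
  if (!(column$rc > column$rr)) stop("need rc > rr", call. = FALSE)
  theta <- retention_theta(psis, column$retention)
  ks <- unsat_conductivity(theta, column$retention, warn = FALSE)
  ks * 2 * pi * column$Rl / log(column$rc / column$rr) * 1e6 / (.const$rho_w * .const$g)
}

#' Advance the soil water balance by one step
#'
#' Explicit bucket update: rainfall infiltrates the top layer (excess above
#' saturation becomes surface runoff), root uptake is removed per layer,
#' and gravity drainage cascades downward at the unsaturated conductivity
#' (unit gradient; free drainage at the base). Water content is kept within
#' `[theta_r, theta_s]`; uptake demand that a layer cannot supply is
#' reported as a shortfall. The update closes the column water balance to
#' numerical precision.
#'
#' @param column A [soil_column()].
#' @param uptake Either a single total uptake flux \[m s-1\] distributed by
#'   root fractions, or a per-layer vector. Must be non-negative (no
#'   hydraulic redistribution).
#' @param precip Rainfall rate \[mm h-1\].
#' @param dt Time step \[s\].
#' @return The updated `soil_column`, with a `balance` attribute listing
#'   infiltration, runoff, actual uptake, drainage, shortfall and the mass
#'   balance residual (all in m of water).
#' @export
step_soil_water <- function(column, uptake = 0, precip = 0, dt = 3600) {
  stopifnot(dt > 0)
  ly <- column$layers
  ret <- column$retention
  nl <- nrow(ly)
  if (length(uptake) == 1) uptake <- uptake * ly$w
  if (length(uptake) != nl) stop("uptake must be scalar or per-layer", call. = FALSE)
  if (any(uptake < -1e-18)) {
    stop("negative uptake (root-to-soil flow) is not allowed", call. = FALSE)
  }

  store0 <- sum(ly$theta * ly$depth)
  infil <- precip / 1000 / 3600 * dt          # [m]
  runoff <- 0
  shortfall <- 0
  drain_out <- 0
  theta <- ly$theta

  # infiltration fills layers top-down; what the whole column cannot hold
  # leaves as surface runoff (an intense event can saturate the column)
  left <- infil
  for (i in seq_len(nl)) {
    room <- (ret$theta_s - theta[i]) * ly$depth[i]
    add <- min(left, room)
    theta[i] <- theta[i] + add / ly$depth[i]
    left <- left - add
    if (left <= 0) break
  }
  runoff <- left

  # root uptake, per layer, limited by available water
  take_req <- uptake * dt
  avail <- (theta - ret$theta_r) * ly$depth
  take <- pmin(take_req, pmax(avail, 0))
  shortfall <- sum(take_req - take)
  theta <- theta - take / ly$depth

  # gravity drainage cascade (unit gradient at k(theta))
  for (i in seq_len(nl)) {
    k <- unsat_conductivity(theta[i], ret, warn = FALSE)
    d <- min(k * dt, pmax((theta[i] - ret$theta_r) * ly$depth[i], 0))
    theta[i] <- theta[i] - d / ly$depth[i]
    if (i < nl) {
      room <- (ret$theta_s - theta[i + 1]) * ly$depth[i + 1]
      pass <- min(d, room)
      theta[i + 1] <- theta[i + 1] + pass / ly$depth[i + 1]
      # what the next layer cannot hold continues downward immediately
      d_excess <- d - pass
      if (d_excess > 0) drain_out <- drain_out + d_excess
    } else {
      drain_out <- drain_out + d
    }
  }

  column$layers$theta <- theta
  store1 <- sum(theta * ly$depth)
  residual <- store1 - store0 - (infil - runoff) + sum(take) + drain_out
  attr(column, "balance") <- list(
    infiltration = infil, runoff = runoff, uptake = sum(take),
    drainage = drain_out, shortfall = shortfall, residual = residual
  )
  column
}

#' Reset a soil column to saturation
#'
#' Used for the drought-relief experiments, where a rainfall event large
#' enough to saturate the whole column ends the dry-down.
#'
#' @param column A [soil_column()].
#' @return The column with all layers at `theta_s`.
#' @export
saturate_soil <- function(column) {
  column$layers$theta <- rep(column$retention$theta_s, nrow(column$layers))
  column
}
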