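#' Minimal carbon-pool state for dynamic vegetation
#'
#' Two pools (leaves and living sapwood) with fixed allocation fractions
#' and first-order turnover. Deliberately reduced relative to a full
#' terrestrial biosphere scheme: fine roots, reserves, fruits, heartwood
#' and phenology are out of scope, and allocation does not respond to
#' xylem damage (a known driver of overestimated drought legacies).
#'
#' @param cleaf,csap Leaf and sapwood carbon \[kg C m-2\].
#' @param sla Specific leaf area \[m2 (kg C)-1\].
#' @param alloc_leaf,alloc_sap Allocation fractions of NPP \[-\]; must sum
#'   to at most 1.
#' @param d_leaf,d_sap Turnover rates \[day-1\].
#' @param resp_frac Autotrophic respiration fraction of GPP \[-\].
#' @return An object of class `carbon_pools`.
#' @export
#' @examples
#' carbon_pools()
carbon_pools <- function(cleaf = 0.3, csap = 6, sla = 10,
                         alloc_leaf = 0.45, alloc_sap = 0.3,
                         d_leaf = 1 / 365, d_sap = 1 / 3650,
                         resp_frac = 0.5) {
  stopifnot(cleaf >= 0, csap >= 0, sla > 0,
            alloc_leaf >= 0, alloc_sap >= 0, alloc_leaf + alloc_sap <= 1,
            d_leaf >= 0, d_sap >= 0, resp_frac >= 0, resp_frac < 1)
  structure(
    list(cleaf = cleaf, csap = csap, sla = sla,
         alloc_leaf = alloc_leaf, alloc_sap = alloc_sap,
         d_leaf = d_leaf, d_sap = d_sap, resp_frac = resp_frac),
    class = "carbon_pools"
  )
}

#' Advance the carbon pools by one (daily) step
#'
#' `NPP = (1 - resp_frac) GPP`; each pool obeys
#' `dC/dt = alloc * NPP - d * C`. Also emits the fractional recruitment
#' (`lambda = alloc * NPP / C`) and turnover (`mu = d`) rates consumed by
#' the damage-cohort module. Carbon mass balance closes exactly.
#'
#' @param pools A [carbon_pools()] object.
#' @param gpp_daily Daily gross primary productivity \[kg C m-2 day-1\],
#'   >= 0.
#' @param dt Step \[days\].
#' @return A list with the updated `pools` and the rates `lambda_leaf`,
#'   `mu_leaf`, `lambda_sap`, `mu_sap` \[fraction day-1\].
#' @export
step_carbon <- function(pools, gpp_daily, dt = 1) {
  stopifnot(gpp_daily >= 0, dt > 0)
  npp <- (1 - pools$resp_frac) * gpp_daily
  gain_leaf <- pools$alloc_leaf * npp
  gain_sap <- pools$alloc_sap * npp
  loss_leaf <- pools$d_leaf * pools$cleaf
  loss_sap <- pools$d_sap * pools$csap
  lambda_leaf <- if (pools$cleaf > 0) gain_leaf / pools$cleaf else 0
  lambda_sap <- if (pools$csap > 0) gain_sap / pools$csap else 0
  pools$cleaf <- max(0, pools$cleaf + (gain_leaf - loss_leaf) * dt)
  pools$csap <- max(0, pools$csap + (gain_sap - loss_sap) * dt)
  list(pools = pools,
       lambda_leaf = lambda_leaf, mu_leaf = pools$d_leaf,
       lambda_sap = lambda_sap, mu_sap = pools$d_sap,
       npp = npp)
}

#' Leaf area index from leaf carbon
#'
#' `LAI = SLA * Cleaf`; the leaf storage capacity is recomputed downstream
#' from the new LAI.
#'
#' @param pools A [carbon_pools()] object.
#' @return Leaf area index \[m2 m-2\].
#' @export
lai_from_leaf_carbon <- function(pools) {
  stopifnot(pools$cleaf >= 0)
  pools$sla * pools$cleaf
}
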