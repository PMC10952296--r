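#' Plot daily fluxes of a simulation run
#'
#' Daily GPP, transpiration and root-zone water potential against time.
#'
#' @param object A `spac_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot spac_run
#' @export
autoplot.spac_run <- function(object, ...) {
  d <- tidy(object, "daily") |>
    tidyr::pivot_longer(c("GPP", "T_mm", "psis"), names_to = "series")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$value)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1,
                        labeller = ggplot2::as_labeller(c(
                          GPP = "GPP [umol CO2 m-2 s-1]",
                          T_mm = "Transpiration [mm d-1]",
                          psis = "Soil water potential [MPa]"))) +
    ggplot2::labs(x = "Day", y = NULL,
                  title = paste("Variant", object$meta$variant)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Compare daily series across the variants of an experiment
#'
#' @param x A `spac_experiment`.
#' @param var Daily column to draw (default `"GPP"`).
#' @return A ggplot object.
#' @export
plot_variants <- function(x, var = "GPP") {
  d <- tidy(x, "daily")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data[[var]],
                                  colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day", y = var, colour = "variant") +
    ggplot2::theme_minimal()
}

#' Normalized diurnal composites across variants
#'
#' Per-hour mean of an hourly column over a window of days, normalized to
#' its maximum; the late-afternoon depression of the hydraulic variants is
#' visible here.
#'
#' @param x A `spac_experiment`.
#' @param var Hourly column (default `"GPP"`).
#' @param days Day indices included in the composite.
#' @return A ggplot object.
#' @export
plot_diurnal <- function(x, var = "GPP", days = 1:5) {
  runs <- x[setdiff(names(x), "meta")]
  d <- purrr::map_dfr(names(runs), function(v) {
    h <- runs[[v]]$hourly[[var]]
    idx <- rep(days, each = 24) * 24 - 24 + rep(1:24, length(days))
    tibble::tibble(variant = v, hour = 0:23,
                   value = diurnal_composite(h[idx], normalize = TRUE))
  })
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hour, y = .data$value,
                                  colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Hour of day", y = paste("normalized", var)) +
    ggplot2::theme_minimal()
}

#' Plot vulnerability curves of a trait set
#'
#' @param traits A [plant_traits()] object.
#' @param psi_range Potential range \[MPa\].
#' @return A ggplot object.
#' @export
plot_vulnerability <- function(traits = plant_traits(), psi_range = c(-8, 0)) {
  psi <- seq(psi_range[1], psi_range[2], length.out = 200)
  d <- dplyr::bind_rows(
    tibble::tibble(psi = psi, tissue = "xylem",
                   k_rel = xylem_vuln(psi, traits) / traits$kxmax),
    tibble::tibble(psi = psi, tissue = "leaf",
                   k_rel = leaf_vuln(psi, traits) / traits$klmax)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$psi, y = .data$k_rel,
                                  colour = .data$tissue)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Water potential [MPa]", y = "relative conductance") +
    ggplot2::theme_minimal()
}
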