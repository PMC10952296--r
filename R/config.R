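#' Read a simulation configuration from YAML
#'
#' The configuration mirrors the package constructors section by section:
#' `traits` (arguments of [plant_traits()]), `soil` (layer depths, water
#' content, root fractions, root geometry, and a `retention` block with a
#' `model` tag of `"vg"` or `"ch"` plus its parameters), `gasx`
#' ([gas_params()] arguments), `stomata` (`model` tag), `veg`
#' ([carbon_pools()] arguments), `forcing` (an optional `column_map`), and
#' `experiment` (variant, scenario, n_days, seed). Omitted sections fall
#' back to package defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with `traits`, `soil`, `params`, `stomata`, `pools`,
#'   `column_map` and `experiment`.
#' @export
read_spac_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)

  traits <- do.call(plant_traits, cfg$traits %||% list())

  soil <- if (is.null(cfg$soil)) {
    default_soil()
  } else {
    s <- cfg$soil
    ret_cfg <- s$retention %||% list(model = "vg")
    # YAML 1.1 parses a bare key `n` as the boolean FALSE; map it back
    names(ret_cfg)[names(ret_cfg) %in% c("FALSE", "n")] <- "n"
    ret <- switch(ret_cfg$model %||% "vg",
      vg = do.call(vg_retention, ret_cfg[setdiff(names(ret_cfg), "model")]),
      ch = do.call(ch_retention, ret_cfg[setdiff(names(ret_cfg), "model")]),
      stop("unknown retention model: ", ret_cfg$model, call. = FALSE)
    )
    soil_column(
      depths = unlist(s$depths %||% c(0.3, 0.3, 0.4)),
      theta = unlist(s$theta %||% ret$theta_s),
      root_frac = unlist(s$root_frac %||% rep(1 / length(s$depths %||% 1:3),
                                              length(s$depths %||% 1:3))),
      retention = ret,
      Rl = s$Rl %||% 6000, rc = s$rc %||% 0.05, rr = s$rr %||% 5e-4
    )
  }

  params <- do.call(gas_params, cfg$gasx %||% list())
  stomata <- (cfg$stomata %||% list())$model
  pools <- do.call(carbon_pools, cfg$veg %||% list())
  list(
    traits = traits, soil = soil, params = params, stomata = stomata,
    pools = pools,
    column_map = (cfg$forcing %||% list())$column_map,
    experiment = cfg$experiment %||% list()
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the hourly and daily series of a run to CSV
#'
#' @param run A `spac_run`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return The output paths, invisibly.
#' @export
write_run_csv <- function(run, dir, prefix = run$meta$variant) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ph <- file.path(dir, paste0(prefix, "_hourly.csv"))
  pd <- file.path(dir, paste0(prefix, "_daily.csv"))
  readr::write_csv(run$hourly, ph)
  readr::write_csv(run$daily, pd)
  invisible(c(hourly = ph, daily = pd))
}
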