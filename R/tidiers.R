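#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation run
#'
#' Returns the hourly (default) or daily series of a [run_spac()] result as
#' a tibble with a `variant` column, ready for binding across runs.
#'
#' @param x A `spac_run`.
#' @param level `"hourly"` or `"daily"`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy spac_run
#' @export
tidy.spac_run <- function(x, level = c("hourly", "daily"), ...) {
  level <- match.arg(level)
  out <- if (level == "hourly") x$hourly else x$daily
  dplyr::mutate(out, variant = x$meta$variant, .before = 1)
}

#' One-row summary of a simulation run
#'
#' Totals and diagnostics: mean GPP, total transpiration, pre-drought
#' water-use efficiency (first five days), the 90%-to-50% GPP decline time,
#' the minimum leaf water potential, and solver fallback counts.
#'
#' @param x A `spac_run`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method glance spac_run
#' @export
glance.spac_run <- function(x, ...) {
  d <- x$daily
  decline <- suppressWarnings(metric_decline_time(d$GPP))
  wue_pre <- suppressWarnings(
    metric_wue(d$GPP, d$T_mm, window = seq_len(min(5, nrow(d)))))
  tibble::tibble(
    variant = x$meta$variant,
    stomata = x$meta$stomata,
    n_days = nrow(d),
    gpp_mean = mean(d$GPP),
    transp_total_mm = sum(d$T_mm),
    wue_predrought = wue_pre,
    decline_time_d = decline,
    psil_min = suppressWarnings(min(x$hourly$psil, na.rm = TRUE)),
    fallback_count = x$meta$fallback_count
  )
}

#' Tidy all runs of an experiment
#'
#' @param x A `spac_experiment` from [run_e1()] or [run_e2()].
#' @inheritParams tidy.spac_run
#' @return A tibble with one block per variant.
#' @method tidy spac_experiment
#' @export
tidy.spac_experiment <- function(x, level = c("hourly", "daily"), ...) {
  level <- match.arg(level)
  runs <- x[setdiff(names(x), "meta")]
  purrr::map_dfr(runs, tidy, level = level)
}

#' @method glance spac_experiment
#' @export
glance.spac_experiment <- function(x, ...) {
  runs <- x[setdiff(names(x), "meta")]
  purrr::map_dfr(runs, glance)
}
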