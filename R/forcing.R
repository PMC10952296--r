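#' Saturation vapour pressure (Tetens)
#'
#' Saturation vapour pressure over liquid water at air temperature `ta`,
#' using the Tetens formula (610.8 Pa base). All model variants share this
#' formulation, so its exact form does not affect inter-variant comparisons.
#'
#' @param ta Air temperature \[degC\]. Must lie in \[-50, 60\].
#' @return Saturation vapour pressure \[Pa\], strictly increasing in `ta`.
#' @export
#' @examples
#' esat(0)   # ~611 Pa
#' esat(25)  # ~3167 Pa
esat <- function(ta) {
  if (any(!is.finite(ta)) || any(ta < -50) || any(ta > 60)) {
    stop("`ta` must be finite and within [-50, 60] degC", call. = FALSE)
  }
  610.8 * exp(17.27 * ta / (ta + 237.3))
}

#' Vapour pressure deficit from temperature and relative humidity
#'
#' D = (1 - RH) * esat(Ta).
#'
#' @param ta Air temperature \[degC\].
#' @param rh Relative humidity as a fraction in \[0, 1\].
#' @return Vapour pressure deficit \[Pa\], zero at saturation.
#' @export
#' @examples
#' vpd_from_rh(25, 0.5)
vpd_from_rh <- function(ta, rh) {
  if (any(!is.finite(rh)) || any(rh < 0) || any(rh > 1)) {
    stop("`rh` must be a fraction in [0, 1]", call. = FALSE)
  }
  (1 - rh) * esat(ta)
}

#' Photosynthetically active radiation from shortwave radiation
#'
#' PAR is taken as 45% of the shortwave energy flux, converted to photon
#' flux at 4.57 umol J-1.
#'
#' @param swdown Downwelling shortwave radiation \[W m-2\].
#' @return PAR \[umol photons m-2 s-1\].
#' @export
par_from_sw <- function(swdown) {
  0.45 * 4.57 * pmax(swdown, 0)
}

.forcing_cols <- c("time", "Ta", "RH", "SWdown", "Patm", "wind", "precip", "ca", "D")

#' Assemble and validate an hourly forcing table
#'
#' Builds a validated tibble of hourly meteorological drivers. Vapour
#' pressure deficit `D` is derived from `Ta` and `RH` when not supplied.
#'
#' @param time POSIXct timestamps (hour-beginning) or an integer hour index.
#' @param Ta Air temperature \[degC\].
#' @param RH Relative humidity \[0-1\].
#' @param SWdown Downwelling shortwave radiation \[W m-2\].
#' @param Patm Atmospheric pressure \[Pa\].
#' @param wind Wind speed \[m s-1\].
#' @param precip Precipitation \[mm h-1\].
#' @param ca Atmospheric CO2 \[umol mol-1\].
#' @param D Optional vapour pressure deficit \[Pa\]; derived if `NULL`.
#' @return A tibble with one row per hour.
#' @export
forcing_record <- function(time, Ta, RH, SWdown, Patm = 101325, wind = 2,
                           precip = 0, ca = 400, D = NULL) {
  x <- tibble::tibble(
    time = time, Ta = Ta, RH = RH, SWdown = SWdown,
    Patm = Patm, wind = wind, precip = precip, ca = ca,
    D = if (is.null(D)) vpd_from_rh(Ta, RH) else D
  )
  validate_forcing(x)
}

#' Validate a forcing table
#'
#' Checks column presence, physical ranges, timestamp monotonicity and
#' hourly regularity; derives `D` from `Ta`/`RH` where missing.
#'
#' @param x A data frame of hourly forcing.
#' @return The validated forcing tibble (invisibly identical content).
#' @export
validate_forcing <- function(x) {
  x <- tibble::as_tibble(x)
  need <- setdiff(.forcing_cols, c("D", names(x)))
  if (length(need)) {
    stop("forcing is missing required columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!"D" %in% names(x)) x$D <- vpd_from_rh(x$Ta, x$RH)
  miss <- is.na(x$D)
  if (any(miss)) x$D[miss] <- vpd_from_rh(x$Ta[miss], x$RH[miss])
  if (anyDuplicated(x$time)) stop("duplicated timestamps in forcing", call. = FALSE)
  if (is.unsorted(as.numeric(x$time), strictly = TRUE)) {
    stop("timestamps must be strictly increasing", call. = FALSE)
  }
  if (inherits(x$time, "POSIXct") && nrow(x) > 1) {
    dt <- diff(as.numeric(x$time))
    if (any(dt != 3600)) stop("forcing must be hourly-regular", call. = FALSE)
  }
  if (any(x$RH < 0 | x$RH > 1)) stop("RH outside [0, 1]", call. = FALSE)
  if (any(x$SWdown < -1e-9)) stop("negative SWdown", call. = FALSE)
  if (any(x$precip < 0)) stop("negative precipitation", call. = FALSE)
  if (any(x$D < -1e-9)) stop("negative vapour pressure deficit", call. = FALSE)
  if (any(x$Ta < -50 | x$Ta > 60)) stop("Ta outside [-50, 60] degC", call. = FALSE)
  x$SWdown <- pmax(x$SWdown, 0)
  x$D <- pmax(x$D, 0)
  x
}

#' Generate a synthetic multi-year hourly forcing archive
#'
#' Produces an hourly archive with a seasonal temperature cycle, AR(1)
#' day-to-day anomalies, a diurnal cycle in temperature and humidity,
#' clear-sky shortwave radiation modulated by daily cloudiness, and
#' intermittent rainfall. The archive is the input to
#' [make_percentile_day()]; it emulates the statistics a flux-tower record
#' would supply (per-hour distributions over the growing season), not any
#' specific site.
#'
#' @param years Number of calendar years (365-day years).
#' @param seed Integer seed; the archive is reproducible given a seed.
#' @param t_mean Annual mean temperature \[degC\].
#' @param t_seas Amplitude of the seasonal temperature cycle \[degC\].
#' @param t_diur Amplitude of the diurnal temperature cycle \[degC\].
#' @param rh_base,rh_diur Mean relative humidity and diurnal amplitude.
#' @param sw_peak Midsummer clear-sky noon shortwave \[W m-2\].
#' @param wet_prob Probability that a day has rainfall.
#' @param ca Atmospheric CO2 \[umol mol-1\].
#' @return An hourly forcing tibble of length `years * 365 * 24`.
#' @export
synthetic_forcing_archive <- function(years = 3, seed = 1,
                                      t_mean = 12, t_seas = 10, t_diur = 6,
                                      rh_base = 0.62, rh_diur = 0.18,
                                      sw_peak = 900, wet_prob = 0.25,
                                      ca = 410) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n_days <- years * 365L
  doy <- rep(1:365, years)
  seas <- -cos(2 * pi * (doy - 15) / 365)       # -1 mid-Jan, +1 mid-Jul
  t_anom <- as.numeric(stats::arima.sim(list(ar = 0.7), n_days, sd = 2))
  rh_anom <- as.numeric(stats::arima.sim(list(ar = 0.5), n_days, sd = 0.10))
  cloud <- runif(n_days, 0.45, 1)^1.3
  wet <- runif(n_days) < wet_prob
  rain_amt <- ifelse(wet, stats::rgamma(n_days, shape = 1.2, scale = 7), 0)

  hour <- rep(0:23, n_days)
  day_i <- rep(seq_len(n_days), each = 24)
  t_day <- t_mean + t_seas * seas + t_anom
  ta <- t_day[day_i] + t_diur * cos(2 * pi * (hour - 14.5) / 24) * 0.5 +
    t_diur * 0.5 * pmax(cos(2 * pi * (hour - 14.5) / 24), -0.4)
  rh <- pmin(1, pmax(0.05,
    rh_base - rh_diur * cos(2 * pi * (hour - 15) / 24) + rh_anom[day_i] +
      0.15 * wet[day_i]))
  sun <- pmax(0, sin(pi * (hour - 6) / 12))
  sw <- (sw_peak * (0.65 + 0.35 * seas[day_i])) * sun * cloud[day_i]
  # rainfall spread over a few afternoon hours of wet days
  precip <- numeric(length(hour))
  wet_rows <- which(wet[day_i] & hour %in% 14:17)
  precip[wet_rows] <- rain_amt[day_i[wet_rows]] / 4
  wind <- 1.2 + stats::rweibull(length(hour), shape = 1.8, scale = 1.5)

  time <- as.POSIXct("2001-01-01 00:00:00", tz = "UTC") + 3600 * (seq_along(hour) - 1)
  forcing_record(time = time, Ta = round(ta, 3), RH = round(rh, 4),
                 SWdown = round(sw, 2), wind = round(wind, 3),
                 precip = round(precip, 3), ca = ca)
}

#' Compose a percentile "warm and sunny" day from an hourly archive
#'
#' For each hour of day, temperature and shortwave radiation are set to the
#' 75th percentile of the archive values over the selected months, relative
#' humidity to the requested percentile (low percentiles give high
#' atmospheric demand), and all other drivers to the per-hour median.
#' Vapour pressure deficit is recomputed from the composed temperature and
#' humidity. The selection of the most active months is an explicit
#' argument.
#'
#' @param archive Hourly forcing tibble covering the requested months.
#' @param months Integer calendar months (e.g. `6:8`).
#' @param rh_percentile Percentile for relative humidity, e.g. `0.10`
#'   (high VPD) or `0.90` (low VPD).
#' @return A 24-row forcing tibble (hours 0-23 of a nominal day).
#' @export
make_percentile_day <- function(archive, months = 6:8, rh_percentile = 0.10) {
  archive <- validate_forcing(archive)
  if (length(months) == 0) stop("`months` must be non-empty", call. = FALSE)
  if (!rh_percentile >= 0 || !rh_percentile <= 1) {
    stop("`rh_percentile` must lie in [0, 1]", call. = FALSE)
  }
  mon <- as.integer(format(archive$time, "%m"))
  sel <- archive[mon %in% months, ]
  if (nrow(sel) < 24) stop("archive does not cover the requested months", call. = FALSE)
  hr <- as.integer(format(sel$time, "%H"))

  day <- sel |>
    dplyr::mutate(hour = hr) |>
    dplyr::group_by(.data$hour) |>
    dplyr::summarise(
      Ta = quantile(.data$Ta, 0.75, names = FALSE),
      SWdown = quantile(.data$SWdown, 0.75, names = FALSE),
      RH = quantile(.data$RH, rh_percentile, names = FALSE),
      Patm = median(.data$Patm),
      wind = median(.data$wind),
      precip = median(.data$precip),
      ca = median(.data$ca),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$hour)
  forcing_record(
    time = as.POSIXct("2001-06-01 00:00:00", tz = "UTC") + 3600 * day$hour,
    Ta = day$Ta, RH = day$RH, SWdown = day$SWdown, Patm = day$Patm,
    wind = day$wind, precip = day$precip, ca = day$ca
  )
}

#' Repeat a single day of forcing into a precipitation-free series
#'
#' Tiles a 24-hour forcing day `n_days` times with a continuous hourly
#' time axis, setting precipitation to zero throughout (a dry-down).
#'
#' @param day A 24-row forcing tibble.
#' @param n_days Number of repetitions (>= 1).
#' @return An hourly forcing tibble of length `24 * n_days`.
#' @export
repeat_forcing <- function(day, n_days) {
  day <- validate_forcing(day)
  if (nrow(day) != 24) stop("`day` must have exactly 24 hourly rows", call. = FALSE)
  if (n_days < 1) stop("`n_days` must be >= 1", call. = FALSE)
  out <- day[rep(seq_len(24), n_days), ]
  out$time <- day$time[1] + 3600 * (seq_len(24 * n_days) - 1)
  out$precip <- 0
  out
}

#' Read hourly forcing from CSV
#'
#' Reads a one-row-per-hour CSV, optionally renaming columns via
#' `column_map` (a named character vector `c(internal = "file_column")`).
#' If the file carries `RH` but no `D`, the deficit is derived with
#' [vpd_from_rh()]. The result is validated (hourly regularity, ranges,
#' duplicate/non-monotone timestamps are errors).
#'
#' @param path Path to a CSV file.
#' @param column_map Optional named character vector mapping internal names
#'   to file column names.
#' @param tz Timezone for parsing the `time` column.
#' @return A validated forcing tibble.
#' @export
read_forcing_csv <- function(path, column_map = NULL, tz = "UTC") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(column_map)) {
    for (internal in names(column_map)) {
      fc <- column_map[[internal]]
      if (!fc %in% names(x)) stop("mapped column not in file: ", fc, call. = FALSE)
      names(x)[names(x) == fc] <- internal
    }
  }
  if (!"time" %in% names(x)) stop("forcing file needs a `time` column", call. = FALSE)
  if (!inherits(x$time, "POSIXct")) {
    x$time <- as.POSIXct(x$time, tz = tz)
  }
  if (!"RH" %in% names(x) && "D" %in% names(x)) {
    x$RH <- pmin(1, pmax(0, 1 - x$D / esat(x$Ta)))
  }
  if (!"RH" %in% names(x)) stop("forcing file needs `RH` or `D`", call. = FALSE)
  for (nm in c("Patm", "wind", "precip", "ca")) {
    if (!nm %in% names(x)) {
      x[[nm]] <- c(Patm = 101325, wind = 2, precip = 0, ca = 400)[[nm]]
    }
  }
  validate_forcing(x[, intersect(.forcing_cols, names(x))])
}

#' Write hourly forcing to CSV
#'
#' @param x A forcing tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_forcing_csv <- function(x, path) {
  readr::write_csv(validate_forcing(x), path)
  invisible(path)
}
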