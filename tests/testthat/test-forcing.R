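test_that("saturation vapour pressure follows Tetens and is monotone", {
  expect_equal(esat(0), 610.8, tolerance = 1e-6)
  # frozen from direct Tetens evaluation: 610.8 * exp(17.27*25/262.3)
  expect_equal(esat(25), 3167.778, tolerance = 1e-4)
  expect_gt(esat(30), esat(20))
  expect_error(esat(-80), "within")
})

test_that("vapour pressure deficit derives from temperature and humidity", {
  expect_equal(vpd_from_rh(13, 1), 0)
  expect_equal(vpd_from_rh(25, 0.5), 0.5 * esat(25))
  expect_equal(vpd_from_rh(25, 0), esat(25))
  expect_error(vpd_from_rh(25, 1.2), "fraction")
})

test_that("percentile day matches a sorted-array oracle on a synthetic archive", {
  archive <- synthetic_forcing_archive(years = 3, seed = 42)
  day <- make_percentile_day(archive, months = 6:8, rh_percentile = 0.10)
  expect_equal(nrow(day), 24)

  mon <- as.integer(format(archive$time, "%m"))
  sel <- archive[mon %in% 6:8, ]
  hr <- as.integer(format(sel$time, "%H"))
  # independent per-hour percentile: sort and linearly interpolate (type-7)
  pct <- function(x, p) {
    x <- sort(x)
    h <- (length(x) - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
  }
  for (h in c(0, 6, 12, 18)) {
    v <- sel$Ta[hr == h]
    expect_equal(day$Ta[h + 1], pct(v, 0.75), tolerance = 1e-12)
    expect_equal(day$RH[h + 1], pct(sel$RH[hr == h], 0.10), tolerance = 1e-12)
    expect_equal(day$SWdown[h + 1], pct(sel$SWdown[hr == h], 0.75),
                 tolerance = 1e-12)
  }
  # D is recomputed from the composed Ta and RH (idempotent derivation)
  expect_equal(day$D, vpd_from_rh(day$Ta, day$RH))
})

test_that("percentile day is order-free and monotone in the RH percentile", {
  archive <- synthetic_forcing_archive(years = 2, seed = 7)
  day_a <- make_percentile_day(archive, 6:8, 0.10)
  # permute whole days within each calendar month, keeping the time axis,
  # so the same observations enter the percentile in a different order
  nd <- nrow(archive) / 24
  day_month <- as.integer(format(archive$time[(0:(nd - 1)) * 24 + 1], "%m"))
  set.seed(99)
  new_day <- integer(nd)
  for (m in unique(day_month)) {
    idx <- which(day_month == m)
    new_day[idx] <- if (length(idx) > 1) sample(idx) else idx
  }
  perm <- rep((new_day - 1) * 24, each = 24) + rep(1:24, nd)
  shuffled <- archive[perm, ]
  shuffled$time <- archive$time
  day_b <- make_percentile_day(shuffled, 6:8, 0.10)
  expect_equal(day_b$Ta, day_a$Ta)
  expect_equal(day_b$RH, day_a$RH)

  day_dry <- make_percentile_day(archive, 6:8, 0.10)
  day_wet <- make_percentile_day(archive, 6:8, 0.90)
  expect_true(all(day_dry$D >= day_wet$D))

  # archive of identical days returns that day unchanged
  one <- archive[1:24, ]
  rep3 <- archive[rep(1:24, 90), ]
  rep3$time <- archive$time[1] + 3600 * (seq_len(24 * 90) - 1)
  mon <- unique(as.integer(format(rep3$time, "%m")))
  same <- make_percentile_day(rep3, mon, 0.5)
  expect_equal(same$Ta, one$Ta)
  expect_equal(same$SWdown, one$SWdown)
})

test_that("repeat_forcing tiles a day without rainfall", {
  day <- test_day()
  expect_equal(nrow(repeat_forcing(day, 1)), 24)
  long <- repeat_forcing(day, 250)
  expect_equal(nrow(long), 6000)
  expect_true(all(long$precip == 0))
  # periodicity: every variable repeats with period 24
  expect_equal(long$Ta[5 + 0:9 * 24], rep(day$Ta[5], 10))
  expect_equal(diff(as.numeric(long$time)), rep(3600, 5999))
  expect_error(repeat_forcing(day, 0), ">= 1")
})

test_that("forcing CSV round-trips and validates", {
  day <- test_day()
  path <- withr::local_tempfile(fileext = ".csv")
  write_forcing_csv(day, path)
  back <- read_forcing_csv(path)
  expect_equal(back$Ta, day$Ta)
  expect_equal(back$D, day$D)

  # a file with RH but no D gets D derived
  stripped <- day[, setdiff(names(day), "D")]
  readr::write_csv(stripped, path)
  back2 <- read_forcing_csv(path)
  expect_equal(back2$D, vpd_from_rh(day$Ta, day$RH))

  # duplicated timestamps are rejected
  dup <- day
  dup$time[2] <- dup$time[1]
  expect_error(validate_forcing(dup))

  # column mapping
  renamed <- day
  names(renamed)[names(renamed) == "Ta"] <- "air_temp"
  readr::write_csv(renamed, path)
  back3 <- read_forcing_csv(path, column_map = c(Ta = "air_temp"))
  expect_equal(back3$Ta, day$Ta)
})
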