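test_that("potential assimilation has the right limits and magnitude", {
  p <- gas_params()
  # dark: pure dark respiration
  expect_equal(farquhar_anpot(280, ta = 25, par = 0, p),
               -dark_respiration(25, p), tolerance = 1e-12)
  # compensation point at saturating light: An = -Rd
  expect_equal(farquhar_anpot(gamma_star(25), ta = 25, par = 1500, p),
               -dark_respiration(25, p), tolerance = 1e-12)

  # direct single-equation oracle at 25 degC (no temperature scaling):
  # Ac = Vcmax (ci - G*) / (ci + Kc (1 + O/Ko)) with the 25 degC constants
  ci <- 280
  gs_ <- 42.75
  ac <- 60 * (ci - gs_) / (ci + 404.9 * (1 + 210 / 278.4))
  q2 <- 0.3 * 1500
  j <- (q2 + 110 - sqrt((q2 + 110)^2 - 4 * 0.7 * q2 * 110)) / (2 * 0.7)
  aj <- j / 4 * (ci - gs_) / (ci + 2 * gs_)
  an_expected <- min(ac, aj) - 0.9
  expect_equal(farquhar_anpot(ci, 25, 1500, p), an_expected, tolerance = 1e-10)
})

test_that("stress factors have the stated shapes", {
  expect_equal(fs_factor(0), 1)
  expect_equal(fs_factor(-1, p = 1, q = 1), exp(-1))
  expect_lt(fs_factor(-2), fs_factor(-1))

  expect_equal(fl_factor(-0.3, -0.3), 1)
  expect_equal(fl_factor(0, -1), 0.5, tolerance = 1e-12)
  expect_equal(fl_factor(0, -0.2), 0.9, tolerance = 1e-12)
  expect_equal(fl_star(0), 1)
  expect_lt(fl_star(-2), fl_star(-1))
})

test_that("fl calibration solves the two-anchor system in closed form", {
  cal <- calibrate_fl(c(1.0, 0.5), c(0.2, 0.1))
  expect_equal(cal$al, log(2), tolerance = 1e-12)
  expect_equal(cal$gamma_l, log(log(0.9) / log(0.5)) / log(0.2),
               tolerance = 1e-12)
  # round trip: evaluating fl at either anchor returns the anchor reduction
  expect_equal(1 - fl_factor(0, -1.0, cal$al, cal$gamma_l), 0.5,
               tolerance = 1e-12)
  expect_equal(1 - fl_factor(0, -0.2, cal$al, cal$gamma_l), 0.1,
               tolerance = 1e-12)
  # anchor order does not matter
  swapped <- calibrate_fl(c(0.2, 0.1), c(1.0, 0.5))
  expect_equal(swapped$al, cal$al, tolerance = 1e-14)
  expect_equal(swapped$gamma_l, cal$gamma_l, tolerance = 1e-14)
  # inconsistent anchors are refused
  expect_error(calibrate_fl(c(1.0, 0.1), c(0.2, 0.5)), "inconsistent")
})

test_that("Leuning conductance algebra", {
  p <- gas_params(g0 = 0.01, a1 = 5, d0 = 1500)
  expect_equal(gs_leuning(0, 1, 300, 42, 1000, p), p$g0)
  g_d0 <- gs_leuning(10, 1, 300, 42, d = 1500, p) - p$g0
  g_0 <- gs_leuning(10, 1, 300, 42, d = 0, p) - p$g0
  expect_equal(g_d0, g_0 / 2, tolerance = 1e-12)
  g_half <- gs_leuning(10, 0.5, 300, 42, 1000, p) - p$g0
  g_full <- gs_leuning(10, 1.0, 300, 42, 1000, p) - p$g0
  expect_equal(g_half, g_full / 2, tolerance = 1e-12)
  # ci below the compensation point: supply term off
  expect_equal(gs_leuning(10, 1, 30, 42, 1000, p), p$g0)
  # negative assimilation floors at g0
  expect_equal(gs_leuning(-2, 1, 300, 42, 1000, p), p$g0)
})

test_that("Tuzet conductance modes", {
  p <- gas_params()
  # fl = 1, fs = 1 at D = 0 matches Leuning structurally
  expect_equal(gs_tuzet(10, 1, 1, 300, 42, p, "full"),
               gs_leuning(10, 1, 300, 42, d = 0, p), tolerance = 1e-12)
  expect_equal(gs_tuzet(10, 1, 0, 300, 42, p, "full"), p$g0)
  # a 1.0 MPa drop halves the non-residual term (anchor via fl_factor)
  fl1 <- fl_factor(0, -1, p$al, p$gamma_l)
  g_full <- gs_tuzet(10, 1, 1, 300, 42, p, "full") - p$g0
  g_drop <- gs_tuzet(10, 1, fl1, 300, 42, p, "full") - p$g0
  expect_equal(g_drop, g_full / 2, tolerance = 1e-12)
  # decoupled modes use their own parameters
  expect_equal(gs_tuzet(10, 0.3, 1, 300, 42, p, "no_fs"),
               p$g0 + p$a1_star * 10 / (300 - 42), tolerance = 1e-12)
  expect_equal(gs_tuzet(10, 0.3, 0.7, 300, 42, p, "light_only"),
               p$g0 + p$a1_light * 10 * 0.7, tolerance = 1e-12)
  expect_error(gs_tuzet(10, 1, 1, 300, 42, p, "bogus"))
})

test_that("ci solution matches a brute-force grid search", {
  p <- gas_params()
  sol <- solve_ci(ta = 25, par = 1200, ca = 400, d = 1200, fs = 0.8,
                  fl = 0.7, params = p, model = "tuzet")
  # brute force on a 1e-4-resolution ci grid
  ci_grid <- seq(gamma_star(25) + 1e-4, 400, by = 1e-4)
  anpot <- farquhar_anpot(ci_grid, 25, 1200, p)
  gs <- gs_tuzet(anpot, 0.8, 0.7, ci_grid, gamma_star(25), p, "full")
  resid <- abs(0.8 * anpot - gs * (400 - ci_grid))
  ci_star <- ci_grid[which.min(resid)]
  expect_equal(sol$ci, ci_star, tolerance = 2e-4)
  expect_lt(abs(sol$an - sol$gs * (400 - sol$ci)), 1e-8)
})

test_that("ci solution limits: open stomata and near-closed stomata", {
  p <- gas_params(a1 = 5000)  # effectively unbounded conductance
  sol <- solve_ci(25, 1500, 400, 500, params = p, model = "tuzet")
  expect_gt(sol$ci, 390)  # ci -> ca without diffusion limitation
  p2 <- gas_params(g0 = 1e-4, a1 = 5)
  sol2 <- solve_ci(25, 1500, 400, 500, fs = 1, fl = 1e-9, params = p2,
                   model = "tuzet")
  expect_lt(sol2$ci, gamma_star(25) + 30)  # supply-limited: ci near Gamma*
  # night with g0 = 0: stomata shut, no diffusion constraint
  p3 <- gas_params(g0 = 0)
  sol3 <- solve_ci(25, 0, 400, 500, params = p3, model = "tuzet")
  expect_equal(sol3$gs, 0)
  expect_equal(sol3$an, -dark_respiration(25, p3), tolerance = 1e-10)
})

test_that("transpiration flux unit conversion and scaling", {
  expect_equal(transp_flux(0.2, 1000, 101325, 1),
               1.6 * 0.2 * (1000 / 101325) * 0.018 / 1000, tolerance = 1e-15)
  expect_equal(transp_flux(0.2, 1000, 101325, 1), 5.7e-8, tolerance = 1e-2)
  expect_equal(transp_flux(0.1, 0, 101325, 3), 0)
  expect_equal(transp_flux(0.1, 800, 101325, 4),
               2 * transp_flux(0.1, 800, 101325, 2), tolerance = 1e-15)
})

test_that("conductance is monotone in VPD and in the potential drop", {
  p <- gas_params()
  d <- seq(0, 4000, by = 500)
  gs_d <- gs_leuning(12, 1, 300, 42, d, p)
  expect_true(all(diff(gs_d) < 0))
  drops <- seq(0, 4, by = 0.5)
  gs_t <- gs_tuzet(12, 1, fl_factor(0, -drops, p$al, p$gamma_l), 300, 42, p)
  expect_true(all(diff(gs_t) < 0))
})
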