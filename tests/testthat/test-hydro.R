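test_that("vulnerability curves and conductance scaling", {
  tr <- plant_traits(kxmax = 2e-7, qx = log(2) / 4, px = 2,
                     klmax = 5e-7, ql = log(2) / 4, pl = 2)
  expect_equal(xylem_vuln(0, tr), tr$kxmax)
  # qx = ln2 / 4 with px = 2 puts the 50% loss point at -2 MPa
  expect_equal(xylem_vuln(-2, tr), 0.5 * tr$kxmax, tolerance = 1e-12)
  expect_equal(leaf_vuln(-2, tr), 0.5 * tr$klmax, tolerance = 1e-12)
  expect_lt(xylem_vuln(-3, tr), xylem_vuln(-1, tr))

  expect_equal(conductance_scaling(1, h = 20, ax = 2e-3), 1e-7)
  expect_equal(conductance_scaling(1, h = 40, ax = 2e-3),
               conductance_scaling(1, 20, 2e-3) / 2)
  expect_equal(conductance_scaling(1, h = 20, ax = 4e-3),
               2 * conductance_scaling(1, 20, 2e-3))
})

test_that("storage capacities and the linear pressure-volume curve", {
  tr <- plant_traits(h = 25, ax = 3e-3, nx = 0.4, lai = 3, lma = 0.12,
                     ldmc = 0.35)
  caps <- storage_capacities(tr)
  expect_equal(caps$vxmax, 0.03)
  expect_equal(caps$vlmax, 3 * 0.12 * (0.65 / 0.35) / 1000, tolerance = 1e-12)
  expect_equal(storage_capacities(tr, lai = 0)$vlmax, 0)

  expect_equal(pv_psi(0.03, 0.03, -10), 0)
  expect_equal(pv_psi(0.015, 0.03, -10), -5)
  v <- seq(0, 0.03, length.out = 7)
  expect_equal(pv_volume(pv_psi(v, 0.03, -8), 0.03, -8), v, tolerance = 1e-14)
  expect_error(pv_psi(0.01, 0, -10), "positive")
})

test_that("steady solve: dark equilibrium and flux conservation", {
  tr <- plant_traits()
  soil <- default_soil()
  params <- gas_params(g0 = 0)
  frow <- test_frow(hour = 2)  # night
  psis <- -0.4
  kr <- soil_root_conductance(soil, psis)
  st <- solve_steady(psis, frow, tr, params, kr)
  expect_equal(st$psix, psis)
  expect_equal(st$psil, psis)
  expect_equal(st$T, 0)

  # daytime: converged solution satisfies Jsx = Jxl = T to < 1%
  params <- gas_params()
  frow <- test_frow(hour = 13)
  st <- solve_steady(psis, frow, tr, params, kr)
  expect_true(st$converged)
  expect_lt(abs(st$Jsx - st$T), 0.01 * st$T)
  expect_lt(abs(st$Jxl - st$T), 0.01 * st$T)
  expect_true(st$psil <= st$psix && st$psix <= psis)
})

test_that("steady solve agrees with the brute-force grid oracle", {
  tr <- plant_traits()
  soil <- default_soil()
  params <- gas_params()
  frow <- test_frow(hour = 13)
  for (psis in c(-0.1, -0.7)) {
    kr <- soil_root_conductance(soil, psis)
    dem <- demand_function(psis, frow, tr, params, "tuzet")
    st <- solve_steady(psis, frow, tr, params, kr, demand = dem)
    resfun <- function(psix, psil) {
      tt <- dem$Tfun(pmin(psil, psix))
      kx <- xylem_vuln(psix, tr)
      list(r1 = sqrt(kr * kx) * (psis - psix) - tt,
           r2 = sqrt(kx * leaf_vuln(psil, tr)) * (psix - psil) - tt)
    }
    go <- grid_oracle(resfun, psis, tfun = dem$Tfun)
    expect_lt(abs(dem$Tfun(go$x[2]) - st$T), 0.01 * st$T)
    expect_lt(abs(go$x[2] - st$psil), 5e-3)
  }
})

test_that("drought response of the steady solve is monotone in psis", {
  tr <- plant_traits()
  soil <- default_soil()
  params <- gas_params()
  frow <- test_frow(hour = 13)
  psis_grid <- seq(-0.05, -1.2, by = -0.05)
  tt <- vapply(psis_grid, function(ps) {
    solve_steady(ps, frow, tr, params,
                 soil_root_conductance(soil, ps))$T
  }, numeric(1))
  expect_true(all(diff(tt) < 1e-12))
})

test_that("capacitance RHS: equilibrium, night relaxation and telescoping", {
  tr <- plant_traits()
  caps <- storage_capacities(tr)
  params <- gas_params(g0 = 0)
  psis <- -0.5
  frow <- test_frow(hour = 2)
  dem <- demand_function(psis, frow, tr, params, "tuzet")
  kr <- 1e-6

  # equilibrium: storages matching psis give zero derivatives
  vx_eq <- pv_volume(psis, caps$vxmax, tr$cx)
  vl_eq <- pv_volume(psis, caps$vlmax, tr$cl)
  r <- rhs_capacitance(vx_eq, vl_eq, psis, dem, tr, kr)
  expect_equal(r$dvx, 0, tolerance = 1e-20)
  expect_equal(r$dvl, 0, tolerance = 1e-20)

  # telescoping: dVx + dVl = Jsx - T at any state
  r2 <- rhs_capacitance(0.8 * caps$vxmax, 0.5 * caps$vlmax, psis, dem, tr, kr)
  expect_equal(r2$dvx + r2$dvl, r2$Jsx - r2$T, tolerance = 1e-20)

  # night relaxation: with T = 0 the leaf store converges to the volume at
  # which psil = psis (analytic equilibrium of the linear PV curve)
  vx <- 0.9 * caps$vxmax
  vl <- 0.4 * caps$vlmax
  for (k in 1:14) {
    st <- step_capacitance(vx, vl, psis, dem, tr, kr, dt = 3600)
    vx <- st$vx; vl <- st$vl
  }
  expect_equal(vl, caps$vlmax * (1 - psis / tr$cl), tolerance = 1e-3)
  expect_equal(st$psil, psis, tolerance = 5e-3)
})

test_that("capacitance integration conserves water and is tolerance-stable", {
  tr <- plant_traits()
  caps <- storage_capacities(tr)
  params <- gas_params()
  soil <- default_soil()
  psis <- -0.3
  kr <- soil_root_conductance(soil, psis)
  frow <- test_frow(hour = 13)
  dem <- demand_function(psis, frow, tr, params, "tuzet")

  st <- step_capacitance(0.95 * caps$vxmax, 0.8 * caps$vlmax, psis, dem, tr,
                         kr, dt = 3600)
  expect_lt(abs(st$balance), 1e-9)

  st_tight <- step_capacitance(0.95 * caps$vxmax, 0.8 * caps$vlmax, psis,
                               dem, tr, kr, dt = 3600, rtol = 5e-7)
  expect_lt(abs(st_tight$T - st$T) / st$T, 1e-4)

  # the embedded Runge-Kutta 2(3) pair gives the same trajectory
  st_rk <- step_capacitance(0.95 * caps$vxmax, 0.8 * caps$vlmax, psis, dem,
                            tr, kr, dt = 3600, method = "ode23")
  expect_lt(abs(st_rk$T - st$T) / st$T, 1e-3)
  expect_lt(abs(st_rk$vx - st$vx), 1e-6)
})

test_that("vanishing capacitance recovers the steady-state solution", {
  tr <- plant_traits()
  tiny <- plant_traits(ax = tr$ax * 1e-6, lma = tr$lma * 1e-6)
  params <- gas_params()
  soil <- default_soil()
  psis <- -0.35
  kr <- soil_root_conductance(soil, psis)
  frow <- test_frow(hour = 13)
  dem <- demand_function(psis, frow, tr, params, "tuzet")
  st <- solve_steady(psis, frow, tr, params, kr, demand = dem)

  caps <- storage_capacities(tiny)
  sc <- step_capacitance(caps$vxmax * (1 - st$psix / tiny$cx) * 0.98,
                         caps$vlmax * 0.8, psis, dem, tiny, kr, dt = 3600)
  expect_lt(abs(sc$T - st$T) / st$T, 0.01)
  expect_equal(sc$psil, st$psil, tolerance = 0.02)
})

test_that("dog-leg root finder solves standard small systems", {
  # Rosenbrock-like residuals with known root (1, 1)
  fn <- function(x) c(10 * (x[2] - x[1]^2), 1 - x[1])
  sol <- dogleg_solve(fn, c(-1.2, 1))
  expect_true(sol$converged)
  expect_equal(sol$x, c(1, 1), tolerance = 1e-8)
  fn2 <- function(x) c(x[1] + 2 * x[2] - 3, x[1] - x[2])
  expect_equal(dogleg_solve(fn2, c(5, -7))$x, c(1, 1), tolerance = 1e-8)
})
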