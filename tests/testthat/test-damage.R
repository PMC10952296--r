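test_that("cohort initialization produces normalized distributions", {
  u <- init_cohorts(10, 100, distribution = "uniform")
  expect_equal(u$p, rep(0.1, 10))
  expect_equal(u$psimin, rep(0, 10))

  e <- init_cohorts(50, 500, distribution = "exponential", turnover = 0.01)
  expect_equal(sum(e$p), 1, tolerance = 1e-14)
  # truncated-exponential closed form: p_i proportional to exp(-mu * age_i)
  age <- (seq_len(50) - 0.5) * 10
  w <- exp(-0.01 * age)
  expect_equal(e$p, w / sum(w), tolerance = 1e-14)
})

test_that("minimum-potential memory is a running minimum", {
  c0 <- init_cohorts(5, 5)
  expect_equal(update_min_potential(c0, 0)$psimin, rep(0, 5))
  # monotone drying: memory equals the last (lowest) value
  cc <- c0
  for (psi in c(-0.5, -1, -2)) cc <- update_min_potential(cc, psi)
  expect_equal(cc$psimin, rep(-2, 5))
  # sawtooth: memory keeps the global minimum, not the final value
  cc <- c0
  for (psi in c(-1, -3, -0.5)) cc <- update_min_potential(cc, psi)
  expect_equal(cc$psimin, rep(-3, 5))
  # idempotent
  expect_equal(update_min_potential(cc, -3)$psimin, cc$psimin)
})

test_that("effective conductance is the density-weighted vulnerability sum", {
  tr <- plant_traits(kxmax = 1e-7, qx = log(2) / 4, px = 2)
  c0 <- init_cohorts(4, 4, tissue = "xylem")
  expect_equal(effective_conductivity(c0, tr), tr$kxmax)

  # half the mass undamaged, half at the 50%-loss potential
  c2 <- init_cohorts(2, 2, distribution = "uniform", tissue = "xylem")
  c2$psimin <- c(0, -2)
  expect_equal(effective_conductivity(c2, tr), 0.75 * tr$kxmax,
               tolerance = 1e-12)

  # random cohort state against a direct summation oracle
  set.seed(3)
  cr <- init_cohorts(30, 300, tissue = "xylem")
  cr$psimin <- -runif(30, 0, 5)
  oracle <- sum(cr$p * tr$kxmax * exp(-tr$qx * abs(cr$psimin)^tr$px))
  expect_equal(effective_conductivity(cr, tr), oracle, tolerance = 1e-14)
  expect_lte(effective_conductivity(cr, tr), tr$kxmax)

  # a current potential below the memory reduces conductance further,
  # a recovered potential does not raise it
  expect_lt(effective_conductivity(cr, tr, psi_now = -6),
            effective_conductivity(cr, tr))
  expect_equal(effective_conductivity(cr, tr, psi_now = 0),
               effective_conductivity(cr, tr))
})

test_that("cohort advection, oldest-first turnover and recruitment", {
  c0 <- init_cohorts(5, 5, distribution = "uniform")
  c0$psimin <- c(-1, -2, -3, -4, -5)

  # pure ageing with dt = class width: an exact shift
  adv <- advance_cohorts(c0, lambda = 0, mu = 0, dt = 1)
  expect_equal(adv$p, c(0, 0.2, 0.2, 0.2, 0.4))
  expect_equal(adv$psimin[2:4], c(-1, -2, -3))
  expect_equal(adv$psimin[5], -5)  # oldest keeps the worse memory

  # turnover removes exactly the oldest class when mu dt = p_oldest
  t1 <- advance_cohorts(c0, lambda = 0.2, mu = 0.2, dt = 1)
  expect_equal(sum(t1$p), 1, tolerance = 1e-14)
  expect_equal(t1$p[5], 0.2)  # shifted class 4 mass remains after removal
  expect_equal(t1$p[1], 0.2)  # recruits
  expect_equal(t1$psimin[1], 0)

  expect_error(advance_cohorts(c0, mu = 2, dt = 1), "exceeds")
  expect_error(advance_cohorts(c0, mu = 0.1, dt = 3), "class width")

  # sustained turnover from a damaged state restores full conductance
  tr <- plant_traits()
  cc <- init_cohorts(10, 10, distribution = "uniform", tissue = "xylem")
  cc$psimin <- rep(-3, 10)
  k0 <- effective_conductivity(cc, tr)
  for (d in 1:12) cc <- advance_cohorts(cc, lambda = 0.1, mu = 0.1, dt = 1)
  expect_equal(effective_conductivity(cc, tr), tr$kxmax, tolerance = 1e-10)
  expect_gt(effective_conductivity(cc, tr), k0)
})

test_that("normalization is conserved over many steps", {
  cc <- init_cohorts(60, 60)
  set.seed(11)
  for (k in 1:1e5) {
    cc <- advance_cohorts(cc, lambda = 0.01, mu = 0.01, dt = 1)
    if (k %% 2e4 == 0) expect_lt(abs(sum(cc$p) - 1), 1e-12)
  }
  expect_lt(abs(sum(cc$p) - 1), 1e-12)
})

test_that("with no turnover, effective conductance never increases", {
  tr <- plant_traits()
  set.seed(5)
  for (case in 1:1000) {
    cc <- init_cohorts(8, 80, tissue = if (case %% 2) "xylem" else "leaf")
    k_prev <- effective_conductivity(cc, tr)
    trace <- -cumsum(runif(12, -0.4, 0.6))  # wandering potential
    trace <- pmin(trace, 0)
    for (psi in trace) {
      cc <- update_min_potential(cc, psi)
      k_now <- effective_conductivity(cc, tr)
      expect_lte(k_now, k_prev + 1e-18)
      k_prev <- k_now
    }
  }
})
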