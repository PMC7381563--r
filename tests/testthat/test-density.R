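test_that("recruitment calibration matches closed forms and its contract", {
  # AFR-1: lambda = S_ad + c * S0 * m/2, so c has a closed form
  c101 <- calibrate_recruitment(STARLING60, 1.01)
  expect_equal(c101, (1.01 - 0.677) / (0.331 * 2.56 / 2), tolerance = 1e-8)
  # AFR-2 quadratic characteristic equation:
  # lambda0^2 = s * lambda0 + c * F * S0 with F = 0.858 * 0.9
  cg <- calibrate_recruitment(GODWIT_K, 1.03)
  expect_equal(cg, (1.03^2 - 0.858 * 1.03) / (0.7722 * 0.169),
               tolerance = 1e-8)
  # a target at the current growth rate leaves recruitment untouched
  lam_now <- dominant_eigen(build_matrix(STARLING60))$lambda
  expect_equal(calibrate_recruitment(STARLING60, lam_now), 1,
               tolerance = 1e-8)
  # calibrated model satisfies its eigenvalue invariant for every fixture
  for (v in CAT11) {
    m <- dd_model(v, 1.1)
    expect_equal(birdpva:::lambda1(v, fecundity_scale = m$recruitment_scalar),
                 1.1, tolerance = 1e-8)
  }
  # unreachable target names the bound
  expect_error(calibrate_recruitment(STARLING60, 0.5), "self-loop 0.677")
})

test_that("dd multiplier is the floored linear ramp", {
  expect_equal(dd_multiplier(0, 1000), 1)
  expect_equal(dd_multiplier(250, 1000), 0.75)
  expect_equal(dd_multiplier(1000, 1000), 0)
  expect_equal(dd_multiplier(2000, 1000), 0)
  expect_error(dd_multiplier(10, 0), "kprime")
  expect_error(dd_multiplier(-1, 10))
})

test_that("leftover r0 follows the AFR-1 closed form", {
  # x = 0: exactly the calibration target
  expect_equal(leftover_r0(dd_model(STARLING60, 1.1)), 0.1, tolerance = 1e-8)
  m <- dd_model(STARLING60, 1.1, extra_mortality = 0.10)
  cc <- m$recruitment_scalar
  expect_equal(leftover_r0(m),
               afr1_lambda(STARLING60, x = 0.10, fec_scale = cc) - 1,
               tolerance = 1e-10)
  expect_equal(leftover_r0(m), -0.0178, tolerance = 2e-3)
  m2 <- dd_model(STARLING60, 1.01, extra_mortality = 0.01)
  expect_equal(leftover_r0(m2), 0.0000, tolerance = 1e-4)
  # stochastic estimator agrees with the eigenvalue in the zero-SD limit
  v0 <- zero_sds_local(STARLING60)
  m0 <- dd_model(v0, 1.1, extra_mortality = 0.05)
  expect_equal(leftover_r0(m0, method = "stochastic", n_reps = 3, years = 20),
               leftover_r0(m0), tolerance = 1e-9)
})

test_that("equilibrium density matches the deterministic fixed point", {
  # zero-SD Starling at lambda0 = 1.1: growth 1 requires
  # S_ad + c * S0 * m/2 * mult = 1, a scalar fixed point
  v0 <- zero_sds_local(STARLING60)
  m <- dd_model(v0, 1.1, kprime = 1e4)
  cc <- m$recruitment_scalar
  mult_star <- (1 - 0.677) / (cc * 0.331 * 1.28)
  A_star <- 1e4 * (1 - mult_star)
  Mstar <- build_matrix(v0, fecundity_scale = cc * mult_star)
  w <- dominant_eigen(Mstar)$w
  nstar_oracle <- A_star / w[2]          # only the adult class breeds at AFR 1
  det <- equilibrium_density(m, method = "deterministic")
  expect_equal(det, nstar_oracle, tolerance = 1e-6)
  # the zero-SD stochastic protocol converges to the same point
  sim <- equilibrium_density(m, n_reps = 2, seed = 1,
                             burn_in = 400, window = 100)
  expect_equal(sim, det, tolerance = 1e-3)
  # subcritical treatment goes extinct: N* = 0
  m_dead <- dd_model(v0, 1.1, extra_mortality = 0.10)
  expect_equal(equilibrium_density(m_dead, method = "deterministic"), 0)
  expect_equal(equilibrium_density(m_dead, n_reps = 2, seed = 1), 0)
  # doubling K' doubles N* in the deterministic limit
  m2 <- dd_model(v0, 1.1, kprime = 2e4)
  expect_equal(equilibrium_density(m2, method = "deterministic"), 2 * det,
               tolerance = 1e-9)
})

test_that("responses are K'-independent and floored at -100", {
  v0 <- zero_sds_local(STARLING60)
  cc <- calibrate_recruitment(v0, 1.1)
  oracle <- 100 * ((afr1_lambda(v0, 0.05, cc) - 1) - 0.1) / 0.1
  for (kp in c(1e3, 1e5)) {
    r <- dd_response(v0, 1.1, 0.05, kprime = kp,
                     nstar_method = "deterministic")
    expect_equal(r$r0_response_pct, oracle, tolerance = 1e-6)
    if (kp == 1e3) first <- r
  }
  expect_equal(r, first, tolerance = 1e-9)
  # stochastic route, same invariance up to shared-seed Monte-Carlo noise
  rs <- lapply(c(1e3, 1e5), function(kp)
    dd_response(STARLING60, 1.1, 0.02, kprime = kp, n_reps = 150, seed = 4,
                burn_in = 600, window = 300))
  expect_equal(rs[[1]]$nstar_response_pct, rs[[2]]$nstar_response_pct,
               tolerance = 0.05)
  # identical treatment: exactly (0, 0)
  base <- dd_model(STARLING60, 1.1)
  z <- response_summary(base, base, n_reps = 50, seed = 2,
                        burn_in = 200, window = 100)
  expect_equal(z$r0_response_pct, 0)
  expect_equal(z$nstar_response_pct, 0)
  # extinction floor
  dead <- dd_response(v0, 1.1, 0.10, nstar_method = "deterministic")
  expect_equal(dead$nstar_response_pct, -100)
  # declining baseline is rejected
  low <- dd_model(zero_sds_local(STARLING90), 0.9)
  expect_error(response_summary(low, low), "r0 <= 0")
})

test_that("response magnitudes grow with x and shrink with lambda0", {
  for (v in list(STARLING60, GODWIT_K, fixture(CAT11, "eagle", "1975"))) {
    v0 <- zero_sds_local(v)
    grid <- expand.grid(x = c(0.01, 0.02, 0.05, 0.10),
                        lam0 = c(1.01, 1.03, 1.1))
    resp <- mapply(function(x, l0) {
      r <- dd_response(v0, l0, x, nstar_method = "deterministic")
      c(r$r0_response_pct, r$nstar_response_pct)
    }, grid$x, grid$lam0)
    for (l0 in unique(grid$lam0)) {          # worse with more mortality
      i <- grid$lam0 == l0
      expect_true(all(diff(resp[1, i]) < 0))
      expect_true(all(diff(resp[2, i]) <= 0))
    }
    for (x in unique(grid$x)) {              # milder at higher lambda0
      i <- grid$x == x
      expect_true(all(diff(resp[1, i]) > 0))
      expect_true(all(diff(resp[2, i]) >= 0))
    }
  }
})
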