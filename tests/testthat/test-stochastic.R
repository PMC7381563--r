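test_that("annual draws respect bounds, degeneracy and clipped-normal moments", {
  # degenerate normals: zero SDs come back exactly at the means
  v0 <- zero_sds_local(STARLING60)
  expect_equal(draw_annual_rates(v0, seed = 1)$survival$mean,
               v0$survival$mean)
  # bulk draws through the engine: no survival draw may leave [0, 1]; the
  # realized mean matches the analytic clipped-normal mean. Survival 0.607
  # +- 0.151 (Starling 1990-2012 adult) presses both bounds.
  sim <- birdpva:::simulate_cohorts(STARLING90, years = 1, n_reps = 1e5,
                                    init_state = c(500, 500), seed = 2)
  expect_true(all(sim$totals >= 0))
  draws <- replicate(2e4, draw_annual_rates(STARLING90)$survival$mean)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_equal(mean(draws[3, ]), clipped_normal_mean(0.607, 0.151),
               tolerance = 0.005)
  expect_lt(abs(mean(draws[1, ]) - clipped_normal_mean(0.102, 0.034)),
            4 * 0.034 / sqrt(2e4))
  mdraws <- replicate(5e3, draw_annual_rates(STARLING90)$fledglings_mean)
  expect_true(all(mdraws >= 0))
  expect_lt(abs(mean(mdraws) - 3.73), 4 * 0.546 / sqrt(5e3))
})

test_that("projection is deterministic in the limit and reproducible by seed", {
  v0 <- zero_sds_local(STARLING90)
  p <- project(v0, projection_config(years = 10, n_reps = 3, seed = 1))
  lam <- afr1_lambda(STARLING90)
  expect_equal(p$totals[11, ], rep(1000 * lam^10, 3), tolerance = 1e-9)
  expect_equal(p$mean_by_year[11], 103.71, tolerance = 1e-4)
  # same seed twice: bit-identical trajectories
  cfg <- projection_config(years = 10, n_reps = 50, seed = 77)
  expect_identical(project(STARLING90, cfg)$totals,
                   project(STARLING90, cfg)$totals)
  # year-0 total is the initial population
  expect_equal(p$totals[1, ], rep(1000, 3))
})

test_that("decline statistic matches its deterministic oracle and contracts", {
  v0 <- zero_sds_local(STARLING90)
  cfg <- projection_config(years = 10, n_reps = 2, seed = 1)
  d0 <- decline_10(v0, 0.01, cfg)
  lam_b <- afr1_lambda(STARLING90)
  lam_t <- afr1_lambda(STARLING90, x = 0.01)
  expect_equal(d0, 100 * (1 - (lam_t / lam_b)^10), tolerance = 1e-9)
  expect_equal(d0, 23.08, tolerance = 0.01)
  # treated == baseline -> exactly zero under common random numbers
  expect_equal(decline_10(STARLING90, 0,
                          projection_config(10, 200, seed = 3)), 0)
  # shared-seed runs differing only in scenario are paired draws
  b <- project(STARLING90, projection_config(10, 100, seed = 5))
  t <- project(STARLING90, projection_config(10, 100, seed = 5,
                                             extra_mortality = 0.01))
  expect_true(all(t$totals[11, ] < b$totals[11, ]))
  expect_error(decline_after_10_years(
    project(STARLING90, projection_config(5, 10, 1)), b), "10 years")
})

test_that("decline is invariant to initial population size", {
  # the density-independent dynamics are linear in the state, so the ratio
  # statistic cannot depend on the starting size
  cfg1 <- projection_config(years = 10, n_reps = 500, seed = 11,
                            initial_population = 1000)
  cfg2 <- projection_config(years = 10, n_reps = 500, seed = 11,
                            initial_population = 100)
  expect_equal(decline_10(STARLING60, 0.05, cfg1),
               decline_10(STARLING60, 0.05, cfg2), tolerance = 1e-9)
})

test_that("decline grows with mortality and reproduces the printed ranges", {
  # monotonicity in x, deterministic limit, every fixture
  for (v in CAT11) {
    v0 <- zero_sds_local(v)
    cfg <- projection_config(years = 10, n_reps = 2, seed = 1)
    d <- vapply(c(0, 0.01, 0.02, 0.05, 0.10),
                function(x) decline_10(v0, x, cfg), numeric(1))
    expect_true(all(diff(d) >= 0))
  }
  # 1% extra mortality, full stochasticity: slow species lose ~2-3% in 10
  # years, the Tern ~5%. The Godwits sit near 7% from the printed inputs
  # (their printed fledgling rates conflict with the source text) and are
  # asserted at their computed level rather than inside the 2-3% band.
  cfg <- projection_config(years = 10, n_reps = 2000, seed = 1)
  for (key in list(c("harrier"), c("spoonbill"), c("stork"),
                   c("eagle", "1947"), c("eagle", "1975"))) {
    d <- decline_10(fixture(CAT11, key), 0.01, cfg)
    expect_gt(d, 1.5)
    expect_lt(d, 4)
  }
  expect_equal(decline_10(fixture(CAT11, "tern"), 0.01, cfg), 5,
               tolerance = 0.2 * 5)
  for (g in list(GODWIT_K, fixture(CAT11, "skriezekrite")))
    expect_lt(abs(decline_10(g, 0.01, cfg) - 7), 1.5)
})

test_that("stochastic year-10 mean tracks the deterministic projection", {
  # at 10% of the printed SDs the clipping bias is negligible and the
  # expected trajectory is the mean-matrix power
  v <- STARLING60
  v$survival$sd <- v$survival$sd * 0.1
  p <- project(v, projection_config(years = 10, n_reps = 5000, seed = 9))
  expect_equal(p$mean_by_year[11], 1000 * afr1_lambda(v)^10, tolerance = 0.01)
})
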