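test_that("domain type constructors enforce their invariants", {
  expect_error(pool_state(B_f = -0.1), class = "allocsim_invalid_argument")
  expect_error(allocation_vector(0.5, 0.4, 0.2), class = "allocsim_invalid_argument")
  expect_error(allocation_vector(0.5, 0.6, -0.1), class = "allocsim_invalid_argument")
  expect_error(turnover_vector(-0.1, 0, 0), class = "allocsim_invalid_argument")
  expect_error(env_state(co2 = 0), class = "allocsim_invalid_argument")
  expect_error(env_state(co2 = 400, W = 1.5), class = "allocsim_invalid_argument")
  expect_equal(total_biomass(pool_state(1, 2, 3, 4)), 10)
  expect_equal(unname(lifespans(turnover_vector(0.5, 0, 2))), c(2, Inf, 0.5))
})

test_that("pool stepping handles the identity and single-sink cases", {
  s <- pool_state(B_f = 0.3, B_w = 5, B_r = 0.2, B_rep = 0.1)
  r <- step_pools(s, npp = 0, alloc = allocation_vector(0.25, 0.25, 0.25, 0.25),
                  turnover = turnover_vector(0, 0, 0), dt = 1)
  expect_equal(unclass(r$state), unclass(s))
  expect_equal(c(r$litter_f, r$litter_w, r$litter_r), c(0, 0, 0))

  r2 <- step_pools(pool_state(), npp = 1, alloc = allocation_vector(1, 0, 0),
                   turnover = turnover_vector(0, 0, 0), dt = 1)
  expect_equal(r2$state[["B_f"]], 1.0)
})

test_that("pool stepping rejects bad arguments and unstable steps", {
  s <- pool_state(B_w = 1)
  a <- allocation_vector(0, 1, 0)
  u <- turnover_vector(0, 0.5, 0)
  expect_error(step_pools(s, -1, a, u, 1), class = "allocsim_invalid_argument")
  expect_error(step_pools(s, 1, a, u, 0), class = "allocsim_invalid_argument")
  err <- tryCatch(step_pools(s, 1, a, turnover_vector(0, 3, 0), dt = 0.5),
                  error = identity)
  expect_s3_class(err, "allocsim_stability_error")
  expect_match(conditionMessage(err), "u_w")
})

test_that("iterated stepping converges to the closed-form steady state", {
  # fixed point of dB = (a npp - u B) dt is B* = a npp / u
  a <- allocation_vector(0.2, 0.5, 0.3)
  u <- turnover_vector(0.5, 0.02, 0.7)
  s <- pool_state()
  dt <- 0.05  # the fixed point does not depend on dt; coarse is fine here
  for (i in seq_len(round(1250 / dt))) s <- step_pools(s, 1.0, a, u, dt)$state
  expect_equal(s[["B_w"]], 0.5 * 1.0 / 0.02, tolerance = 1e-6)
  expect_equal(s[["B_f"]], 0.2 / 0.5, tolerance = 1e-6)
  expect_equal(s[["B_r"]], 0.3 / 0.7, tolerance = 1e-6)
})

test_that("each step conserves mass and preserves non-negativity", {
  set.seed(7)
  for (i in 1:50) {
    s <- pool_state(runif(1, 0, 1), runif(1, 0, 10), runif(1, 0, 1), runif(1, 0, 0.2))
    raw <- runif(4); raw <- raw / sum(raw)
    a <- allocation_vector(raw[1], raw[2], raw[3], raw[4])
    u <- turnover_vector(runif(1, 0, 2), runif(1, 0, 0.1), runif(1, 0, 2))
    npp <- runif(1, 0, 3)
    dt <- runif(1, 1e-4, 0.2)
    r <- step_pools(s, npp, a, u, dt)
    gained <- total_biomass(r$state) - total_biomass(s)
    shed <- r$litter_f + r$litter_w + r$litter_r
    expect_equal(gained, npp * dt - shed, tolerance = 1e-9)
    expect_true(all(unclass(r$state) >= 0))
    expect_true(all(c(r$litter_f, r$litter_w, r$litter_r) >= 0))
  }
})

test_that("with zero turnover pools grow exactly linearly", {
  a <- allocation_vector(0.4, 0.4, 0.2)
  u <- turnover_vector(0, 0, 0)
  s <- pool_state()
  for (i in 1:730) s <- step_pools(s, 2.0, a, u, 1 / 365)$state
  expect_equal(s[["B_f"]], 0.4 * 2.0 * 2, tolerance = 1e-12)
  expect_equal(s[["B_r"]], 0.2 * 2.0 * 2, tolerance = 1e-12)
})

test_that("halving the time step changes a 10-year trajectory by under 1%", {
  a <- allocation_vector(0.3, 0.5, 0.2)
  u <- turnover_vector(0.5, 0.02, 0.7)
  run <- function(dt) {
    s <- pool_state(B_f = 0.1, B_w = 1, B_r = 0.1)
    for (i in seq_len(round(10 / dt))) s <- step_pools(s, 1, a, u, dt)$state
    unclass(s)
  }
  b1 <- run(1 / 365)
  b2 <- run(1 / 730)
  expect_true(all(abs(b1 - b2) / pmax(b2, 1e-12) < 0.01))
})

test_that("the phenology clock visits phases in cyclic order", {
  p <- phenology_params(deciduous = TRUE, lai_max = 5)
  # pre-season: below the budburst temperature sum
  expect_equal(advance_phenology(env_state(400, t_day = 30, degree_days = 10),
                                 lai = 0, lai_max = 5, p, "DORMANT"), "DORMANT")
  # budburst
  expect_equal(advance_phenology(env_state(400, t_day = 100, degree_days = 200),
                                 lai = 0.1, lai_max = 5, p, "DORMANT"), "LEAF_EXPANSION")
  # LAI rising through half the maximum ends expansion
  expect_equal(advance_phenology(env_state(400, t_day = 140, degree_days = 500),
                                 lai = 2.6, lai_max = 5, p, "LEAF_EXPANSION"), "STEADY_GROWTH")
  # after midseason, falling below 95% of the maximum starts senescence
  expect_equal(advance_phenology(env_state(400, t_day = 250, degree_days = 2000),
                                 lai = 4.7, lai_max = 5, p, "STEADY_GROWTH"), "SENESCENCE")
  # the same LAI before midseason does not
  expect_equal(advance_phenology(env_state(400, t_day = 150, degree_days = 800),
                                 lai = 4.7, lai_max = 5, p, "STEADY_GROWTH"), "STEADY_GROWTH")
  # bare canopy ends the cycle
  expect_equal(advance_phenology(env_state(400, t_day = 300, degree_days = 2500),
                                 lai = 0.1, lai_max = 5, p, "SENESCENCE"), "DORMANT")
  expect_error(advance_phenology(env_state(400), lai = 1, lai_max = 0, p, "DORMANT"),
               class = "allocsim_invalid_argument")
  # evergreen stays in steady growth
  expect_equal(advance_phenology(env_state(400), 0, 5,
                                 phenology_params(deciduous = FALSE), "DORMANT"),
               "STEADY_GROWTH")
})
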