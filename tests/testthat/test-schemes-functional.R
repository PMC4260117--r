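test_that("deficit-filling reserve C splits 70:30 between wood and reproduction", {
  sch <- ed2_scheme()
  # put leaf and root pools exactly at their targets so everything is reserve
  env <- env_state(co2 = 380, W = 1, Nfac = 1)
  q <- sch$q_base                      # no stress
  denom <- 1 + q + sch$q_sw * sch$height
  B_w <- 5
  # solve B_f = active/denom with active = B_f + awf*B_w + B_r, B_r = q*B_f
  B_f <- sch$active_wood_frac * B_w / (denom - 1 - q)
  st <- pool_state(B_f = B_f, B_w = B_w, B_r = q * B_f)
  a <- ed2_alloc(st, env, e_t = 1, params = sch, growth_c = 0.01)
  expect_equal(a[["a_w"]], 0.70, tolerance = 1e-9)
  expect_equal(a[["a_rep"]], 0.30, tolerance = 1e-9)
  # leaf-off phenology shuts down foliage allocation
  a0 <- ed2_alloc(pool_state(0, 5, 0), env, e_t = 0, sch, growth_c = 0.01)
  expect_equal(a0[["a_f"]], 0)
  expect_error(ed2_alloc(st, env, e_t = 1.2, sch, 0.01),
               class = "allocsim_invalid_argument")
})

test_that("raising the root:leaf ratio never lowers root allocation", {
  # oracle: recompute targets and deficits by hand over a small stress grid
  sch0 <- ed2_scheme(q_stress_gain = 0)
  st <- pool_state(B_f = 0.2, B_w = 5, B_r = 0.1)
  for (W in c(1, 0.6, 0.2)) {
    env <- env_state(380, W = W)
    a_lo <- ed2_alloc(st, env, 1, ed2_scheme(q_base = 0.3), 0.02)
    a_hi <- ed2_alloc(st, env, 1, ed2_scheme(q_base = 0.6), 0.02)
    # hand oracle for the low-q case
    q <- 0.3 + 0.8 * (1 - W)
    active <- 0.2 + 0.3 * 5 + 0.1
    peak <- active / (1 + q + 0.1 * 18)
    d_f <- max(0, peak - 0.2); d_r <- max(0, q * peak - 0.1)
    hand <- ed2_alloc(st, env, 1, ed2_scheme(), 0.02)
    if (d_f + d_r >= 0.02) {
      expect_equal(hand[["a_r"]], d_r / (d_f + d_r), tolerance = 1e-9)
    }
    expect_gte(a_hi[["a_r"]], a_lo[["a_r"]] - 1e-12)
  }
})

test_that("allometric allocation sends exactly the reproduction fraction first", {
  sch <- lpj_scheme()
  pools <- lpj_initial_state(sch, lai = 3)
  res <- lpj_alloc_annual(pools, annual_npp = 0.8, N = 1, W = 1, sch)
  expect_equal(res$alloc[["a_rep"]], 0.10, tolerance = 1e-12)
  expect_valid_alloc(res$alloc)
})

test_that("on-allometry increments preserve the leaf:root ratio as NPP -> 0", {
  sch <- lpj_scheme()
  pools <- lpj_initial_state(sch, lai = 3, N = 1, W = 1)
  res <- lpj_alloc_annual(pools, annual_npp = 1e-6, N = 1, W = 1, sch)
  inc <- res$increments
  expect_equal(inc[["d_f"]] / inc[["d_r"]], sch$lr_max, tolerance = 1e-4)
})

test_that("post-growth stocks satisfy the structural constraints", {
  sch <- lpj_scheme()
  set.seed(31)
  for (i in 1:10) {
    lai0 <- runif(1, 1, 5)
    N <- runif(1, 0.4, 1); W <- runif(1, 0.4, 1)
    pools <- lpj_initial_state(sch, lai = lai0, N = N, W = W)
    res <- lpj_alloc_annual(pools, annual_npp = runif(1, 0.2, 1.2), N, W, sch)
    inc <- res$increments
    C_f <- pools[["B_f"]] + inc[["d_f"]]
    C_w <- pools[["B_w"]] + inc[["d_w"]]
    C_r <- pools[["B_r"]] + inc[["d_r"]]
    # pipe model + height-diameter: wood exactly supports the new leaf stock
    expect_equal(C_w, wood_required(C_f, sch), tolerance = 1e-6)
    # functional balance on stocks
    expect_equal(C_f / C_r, sch$lr_max * min(N, W), tolerance = 1e-6)
    expect_true(all(inc >= 0))
  }
})

test_that("the bisection solution matches a fine 1-D scan of the leaf increment", {
  # oracle: exhaustive scan over the leaf increment at 1e-6 resolution, with
  # the wood and root constraints eliminating the other two increments
  set.seed(17)
  for (i in 1:20) {
    sch <- lpj_scheme(k_la_sa = runif(1, 2000, 6000),
                      lr_max = runif(1, 0.6, 1.5),
                      sla = runif(1, 6, 14))
    N <- runif(1, 0.3, 1); W <- runif(1, 0.3, 1)
    pools <- lpj_initial_state(sch, lai = runif(1, 1.5, 4), N = N, W = W)
    ## shift the pools slightly off allometry so the solve is non-trivial
    pools <- pool_state(pools[["B_f"]] * runif(1, 0.9, 1.0),
                        pools[["B_w"]] * runif(1, 0.95, 1.05),
                        pools[["B_r"]] * runif(1, 0.9, 1.1))
    npp <- runif(1, 0.1, 0.5)
    avail <- (1 - sch$repro_fraction) * npp
    grid <- seq(0, avail, by = 1e-6)
    s <- min(max(min(N, W), 1e-6), 1)
    root_def <- pmax(0, (pools[["B_f"]] + grid) / (sch$lr_max * s) - pools[["B_r"]])
    wood_def <- pmax(0, vapply(pools[["B_f"]] + grid, wood_required, numeric(1), sch) -
                       pools[["B_w"]])
    resid <- grid + root_def + wood_def - avail
    x_grid <- grid[which.min(abs(resid))]
    res <- lpj_alloc_annual(pools, npp, N, W, sch)
    expect_lt(abs(res$increments[["d_f"]] - x_grid), 1e-5)
  }
})

test_that("off-allometry pools yield a flagged constrained solution, never disinvestment", {
  sch <- lpj_scheme()
  # wood far below what the (large) canopy requires: a mortality-like state
  pools <- pool_state(B_f = 0.5, B_w = 0.05, B_r = 0.5)
  res <- lpj_alloc_annual(pools, annual_npp = 0.3, N = 1, W = 1, sch)
  expect_true("off_allometry" %in% res$flags)
  expect_true(all(res$increments >= 0))
  expect_valid_alloc(res$alloc)
})

test_that("daily allocation integrates to the annual solution under constant forcing", {
  ann <- lpj_scheme()
  dai <- ocn_scheme()
  pools <- lpj_initial_state(ann, lai = 3)
  npp_year <- 0.8
  res_a <- lpj_alloc_annual(pools, npp_year, N = 1, W = 1, ann)
  p <- pools
  tot <- c(d_f = 0, d_w = 0, d_r = 0, d_rep = 0)
  for (d in 1:365) {
    r <- ocn_daily_alloc(p, npp_year / 365, N = 1, W = 1, dai)
    tot <- tot + r$increments
    p <- pool_state(p[["B_f"]] + r$increments[["d_f"]],
                    p[["B_w"]] + r$increments[["d_w"]],
                    p[["B_r"]] + r$increments[["d_r"]],
                    p[["B_rep"]] + r$increments[["d_rep"]])
  }
  for (k in names(tot)) {
    expect_equal(tot[[k]], res_a$increments[[k]],
                 tolerance = 0.02 * max(res_a$increments[[k]], npp_year * 0.05))
  }
  # a zero-NPP day allocates nothing and says so
  r0 <- ocn_daily_alloc(pools, 0, 1, 1, dai)
  expect_true("no_growth" %in% r0$flags)
  expect_equal(sum(r0$increments), 0)
})

test_that("declining nitrogen availability shifts cumulative allocation to roots", {
  dai <- ocn_scheme()
  p <- lpj_initial_state(dai, lai = 3)
  root_share <- numeric(0)
  for (yr in 1:6) {
    N <- 1 - 0.08 * (yr - 1)
    tot <- c(0, 0, 0, 0)
    for (d in 1:73) {  # coarse 5-day lumps keep this quick
      r <- ocn_daily_alloc(p, 0.8 / 73, N = N, W = 1, dai)
      tot <- tot + unname(r$increments)
      p <- pool_state(p[["B_f"]] + r$increments[["d_f"]],
                      p[["B_w"]] + r$increments[["d_w"]],
                      p[["B_r"]] + r$increments[["d_r"]])
    }
    root_share <- c(root_share, tot[3] / sum(tot))
  }
  # sign check: year-on-year differences all non-negative, overall rise clear
  expect_true(all(diff(root_share) > -1e-9))
  expect_gt(root_share[6], root_share[1])
})

test_that("lower resource availability raises the equilibrium root:leaf ratio", {
  sch <- lpj_scheme()
  equil_ratio <- function(N, W) {
    pools <- lpj_initial_state(sch, lai = 3, N = N, W = W)
    for (yr in 1:10) {
      res <- lpj_alloc_annual(pools, 0.8, N, W, sch)
      inc <- res$increments
      u <- default_turnover()
      pools <- pool_state(
        max(0, pools[["B_f"]] * (1 - u[["u_f"]]) + inc[["d_f"]]),
        max(0, pools[["B_w"]] * (1 - u[["u_w"]]) + inc[["d_w"]]),
        max(0, pools[["B_r"]] * (1 - u[["u_r"]]) + inc[["d_r"]]))
    }
    pools[["B_r"]] / pools[["B_f"]]
  }
  r_unstressed <- equil_ratio(1, 1)
  r_n_limited <- equil_ratio(0.6, 1)
  r_w_limited <- equil_ratio(1, 0.5)
  expect_gt(r_n_limited, r_unstressed)
  expect_gt(r_w_limited, r_n_limited)
})
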