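cable_like <- function() fixed_scheme(
  base = allocation_vector(0.30, 0.50, 0.20),
  phase_table = list(
    LEAF_EXPANSION = allocation_vector(0.80, 0.10, 0.10),
    STEADY_GROWTH = allocation_vector(0.30, 0.50, 0.20),
    SENESCENCE = allocation_vector(0, 0.55, 0.45),
    DORMANT = allocation_vector(0, 0.55, 0.45)
  ))

test_that("phase-tabled coefficients are returned verbatim per phase", {
  sch <- cable_like()
  expect_equal(unclass(fixed_alloc(sch, "LEAF_EXPANSION", "ambient", 1))[1:3],
               c(a_f = 0.80, a_w = 0.10, a_r = 0.10))
  expect_equal(unclass(fixed_alloc(sch, "SENESCENCE", "ambient", 1))[1:3],
               c(a_f = 0, a_w = 0.55, a_r = 0.45))
  # construction-time validation of a non-normalised vector
  expect_error(fixed_scheme(c(0.5, 0.4, 0.2)), class = "allocsim_invalid_argument")
  # strict mode demands phase coverage
  strict <- fixed_scheme(allocation_vector(1, 0, 0),
                         phase_table = list(STEADY_GROWTH = allocation_vector(1, 0, 0)),
                         strict_phases = TRUE)
  expect_error(fixed_alloc(strict, "SENESCENCE"), class = "allocsim_config_error")
})

test_that("a treatment override switches coefficients from its start year", {
  sch <- fixed_scheme(allocation_vector(0.3, 0.5, 0.2),
                      treatment_override = allocation_vector(0.3, 0.4, 0.3),
                      override_start_year = 2)
  expect_equal(fixed_alloc(sch, treatment = "elevated", year = 1)[["a_r"]], 0.2)
  expect_equal(fixed_alloc(sch, treatment = "elevated", year = 2)[["a_r"]], 0.3)
  expect_equal(fixed_alloc(sch, treatment = "ambient", year = 5)[["a_r"]], 0.2)
})

test_that("a pure fixed scheme has exactly zero CO2 allocation response", {
  exp <- run_experiment(
    scheme = fixed_scheme(allocation_vector(0.3, 0.5, 0.2)),
    turnover = default_turnover(),
    scenario = quick_scenario(noise_cv = 0.05, seed = 9))
  # the simulated coefficients are identical between treatments even though
  # NPP differs; only observation noise can make recovered fractions differ
  resp <- exp$responses$alloc_response_true
  expect_equal(max(abs(as.matrix(resp[, -1]))), 0, tolerance = 1e-12)

  noise_free <- run_experiment(
    scheme = fixed_scheme(allocation_vector(0.3, 0.5, 0.2)),
    turnover = default_turnover(),
    scenario = quick_scenario(noise_cv = 0, seed = 9))
  expect_equal(max(abs(as.matrix(noise_free$responses$alloc_response[, -1]))), 0,
               tolerance = 1e-12)
})

test_that("phased coefficients plus a drought year shift annual wood allocation", {
  # elevated CO2 relieves drought stress, so the NPP enhancement peaks in
  # the wood-heavy post-expansion phase; the NPP-weighted annual wood
  # fraction must then rise even though every phase vector is fixed
  scn <- face_scenario(n_years = 4, npp0 = 0.9, deciduous = TRUE,
                       drought_years = 3L, drought_w = 0.35,
                       drought_mitigation_eco2 = 0.4, sla = 15, seed = 5)
  phen <- phenology_params(deciduous = TRUE, lai_max = 4)
  exp <- run_experiment(scheme = cable_like(), turnover = default_turnover(),
                        scenario = scn, phenology = phen,
                        init = pool_state(B_f = 0.01, B_w = 5, B_r = 0.1))
  resp <- exp$responses$alloc_response
  drought_resp <- resp$d_a_w[resp$year == 3]
  other_resp <- resp$d_a_w[resp$year != 3]
  expect_gt(drought_resp, 0)
  expect_gt(drought_resp, max(abs(other_resp)))
})

test_that("the prescribed-LAI scheme switches allocation at its breakpoint", {
  sch <- ealco_scheme(lai_max_by_year = 5.5)
  expect_equal(unclass(ealco_alloc(sch, lai = 2.0)),
               c(a_f = 1, a_w = 0, a_r = 0, a_rep = 0))
  expect_equal(unclass(ealco_alloc(sch, lai = 5.5)),
               c(a_f = 0, a_w = 0.60, a_r = 0.40, a_rep = 0))
  expect_equal(unclass(ealco_alloc(sch, lai = 9)),
               c(a_f = 0, a_w = 0.60, a_r = 0.40, a_rep = 0))
  # piecewise constant in lai with a single breakpoint
  lais <- seq(0, 8, by = 0.25)
  afs <- vapply(lais, function(l) ealco_alloc(sch, l)[["a_f"]], numeric(1))
  expect_equal(unique(afs), c(1, 0))
  expect_equal(sum(diff(afs) != 0), 1)
  # degenerate threshold: the post-maximum split applies from the start
  zero <- ealco_scheme(lai_max_by_year = 0)
  expect_equal(ealco_alloc(zero, lai = 0)[["a_f"]], 0)
})

test_that("per-year prescribed LAI tables are looked up by year and treatment", {
  tab <- data.frame(year = c(1, 1), treatment = c("ambient", "elevated"),
                    lai_max = c(4, 4.5))
  sch <- ealco_scheme(lai_max_by_year = tab)
  expect_equal(ealco_alloc(sch, lai = 4.2, year = 1, treatment = "ambient")[["a_f"]], 0)
  expect_equal(ealco_alloc(sch, lai = 4.2, year = 1, treatment = "elevated")[["a_f"]], 1)
  expect_error(ealco_alloc(sch, lai = 1, year = 2, treatment = "ambient"),
               class = "allocsim_config_error")
})
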