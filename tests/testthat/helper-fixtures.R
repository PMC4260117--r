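# Shared fixtures: small, fast study conditions used across test files.

default_turnover <- function() turnover_vector(u_f = 0.5, u_w = 0.02, u_r = 0.7)

quick_scenario <- function(...) {
  args <- utils::modifyList(list(n_years = 5, seed = 42, noise_cv = 0), list(...))
  do.call(face_scenario, args)
}

flat_forcing <- function(n_years, npp = 1, co2 = 380, W = 1, Nfac = 1) {
  doy <- rep(1:365, n_years)
  data.frame(year = rep(seq_len(n_years), each = 365), doy = doy,
             co2 = co2, W = W, Nfac = Nfac, npp = npp,
             degree_days = rep(cumsum(rep(10, 365)), n_years))
}

expect_valid_alloc <- function(a) {
  expect_s3_class(a, "allocation_vector")
  expect_true(all(a >= 0 & a <= 1))
  expect_equal(sum(a), 1, tolerance = 1e-9)
}
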