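test_that("annual-record CSVs round-trip losslessly and reject bad files", {
  scn <- quick_scenario(noise_cv = 0.05, seed = 6)
  obs <- generate_observations(scn, fixed_scheme(allocation_vector(0.3, 0.5, 0.2)),
                               default_turnover(), "ambient")
  rec <- obs$records
  attr(rec, "run_id") <- NULL
  path <- file.path(tempdir(), "annual.csv")
  write_annual_records(rec, path)
  back <- read_annual_records(path)
  expect_equal(back, rec, tolerance = 1e-12)
  # missing values survive as empty fields
  rec2 <- rec; rec2$lai_max[2] <- NA
  write_annual_records(rec2, path)
  expect_true(is.na(read_annual_records(path)$lai_max[2]))
  # duplicate years are named in the error
  dup <- rbind(rec, rec[1, ])
  expect_error(write_annual_records(dup, path), class = "allocsim_schema_error")
  # non-numeric cells are located
  txt <- readLines(path)
  txt[3] <- sub("^([^,]*),[^,]*", "\\1,oops", txt[3])
  writeLines(txt, path)
  err <- tryCatch(read_annual_records(path), error = identity)
  expect_s3_class(err, "allocsim_schema_error")
  expect_match(conditionMessage(err), "row 2")
  # unknown columns are rejected
  bad <- rec; names(bad)[2] <- "npp_leaf"
  path2 <- file.path(tempdir(), "annual2.csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_annual_records(path2), class = "allocsim_schema_error")
})

test_that("re-diagnosing an exported table reproduces the diagnostics", {
  scn <- quick_scenario(noise_cv = 0.05, seed = 12)
  exp <- run_experiment(scheme = make_scheme("isam", list()),
                        turnover = default_turnover(), scenario = scn)
  path <- file.path(tempdir(), "amb.csv")
  rec <- exp$records$ambient
  attr(rec, "run_id") <- NULL
  write_annual_records(rec, path)
  d2 <- diagnose_records(read_annual_records(path))
  expect_equal(d2$mean_fractions, exp$diagnostics$ambient$mean_fractions,
               tolerance = 1e-12)
  expect_equal(d2$lifespan, exp$diagnostics$ambient$lifespan, tolerance = 1e-12)
})

test_that("config files are validated with field paths and drive a full run", {
  cfg_path <- file.path(tempdir(), "exp.yaml")
  writeLines(c(
    "schema_version: 1",
    "scheme:",
    "  name: fixed",
    "  params:",
    "    base: [0.3, 0.5, 0.2]",
    "turnover: {u_f: 0.5, u_w: 0.02, u_r: 0.7}",
    "scenario: {n_years: 3, seed: 2}"
  ), cfg_path)
  exp <- run_experiment(cfg_path)
  expect_s3_class(exp, "face_experiment")
  expect_equal(nrow(exp$records$ambient), 3)

  writeLines(c("schema_version: 1", "scheme: {name: fixed}",
               "turnover: {u_f: 0.5, u_w: 0.02}",
               "scenario: {n_years: 3}"), cfg_path)
  err <- tryCatch(run_experiment(cfg_path), error = identity)
  expect_s3_class(err, "allocsim_config_error")
  expect_match(conditionMessage(err), "turnover.u_r", fixed = TRUE)
  expect_error(make_scheme("nonesuch"), class = "allocsim_config_error")
})

test_that("re-running the same configuration and seed reproduces every output", {
  args <- list(scheme = make_scheme("teco", list()),
               turnover = default_turnover(),
               scenario = quick_scenario(noise_cv = 0.05, seed = 33))
  e1 <- do.call(run_experiment, args)
  e2 <- do.call(run_experiment, args)
  expect_identical(e1$records, e2$records)
  expect_identical(e1$responses, e2$responses)
  # and a different seed changes the noisy outputs
  e3 <- do.call(run_experiment, c(args["scheme"], args["turnover"],
                                  list(scenario = quick_scenario(noise_cv = 0.05,
                                                                 seed = 34))))
  expect_false(identical(e1$records$ambient, e3$records$ambient))
})

test_that("experiment outputs are written as the documented file bundle", {
  outdir <- file.path(tempdir(), "expout")
  unlink(outdir, recursive = TRUE)
  exp <- run_experiment(scheme = fixed_scheme(allocation_vector(0.3, 0.5, 0.2)),
                        turnover = default_turnover(),
                        scenario = quick_scenario(seed = 2), outdir = outdir)
  expect_true(all(file.exists(file.path(outdir,
    c("annual_ambient.csv", "annual_elevated.csv", "diagnostics.csv", "report.txt")))))
  back <- read_annual_records(file.path(outdir, "annual_ambient.csv"))
  expect_equal(back$npp_w, exp$records$ambient$npp_w, tolerance = 1e-12)
})

test_that("model-object methods expose coefficients, summaries and replicates", {
  exp <- run_experiment(scheme = fixed_scheme(allocation_vector(0.3, 0.5, 0.2)),
                        turnover = default_turnover(),
                        scenario = quick_scenario(noise_cv = 0.02, seed = 2))
  cf <- coef(exp)
  expect_equal(dim(cf), c(4, 2))
  expect_equal(colnames(cf), c("ambient", "elevated"))
  expect_output(print(exp), "NPP response ratio")
  expect_output(summary(exp), "Mean allocation fractions")
  reps <- simulate(exp, nsim = 2)
  expect_length(reps, 2)
  expect_false(identical(reps[[1]]$records$ambient, reps[[2]]$records$ambient))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(exp))
})
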