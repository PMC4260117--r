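## Annual-record I/O ---------------------------------------------------------

#' Validate an annual-record table
#'
#' Checks the documented column set, numeric content and unique years;
#' raises a schema error naming the offending row/column otherwise.
#'
#' @param records A data frame of annual records.
#' @return The records, invisibly, if valid.
#' @export
validate_annual_records <- function(records) {
  if (!is.data.frame(records)) schema_error("annual records must be a data frame")
  if (!identical(names(records), annual_record_cols))
    schema_error(paste0(
      "annual records must have exactly the columns ",
      paste(annual_record_cols, collapse = ","),
      "; got ", paste(names(records), collapse = ",")))
  for (col in annual_record_cols) {
    if (!is.numeric(records[[col]]))
      schema_error(sprintf("annual records: column '%s' is not numeric", col))
  }
  dup <- records$year[duplicated(records$year)]
  if (length(dup))
    schema_error(sprintf("annual records: duplicate year %s", dup[1]))
  bad <- which(records[setdiff(annual_record_cols, "year")] < 0, arr.ind = TRUE)
  if (nrow(bad))
    schema_error(sprintf("annual records: negative value at row %d, column '%s'",
                         bad[1, 1], setdiff(annual_record_cols, "year")[bad[1, 2]]))
  invisible(records)
}

#' Read and write annual-record CSV files
#'
#' The dialect is a UTF-8 CSV with header
#' `year,npp_f,npp_w,npp_r,npp_rep,litter_f,litter_w,litter_r,bmax_f,bmax_w,bmax_r,lai_max`,
#' '.' decimal, and empty fields for missing values. Units: NPP and litter
#' in kg C m-2 yr-1, biomass maxima in kg C m-2, LAI in m2 m-2. Finite
#' values round-trip losslessly.
#'
#' @param path File path.
#' @param records Table to write (validated first).
#' @return `read_annual_records()` returns the validated data frame;
#'   `write_annual_records()` returns `path` invisibly.
#' @export
read_annual_records <- function(path) {
  if (!file.exists(path)) schema_error(sprintf("no such file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), annual_record_cols))
    schema_error(paste0(path, ": header must be ",
                        paste(annual_record_cols, collapse = ",")))
  out <- raw
  for (col in annual_record_cols) {
    v <- raw[[col]]
    v[v == ""] <- NA
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      schema_error(sprintf("%s: non-numeric cell at row %d, column '%s'",
                           path, bad[1], col))
    out[[col]] <- num
  }
  validate_annual_records(out)
  out
}

#' @rdname read_annual_records
#' @export
write_annual_records <- function(records, path) {
  validate_annual_records(records)
  utils::write.csv(records, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

## Experiment configuration --------------------------------------------------

#' Read an experiment configuration file
#'
#' YAML with a versioned schema: top-level keys `schema_version` (1),
#' `scheme` (`name` + `params`), `turnover` (`u_f`, `u_w`, `u_r`),
#' `scenario` (fields of [face_scenario()]), and optional `sla` override,
#' `init` (`B_f`, `B_w`, `B_r`), `phenology`, `seed`, `outdir`. Violations
#' are reported with field paths.
#'
#' @param path Path to the YAML file.
#' @return A validated configuration list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("no such config file: %s", path))
  cfg <- yaml::read_yaml(path)
  validate_experiment_config(cfg)
}

validate_experiment_config <- function(cfg) {
  if (!is.list(cfg)) config_error("config: must be a mapping")
  if (is.null(cfg$schema_version) || cfg$schema_version != 1)
    config_error("config: schema_version must be 1")
  if (is.null(cfg$scheme$name)) config_error("config: scheme.name is required")
  if (is.null(cfg$turnover)) config_error("config: turnover is required")
  for (k in c("u_f", "u_w", "u_r"))
    if (is.null(cfg$turnover[[k]]))
      config_error(sprintf("config: turnover.%s is required", k))
  if (is.null(cfg$scenario)) config_error("config: scenario is required")
  cfg
}

## Paired-treatment experiment driver ----------------------------------------

#' Run a paired ambient/elevated allocation experiment
#'
#' The package's main entry point: simulates the same stand under ambient
#' and elevated CO2 forcing that share everything except the CO2-dependent
#' terms, computes the full diagnostics for both treatments, and the
#' between-treatment responses (CO2 response ratios of NPP, peak foliage
#' biomass, LAI and canopy SLA; per-component allocation responses; the NPP
#' retention rate). Deterministic given the configuration and seed.
#'
#' @param config A configuration list (see [read_experiment_config()]) or a
#'   path to a YAML config file. Programmatic callers can instead pass the
#'   pieces directly via `scheme`, `turnover` and `scenario`.
#' @param scheme,turnover,scenario Optional direct arguments overriding the
#'   config: an allocation scheme object, a [turnover_vector()], a
#'   [face_scenario()].
#' @param seed Optional seed overriding the scenario's.
#' @param outdir Optional directory: annual records per treatment, the
#'   diagnostics CSV and a text report are written there.
#' @param init Initial [pool_state()].
#' @param phenology Optional [phenology_params()].
#' @param mortality_events Passed to [simulate_stand()].
#' @return An object of class `"face_experiment"`; see
#'   [print.face_experiment()], [summary.face_experiment()],
#'   [coef.face_experiment()], [plot.face_experiment()].
#' @examples
#' exp <- run_experiment(
#'   scheme = fixed_scheme(allocation_vector(0.3, 0.5, 0.2)),
#'   turnover = turnover_vector(0.5, 0.02, 0.7),
#'   scenario = face_scenario(n_years = 4, seed = 1))
#' coef(exp)
#' @export
run_experiment <- function(config = NULL, scheme = NULL, turnover = NULL,
                           scenario = NULL, seed = NULL, outdir = NULL,
                           init = pool_state(B_f = 0.1, B_w = 5, B_r = 0.1),
                           phenology = NULL, mortality_events = NULL) {
  if (is.character(config)) config <- read_experiment_config(config)
  if (!is.null(config)) {
    config <- validate_experiment_config(config)
    if (is.null(scheme))
      scheme <- make_scheme(config$scheme$name, config$scheme$params %||% list())
    if (is.null(turnover)) turnover <- do.call(turnover_vector, config$turnover)
    if (is.null(scenario)) scenario <- do.call(face_scenario, config$scenario)
    if (is.null(seed) && !is.null(config$seed)) seed <- config$seed
    if (is.null(outdir) && !is.null(config$outdir)) outdir <- config$outdir
    if (!is.null(config$init) && missing(init)) init <- do.call(pool_state, config$init)
    if (!is.null(config$phenology) && is.null(phenology))
      phenology <- do.call(phenology_params, config$phenology)
  }
  if (is.null(scheme) || is.null(turnover) || is.null(scenario))
    config_error("run_experiment: scheme, turnover and scenario are all required")
  if (!is.null(seed)) scenario$seed <- as.integer(seed)

  runs <- lapply(c(ambient = "ambient", elevated = "elevated"), function(trt)
    generate_observations(scenario, scheme, turnover, trt,
                          phenology = phenology, init = init,
                          mortality_events = mortality_events))
  diag <- lapply(runs, function(r) diagnose_records(r$records))

  amb <- runs$ambient$records; ele <- runs$elevated$records
  npp_tot <- function(r) r$npp_f + r$npp_w + r$npp_r + r$npp_rep
  responses <- list(
    npp_ratio = co2_response_ratio(npp_tot(ele), npp_tot(amb)),
    foliage_biomass_ratio = co2_response_ratio(ele$bmax_f, amb$bmax_f),
    lai_ratio = co2_response_ratio(ele$lai_max, amb$lai_max),
    sla_ratio = co2_response_ratio(canopy_sla(ele$lai_max, ele$bmax_f),
                                   canopy_sla(amb$lai_max, amb$bmax_f)),
    alloc_response = {
      fa <- allocation_fractions(amb); fe <- allocation_fractions(ele)
      data.frame(year = fa$year,
                 d_a_f = fe$a_f - fa$a_f, d_a_w = fe$a_w - fa$a_w,
                 d_a_r = fe$a_r - fa$a_r, d_a_rep = fe$a_rep - fa$a_rep)
    },
    ## same response on the simulator's true (noise-free) coefficients
    alloc_response_true = {
      ta <- runs$ambient$ledger$alloc; te <- runs$elevated$ledger$alloc
      data.frame(year = ta$year,
                 d_a_f = te$a_f - ta$a_f, d_a_w = te$a_w - ta$a_w,
                 d_a_r = te$a_r - ta$a_r, d_a_rep = te$a_rep - ta$a_rep)
    },
    npp_retention = npp_retention(
      sum(npp_tot(amb)), sum(npp_tot(ele)),
      diag$ambient$biomass_increment, diag$elevated$biomass_increment),
    ## retention on the simulator's true carbon ledger (no observation
    ## noise): live-biomass change over cumulative NPP, per treatment
    npp_retention_true = {
      tr_a <- runs$ambient$ledger$truth; tr_e <- runs$elevated$ledger$truth
      d_tr <- function(tr) {
        b <- tr$bmax_f + tr$bmax_w + tr$bmax_r
        b[length(b)] - b[1]
      }
      npp_retention(sum(npp_tot(tr_a)), sum(npp_tot(tr_e)),
                    d_tr(tr_a), d_tr(tr_e))
    }
  )
  out <- list(scheme = scheme, turnover = turnover, scenario = scenario,
              records = list(ambient = amb, elevated = ele),
              ledgers = list(ambient = runs$ambient$ledger,
                             elevated = runs$elevated$ledger),
              runs = list(ambient = runs$ambient$run, elevated = runs$elevated$run),
              diagnostics = diag, responses = responses,
              flags = unique(c(runs$ambient$run$flags, runs$elevated$run$flags)))
  class(out) <- "face_experiment"
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

write_experiment <- function(x, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (trt in c("ambient", "elevated"))
    write_annual_records(x$records[[trt]],
                         file.path(outdir, paste0("annual_", trt, ".csv")))
  dd <- data.frame(
    treatment = rep(c("ambient", "elevated"), each = 4),
    component = rep(c("f", "w", "r", "rep"), 2),
    mean_fraction = c(x$diagnostics$ambient$mean_fractions,
                      x$diagnostics$elevated$mean_fractions),
    lifespan = c(x$diagnostics$ambient$lifespan, NA,
                 x$diagnostics$elevated$lifespan, NA)
  )
  utils::write.csv(dd, file.path(outdir, "diagnostics.csv"), row.names = FALSE)
  rpt <- file.path(outdir, "report.txt")
  con <- file(rpt, open = "wt")
  on.exit(close(con))
  sink(con); on.exit(sink(), add = TRUE, after = FALSE)
  print(summary(x))
  invisible(outdir)
}

## Methods -------------------------------------------------------------------

#' @export
print.face_experiment <- function(x, ...) {
  cat("Paired FACE allocation experiment\n")
  cat(sprintf("  scheme: %s (%s allocation)\n", class(x$scheme)[1],
              scheme_timestep(x$scheme)))
  cat(sprintf("  %d years, CO2 %g -> %g umol mol-1, seed %d\n",
              x$scenario$n_years, x$scenario$co2_ambient,
              x$scenario$co2_elevated, x$scenario$seed))
  cat(sprintf("  NPP response ratio: %.3f; NPP retention: %.1f%%\n",
              x$responses$npp_ratio, x$responses$npp_retention))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a paired FACE experiment
#'
#' @param object A `"face_experiment"`.
#' @param ... Unused.
#' @return The object, invisibly, after printing mean allocation fractions
#'   per treatment, allocation responses, response ratios, lifespans and the
#'   NPP retention rate.
#' @export
summary.face_experiment <- function(object, ...) {
  x <- object
  print(x)
  cat("\nMean allocation fractions (ambient | elevated | response):\n")
  fa <- x$diagnostics$ambient$mean_fractions
  fe <- x$diagnostics$elevated$mean_fractions
  m <- cbind(ambient = fa, elevated = fe, response = fe - fa)
  print(round(m, 4))
  cat("\nMean lifespans, yr (ambient | elevated):\n")
  print(round(cbind(ambient = x$diagnostics$ambient$lifespan,
                    elevated = x$diagnostics$elevated$lifespan), 2))
  cat(sprintf("\nResponse ratios: NPP %.3f, foliage biomass %.3f, LAI %.3f, SLA %.3f\n",
              x$responses$npp_ratio, x$responses$foliage_biomass_ratio,
              x$responses$lai_ratio, x$responses$sla_ratio))
  invisible(x)
}

#' Mean allocation coefficients of an experiment
#'
#' @param object A `"face_experiment"`.
#' @param ... Unused.
#' @return Matrix of mean allocation fractions, treatments in columns.
#' @export
coef.face_experiment <- function(object, ...) {
  cbind(ambient = object$diagnostics$ambient$mean_fractions,
        elevated = object$diagnostics$elevated$mean_fractions)
}

#' Plot annual allocation fractions of both treatments
#'
#' Base-graphics time series of the annual foliage, wood and root fractions,
#' solid for ambient and dashed for elevated.
#'
#' @param x A `"face_experiment"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.face_experiment <- function(x, ...) {
  fa <- allocation_fractions(x$records$ambient)
  fe <- allocation_fractions(x$records$elevated)
  cols <- c("forestgreen", "sienna", "steelblue")
  graphics::matplot(fa$year, cbind(fa$a_f, fa$a_w, fa$a_r,
                                   fe$a_f, fe$a_w, fe$a_r),
                    type = "l", lty = rep(c(1, 2), each = 3),
                    col = rep(cols, 2), xlab = "year",
                    ylab = "allocation fraction", ...)
  graphics::legend("topright", bty = "n",
                   legend = c("foliage", "wood", "fine root"),
                   col = cols, lty = 1)
  invisible(x)
}

#' Re-run an experiment under new seeds
#'
#' Regenerates the whole paired experiment (forcing noise and observation
#' noise) under `nsim` consecutive seeds, as replicate realisations of the
#' same study conditions.
#'
#' @param object A `"face_experiment"`.
#' @param nsim Number of replicate experiments.
#' @param seed First seed; replicate `i` uses `seed + i - 1`.
#' @param ... Unused.
#' @return List of `"face_experiment"` objects, length `nsim`.
#' @export
simulate.face_experiment <- function(object, nsim = 1, seed = NULL, ...) {
  seed0 <- if (is.null(seed)) object$scenario$seed + 1L else as.integer(seed)
  lapply(seq_len(nsim), function(i)
    run_experiment(scheme = object$scheme, turnover = object$turnover,
                   scenario = object$scenario, seed = seed0 + i - 1L))
}
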