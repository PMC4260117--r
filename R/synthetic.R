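## Synthetic FACE-experiment generator ---------------------------------------

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

substream <- function(seed, treatment, purpose) {
  k <- match(treatment, c("ambient", "elevated"))
  p <- match(purpose, c("forcing", "observation"))
  ((seed %% 100000L) * 10007L + k * 1009L + p * 101L) %% 2147483647L
}

#' Scenario for a synthetic paired FACE experiment
#'
#' Defines the study conditions of a desk-scale free-air CO2 enrichment
#' emulation: paired ambient/elevated forcing with a logarithmic CO2
#' fertilisation of NPP, optional progressive nitrogen limitation under
#' elevated CO2, optional drought years (with partial stress relief under
#' elevated CO2, the water-savings effect), an optional SLA reduction under
#' elevated CO2, and multiplicative lognormal noise.
#'
#' @param n_years Experiment length (>= 2).
#' @param co2_ambient,co2_elevated Treatment CO2 (umol mol-1), elevated >
#'   ambient.
#' @param beta CO2 fertilisation coefficient: potential NPP is multiplied by
#'   `1 + beta * log(co2 / co2_ambient)`.
#' @param npp0 Baseline potential NPP (kg C m-2 yr-1).
#' @param n_decline Linear per-year decrease of the nitrogen scalar under
#'   the elevated treatment (progressive N limitation); ambient keeps
#'   `Nfac = 1`.
#' @param drought_years Integer years (1-based) in which water availability
#'   drops to `drought_w` during midseason (days 160-250).
#' @param drought_w Water scalar in drought years (ambient treatment).
#' @param drought_mitigation_eco2 Fraction of drought stress relieved under
#'   elevated CO2 (stomatal water savings): `W_e = 1 - (1 - W_a) * (1 -
#'   mitigation)`.
#' @param w_ambient,w_elevated Baseline water scalars outside drought.
#' @param stress_exponent Exponent of the stress response of NPP,
#'   `g(x) = x^stress_exponent`.
#' @param sla Specific leaf area (m2 kg-1 C) of the ambient canopy.
#' @param sla_reduction_eco2 Fractional SLA decrease under elevated CO2.
#' @param noise_cv Coefficient of variation of the multiplicative lognormal
#'   noise (interannual NPP variability and observation error).
#' @param deciduous Simulate a deciduous canopy (seasonal NPP confined to
#'   the growing season, phenology phases active).
#' @param seed Integer seed; all randomness derives from per-treatment
#'   substreams of it, so ambient/elevated runs are paired and reproducible.
#' @return List of class `"face_scenario"`.
#' @export
face_scenario <- function(n_years = 10, co2_ambient = 380, co2_elevated = 580,
                          beta = 0.6, npp0 = 0.8, n_decline = 0,
                          drought_years = integer(), drought_w = 0.4,
                          drought_mitigation_eco2 = 0.3,
                          w_ambient = 1, w_elevated = 1,
                          stress_exponent = 0.5,
                          sla = 8, sla_reduction_eco2 = 0,
                          noise_cv = 0, deciduous = FALSE, seed = 1L) {
  if (n_years < 2) config_error("face_scenario: n_years must be >= 2")
  if (co2_elevated <= co2_ambient)
    config_error("face_scenario: co2_elevated must exceed co2_ambient")
  if (noise_cv < 0) config_error("face_scenario: noise_cv must be >= 0")
  if (sla_reduction_eco2 < 0 || sla_reduction_eco2 >= 1)
    config_error("face_scenario: sla_reduction_eco2 must lie in [0, 1)")
  structure(list(
    n_years = as.integer(n_years), co2_ambient = co2_ambient,
    co2_elevated = co2_elevated, beta = beta, npp0 = npp0,
    n_decline = n_decline, drought_years = as.integer(drought_years),
    drought_w = drought_w, drought_mitigation_eco2 = drought_mitigation_eco2,
    w_ambient = w_ambient, w_elevated = w_elevated,
    stress_exponent = stress_exponent, sla = sla,
    sla_reduction_eco2 = sla_reduction_eco2, noise_cv = noise_cv,
    deciduous = deciduous, seed = as.integer(seed)
  ), class = "face_scenario")
}

#' Pine-plantation-like scenario preset
#'
#' Evergreen canopy, +200 umol mol-1 CO2 step, a midseason drought year, a
#' modest SLA reduction under elevated CO2.
#' @param ... Overrides passed to [face_scenario()].
#' @export
face_scenario_duke <- function(...) {
  defaults <- list(n_years = 10, co2_ambient = 380, co2_elevated = 580,
                   npp0 = 0.8, deciduous = FALSE, drought_years = 7L,
                   drought_w = 0.4, sla = 8, sla_reduction_eco2 = 0.064,
                   noise_cv = 0.05)
  do.call(face_scenario, utils::modifyList(defaults, list(...)))
}

#' Deciduous-plantation-like scenario preset
#'
#' Deciduous canopy, 547 vs 395 umol mol-1, progressive N limitation under
#' elevated CO2, a modest SLA reduction.
#' @param ... Overrides passed to [face_scenario()].
#' @export
face_scenario_ornl <- function(...) {
  defaults <- list(n_years = 11, co2_ambient = 395, co2_elevated = 547,
                   npp0 = 0.9, deciduous = TRUE, n_decline = 0.03,
                   sla = 15, sla_reduction_eco2 = 0.053, noise_cv = 0.05)
  do.call(face_scenario, utils::modifyList(defaults, list(...)))
}

seasonal_weight <- function(doy, deciduous) {
  if (deciduous) {
    w <- pmax(0, sin(pi * (doy - 90) / 210))
    w[doy < 90 | doy > 300] <- 0
  } else {
    w <- 1 + 0.6 * sin(2 * pi * (doy - 105) / 365)
  }
  w / mean(w)
}

degree_day_series <- function(doy) {
  temp <- pmax(0, 15 * sin(pi * (doy - 60) / 245))
  temp[doy < 60 | doy > 305] <- 0
  cumsum(temp)
}

#' Generate daily forcing for one treatment
#'
#' Daily environment and NPP series over the scenario years. Potential NPP
#' is `npp0 * (1 + beta * log(co2/co2_ambient))`, modulated by the stress
#' responses `W^g` and `Nfac^g`, a seasonal shape (confined to the growing
#' season for deciduous canopies), and a lognormal annual multiplier with
#' CV `noise_cv` (mean 1). Same seed, same table, always.
#'
#' @param scn A [face_scenario()].
#' @param treatment `"ambient"` or `"elevated"`.
#' @return Data frame with columns `year`, `doy`, `co2`, `W`, `Nfac`, `npp`
#'   (kg C m-2 yr-1) and `degree_days`; attribute `treatment`.
#' @export
generate_forcing <- function(scn, treatment = c("ambient", "elevated")) {
  treatment <- match.arg(treatment)
  elevated <- treatment == "elevated"
  doy <- rep(1:365, scn$n_years)
  year <- rep(seq_len(scn$n_years), each = 365)
  co2 <- if (elevated) scn$co2_elevated else scn$co2_ambient
  fert <- 1 + scn$beta * log(co2 / scn$co2_ambient)

  w_base <- if (elevated) scn$w_elevated else scn$w_ambient
  W <- rep(w_base, length(doy))
  if (length(scn$drought_years)) {
    w_dr <- if (elevated)
      1 - (1 - scn$drought_w) * (1 - scn$drought_mitigation_eco2)
    else scn$drought_w
    dr <- year %in% scn$drought_years & doy >= 160 & doy <= 250
    W[dr] <- pmin(W[dr], w_dr)
  }
  Nfac <- if (elevated) pmax(0, 1 - scn$n_decline * (year - 1)) else rep(1, length(doy))

  eps_y <- if (scn$noise_cv > 0) {
    sdlog <- sqrt(log(1 + scn$noise_cv^2))
    with_seed(substream(scn$seed, treatment, "forcing"),
              stats::rlnorm(scn$n_years, -sdlog^2 / 2, sdlog))
  } else rep(1, scn$n_years)

  season <- seasonal_weight(1:365, scn$deciduous)
  g <- scn$stress_exponent
  npp <- scn$npp0 * fert * (W^g) * (Nfac^g) * season[doy] * eps_y[year]
  out <- data.frame(year = year, doy = doy, co2 = co2, W = W, Nfac = Nfac,
                    npp = npp, degree_days = rep(degree_day_series(1:365), scn$n_years))
  attr(out, "treatment") <- treatment
  out
}

#' Generate an observation-style table and its truth ledger
#'
#' Runs the stand simulator under [generate_forcing()], aggregates to
#' annual records, then applies multiplicative lognormal observation noise
#' (CV `noise_cv`, mean 1) independently per year to each NPP and litter
#' component. The annual-maximum foliage biomass and LAI receive a shared
#' multiplier per year (leaf area is derived from the same canopy sample as
#' leaf mass), wood and root maxima independent ones. Under the elevated
#' treatment the canopy SLA is reduced by `sla_reduction_eco2`, which both
#' feeds back on simulated LAI and shows up in the observations. The truth
#' ledger records the noise-free table and the generating coefficients for
#' recovery testing.
#'
#' @param scn A [face_scenario()].
#' @param scheme An allocation scheme.
#' @param turnover A [turnover_vector()].
#' @param treatment `"ambient"` or `"elevated"`.
#' @param phenology Optional [phenology_params()]; defaults to a deciduous
#'   clock when the scenario is deciduous.
#' @param init Initial [pool_state()].
#' @param mortality_events Passed to [simulate_stand()].
#' @return List with `records` (the noisy annual table, `run_id` attribute
#'   set), `ledger` (truth: noise-free records, true allocation fractions,
#'   turnover rates, SLA), and `run` (the full `"stand_run"`).
#' @export
generate_observations <- function(scn, scheme, turnover,
                                  treatment = c("ambient", "elevated"),
                                  phenology = NULL,
                                  init = pool_state(B_f = 0.1, B_w = 5, B_r = 0.1),
                                  mortality_events = NULL) {
  treatment <- match.arg(treatment)
  forcing <- generate_forcing(scn, treatment)
  sla_trt <- scn$sla *
    (1 - if (treatment == "elevated") scn$sla_reduction_eco2 else 0)
  if (is.null(phenology) && scn$deciduous) {
    ## biome maximum LAI of the order of the achievable peak: roughly a
    ## third of a year's NPP ends up in foliage at the given SLA
    phenology <- phenology_params(deciduous = TRUE,
                                  lai_max = 0.35 * scn$sla * scn$npp0)
  }
  run <- simulate_stand(scheme, turnover, forcing, sla = sla_trt, init = init,
                        phenology = phenology, mortality_events = mortality_events,
                        keep_daily = FALSE)
  truth <- run$annual
  obs <- truth
  if (scn$noise_cv > 0) {
    sdlog <- sqrt(log(1 + scn$noise_cv^2))
    ny <- nrow(truth)
    obs <- with_seed(substream(scn$seed, treatment, "observation"), {
      mult <- function() stats::rlnorm(ny, -sdlog^2 / 2, sdlog)
      for (col in c("npp_f", "npp_w", "npp_r", "npp_rep",
                    "litter_f", "litter_w", "litter_r", "bmax_w", "bmax_r"))
        obs[[col]] <- obs[[col]] * mult()
      canopy_mult <- mult()
      obs$bmax_f <- obs$bmax_f * canopy_mult
      obs$lai_max <- obs$lai_max * canopy_mult
      obs
    })
  }
  run_id <- paste(scn$seed, treatment, scn$n_years, sep = ":")
  attr(obs, "run_id") <- run_id
  ledger <- list(run_id = run_id, treatment = treatment,
                 truth = truth, alloc = run$alloc_annual,
                 turnover = turnover,
                 ## diagnostic-scale truth: what the turnover diagnostic
                 ## yields on the noise-free table (bmax-based, so it can
                 ## differ from u by within-year biomass variation)
                 turnover_rates = vapply(c(f = "f", w = "w", r = "r"),
                                         function(k) turnover_lifespan(truth, k)$mean_rate,
                                         numeric(1)),
                 sla = sla_trt)
  list(records = obs, ledger = ledger, run = run)
}

#' Recovery of generator truth by the diagnostics
#'
#' Compares the diagnostics computed from a (possibly noisy) observation
#' table against the truth ledger of the same run: mean allocation
#' fractions, per-component mean turnover rates, and canopy SLA.
#'
#' @param records Observation table from [generate_observations()].
#' @param ledger Matching truth ledger.
#' @return Data frame with columns `metric`, `truth`, `recovered`, `bias`.
#' @export
recovery_report <- function(records, ledger) {
  validate_annual_records(records)
  if (!identical(attr(records, "run_id"), ledger$run_id))
    invalid_argument("recovery_report: records and ledger come from different runs")
  fr <- attr(allocation_fractions(records), "mean")
  truth_fr <- colMeans(ledger$alloc[, c("a_f", "a_w", "a_r", "a_rep")], na.rm = TRUE)
  turn_rec <- vapply(c(f = "f", w = "w", r = "r"),
                     function(k) turnover_lifespan(records, k)$mean_rate, numeric(1))
  sla_rec <- mean(canopy_sla(records$lai_max, records$bmax_f))
  out <- data.frame(
    metric = c("a_f", "a_w", "a_r", "a_rep", "u_f", "u_w", "u_r", "sla"),
    truth = c(truth_fr, unname(ledger$turnover_rates), ledger$sla),
    recovered = c(fr, unname(turn_rec), sla_rec)
  )
  out$bias <- out$recovered - out$truth
  out
}
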