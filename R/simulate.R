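## Stand simulator -----------------------------------------------------------

#' Run a stand simulation under prescribed forcing
#'
#' Integrates the pool dynamics with explicit Euler at the forcing's daily
#' resolution, letting the supplied allocation scheme partition each step's
#' NPP (daily schemes) or each year's accumulated NPP (annual schemes). LAI
#' is diagnosed as `sla * B_f` throughout. Deciduous phenology, when
#' enabled, advances the phase clock each day and adds an autumn shedding
#' flux to foliage turnover during senescence.
#'
#' @param scheme An allocation scheme (see [make_scheme()]).
#' @param turnover A [turnover_vector()].
#' @param forcing Data frame with one row per simulated day and columns
#'   `year`, `doy`, `co2`, `W`, `Nfac`, `npp` (kg C m-2 yr-1) and
#'   `degree_days` (see [generate_forcing()]).
#' @param sla Specific leaf area (m2 kg-1 C) converting foliage C to LAI.
#' @param init Initial [pool_state()].
#' @param phenology A [phenology_params()] list, or `NULL` for evergreen.
#' @param mortality_events Optional data frame with columns `year` and
#'   `fraction`: that fraction of wood biomass is removed (to wood litter)
#'   on day 1 of the year, emulating exogenous mortality.
#' @param dt Time step in years (default one day).
#' @param keep_daily Keep the daily trajectory (set `FALSE` to save memory
#'   in large sweeps).
#' @return List of class `"stand_run"` with elements `annual` (the annual
#'   observation-style records, see [write_annual_records()] for the
#'   columns), `daily` (trajectory data frame or `NULL`), `init_state`,
#'   `final_state`, `flags`, and `alloc_annual` (true NPP-weighted annual
#'   allocation fractions).
#' @export
simulate_stand <- function(scheme, turnover, forcing, sla,
                           init = pool_state(B_f = 0.1, B_w = 5, B_r = 0.1),
                           phenology = NULL, mortality_events = NULL,
                           dt = 1 / 365, keep_daily = TRUE) {
  req <- c("year", "doy", "co2", "W", "Nfac", "npp", "degree_days")
  miss <- setdiff(req, names(forcing))
  if (length(miss)) invalid_argument(paste("simulate_stand: forcing lacks columns:",
                                           paste(miss, collapse = ", ")))
  n <- nrow(forcing)
  years <- unique(forcing$year)
  ny <- length(years)
  annual_scheme <- identical(scheme_timestep(scheme), "annual")
  deciduous <- !is.null(phenology) && isTRUE(phenology$deciduous)
  phase <- if (deciduous) "DORMANT" else "STEADY_GROWTH"

  state <- init
  memory <- list()
  all_flags <- character()

  ## annual accumulators
  zero <- stats::setNames(numeric(ny), years)
  npp_c <- matrix(0, ny, 4, dimnames = list(years, c("f", "w", "r", "rep")))
  lit <- matrix(0, ny, 3, dimnames = list(years, c("f", "w", "r")))
  bmax <- matrix(0, ny, 3, dimnames = list(years, c("f", "w", "r")))
  lai_max_y <- zero
  acc_npp <- 0
  acc_W <- 0; acc_N <- 0; acc_co2 <- 0; acc_days <- 0

  if (keep_daily) {
    daily <- matrix(NA_real_, n, 10,
                    dimnames = list(NULL, c("B_f", "B_w", "B_r", "B_rep", "lai",
                                            "a_f", "a_w", "a_r", "a_rep", "litter_total")))
  }
  phase_trace <- if (keep_daily) character(n) else NULL

  f_year <- forcing$year; f_doy <- forcing$doy; f_co2 <- forcing$co2
  f_W <- forcing$W; f_N <- forcing$Nfac; f_npp <- forcing$npp
  f_gdd <- forcing$degree_days
  treatment_lbl <- attr(forcing, "treatment") %||% "ambient"

  yi <- 0L; cur_year <- NA
  for (i in seq_len(n)) {
    row <- list(year = f_year[i], doy = f_doy[i], co2 = f_co2[i], W = f_W[i],
                Nfac = f_N[i], npp = f_npp[i], degree_days = f_gdd[i])
    if (!identical(row$year, cur_year)) {
      cur_year <- row$year
      yi <- yi + 1L
      if (!is.null(mortality_events)) {
        ev <- mortality_events$fraction[mortality_events$year == cur_year]
        if (length(ev)) {
          shed <- sum(ev) * state[["B_w"]]
          lit[yi, "w"] <- lit[yi, "w"] + shed
          state <- pool_state(state[["B_f"]], state[["B_w"]] - shed,
                              state[["B_r"]], state[["B_rep"]])
        }
      }
    }
    env <- env_state(co2 = row$co2, W = row$W, Nfac = row$Nfac,
                     t_day = row$doy, degree_days = row$degree_days)
    lai <- sla * state[["B_f"]]
    if (deciduous)
      phase <- advance_phenology(env, lai, phenology$lai_max, phenology, phase)

    growth_day <- row$npp * dt
    if (annual_scheme) {
      acc_npp <- acc_npp + growth_day
      acc_W <- acc_W + row$W; acc_N <- acc_N + row$Nfac
      acc_co2 <- acc_co2 + row$co2; acc_days <- acc_days + 1
      alloc <- NULL
    } else if (growth_day > 0) {
      ctx <- list(pools = state, env = env, lai = lai, phase = phase,
                  growth_c = growth_day, year = yi, treatment = treatment_lbl,
                  sla = sla, turnover = turnover, dt = dt, memory = memory,
                  e_t = if (!deciduous) 1 else if (phase %in% c("LEAF_EXPANSION", "STEADY_GROWTH")) 1 else 0)
      res <- scheme_allocate(scheme, ctx)
      memory <- res$memory
      all_flags <- union(all_flags, res$flags)
      alloc <- res$alloc
    } else {
      alloc <- NULL
    }

    if (is.null(alloc)) {
      stepped <- step_pools(state, 0, allocation_vector(0, 1, 0, 0), turnover, dt)
    } else {
      stepped <- step_pools(state, row$npp, alloc, turnover, dt)
      npp_c[yi, ] <- npp_c[yi, ] + unname(alloc) * growth_day
    }
    state <- stepped$state
    extra_shed <- 0
    if (deciduous && phase == "SENESCENCE" && phenology$shed_rate > 0) {
      floor_bf <- phenology$winter_lai / sla
      extra_shed <- min(phenology$shed_rate * state[["B_f"]] * dt,
                        max(0, state[["B_f"]] - floor_bf))
      state <- pool_state(state[["B_f"]] - extra_shed, state[["B_w"]],
                          state[["B_r"]], state[["B_rep"]])
    }
    lit[yi, ] <- lit[yi, ] + c(stepped$litter_f + extra_shed,
                               stepped$litter_w, stepped$litter_r)

    ## end-of-year allocation for annual schemes (before recording maxima)
    last_of_year <- i == n || f_year[i + 1] != cur_year
    if (annual_scheme && last_of_year) {
      env_y <- env_state(co2 = acc_co2 / acc_days, W = acc_W / acc_days,
                         Nfac = acc_N / acc_days, t_day = row$doy,
                         degree_days = row$degree_days)
      ctx <- list(pools = state, env = env_y, lai = sla * state[["B_f"]],
                  phase = phase, growth_c = acc_npp, year = yi,
                  treatment = treatment_lbl,
                  sla = sla, turnover = turnover, dt = 1, memory = memory)
      res <- scheme_allocate(scheme, ctx)
      memory <- res$memory
      all_flags <- union(all_flags, setdiff(res$flags, "no_growth"))
      gains <- unname(res$alloc) * acc_npp
      npp_c[yi, ] <- npp_c[yi, ] + gains
      state <- pool_state(state[["B_f"]] + gains[1], state[["B_w"]] + gains[2],
                          state[["B_r"]] + gains[3], state[["B_rep"]] + gains[4])
      acc_npp <- 0; acc_W <- 0; acc_N <- 0; acc_co2 <- 0; acc_days <- 0
      alloc <- res$alloc
    }

    lai <- sla * state[["B_f"]]
    bmax[yi, ] <- pmax(bmax[yi, ], unname(state)[1:3])
    lai_max_y[yi] <- max(lai_max_y[yi], lai)
    if (keep_daily) {
      daily[i, ] <- c(unname(state), lai,
                      if (is.null(alloc)) rep(NA_real_, 4) else unname(alloc),
                      stepped$litter_f + extra_shed + stepped$litter_w + stepped$litter_r)
      phase_trace[i] <- phase
    }
  }

  npp_total <- rowSums(npp_c)
  annual <- data.frame(
    year = years,
    npp_f = npp_c[, "f"], npp_w = npp_c[, "w"], npp_r = npp_c[, "r"],
    npp_rep = npp_c[, "rep"],
    litter_f = lit[, "f"], litter_w = lit[, "w"], litter_r = lit[, "r"],
    bmax_f = bmax[, "f"], bmax_w = bmax[, "w"], bmax_r = bmax[, "r"],
    lai_max = unname(lai_max_y),
    row.names = NULL
  )
  alloc_annual <- data.frame(
    year = years,
    a_f = ifelse(npp_total > 0, npp_c[, "f"] / npp_total, NA_real_),
    a_w = ifelse(npp_total > 0, npp_c[, "w"] / npp_total, NA_real_),
    a_r = ifelse(npp_total > 0, npp_c[, "r"] / npp_total, NA_real_),
    a_rep = ifelse(npp_total > 0, npp_c[, "rep"] / npp_total, NA_real_),
    row.names = NULL
  )
  out <- list(
    annual = annual,
    daily = if (keep_daily) {
      d <- data.frame(year = forcing$year, doy = forcing$doy, daily)
      d$phase <- phase_trace
      d
    } else NULL,
    init_state = init, final_state = state,
    alloc_annual = alloc_annual, flags = all_flags, sla = sla
  )
  class(out) <- "stand_run"
  out
}

#' @export
print.stand_run <- function(x, ...) {
  ny <- nrow(x$annual)
  cat(sprintf("Stand simulation: %d years, final total biomass %.3f kg C m-2\n",
              ny, total_biomass(x$final_state)))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Mass-balance closure of a simulation
#'
#' Cumulative NPP must equal the change in total live biomass plus
#' cumulative litter, up to floating-point error. Returns the relative
#' closure error.
#'
#' @param run A `"stand_run"` from [simulate_stand()].
#' @return Relative error `|sum(NPP) - dB - sum(litter)| / max(sum(NPP), 1e-12)`.
#' @export
mass_balance_error <- function(run) {
  a <- run$annual
  tot_npp <- sum(a$npp_f + a$npp_w + a$npp_r + a$npp_rep)
  tot_lit <- sum(a$litter_f + a$litter_w + a$litter_r)
  dB <- total_biomass(run$final_state) - total_biomass(run$init_state)
  abs(tot_npp - dB - tot_lit) / max(tot_npp, 1e-12)
}
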