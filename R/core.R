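#' @keywords internal
#' @importFrom stats coef simulate
#' @importFrom graphics plot
"_PACKAGE"

## Condition helpers ---------------------------------------------------------

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "allocsim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

invalid_argument <- function(msg) abort(msg, "allocsim_invalid_argument")
config_error     <- function(msg) abort(msg, "allocsim_config_error")
schema_error     <- function(msg) abort(msg, "allocsim_schema_error")

#' Phenological phases of a deciduous canopy
#'
#' The four phases visited cyclically by a deciduous stand:
#' `"LEAF_EXPANSION"`, `"STEADY_GROWTH"`, `"SENESCENCE"`, `"DORMANT"`.
#' Evergreen stands remain in `"STEADY_GROWTH"`.
#'
#' @format Character vector of the four phase names, in cyclic order.
#' @export
PHENO_PHASES <- c("LEAF_EXPANSION", "STEADY_GROWTH", "SENESCENCE", "DORMANT")

## Domain types --------------------------------------------------------------

#' Live biomass pools of a stand
#'
#' Carbon in the four plant components tracked by the simulator: foliage,
#' wood (stem, branches and coarse roots lumped together), fine roots and
#' cumulative reproduction. All in kg C m-2 ground.
#'
#' @param B_f,B_w,B_r,B_rep Non-negative biomass (kg C m-2). `B_rep` is a
#'   cumulative sink: reproductive C never returns to litter here.
#' @return A named numeric vector of class `"pool_state"`.
#' @examples
#' p <- pool_state(B_f = 0.3, B_w = 8, B_r = 0.25)
#' total_biomass(p)
#' @export
pool_state <- function(B_f = 0, B_w = 0, B_r = 0, B_rep = 0) {
  x <- c(B_f = B_f, B_w = B_w, B_r = B_r, B_rep = B_rep)
  if (!all(is.finite(x))) invalid_argument("pool_state: all pools must be finite")
  if (any(x < 0)) invalid_argument("pool_state: biomass pools must be non-negative")
  structure(x, class = "pool_state")
}

#' Total live biomass
#' @param state A [pool_state()].
#' @return Sum of the four pools (kg C m-2).
#' @export
total_biomass <- function(state) unname(sum(state))

#' Allocation coefficients
#'
#' The fractions of growth carbon directed to each component in a period.
#' Each lies in \[0, 1\] and they sum to 1 (checked to 1e-9).
#'
#' @param a_f,a_w,a_r,a_rep Fractions for foliage, wood, fine roots,
#'   reproduction.
#' @return Named numeric of class `"allocation_vector"`.
#' @examples
#' allocation_vector(0.3, 0.5, 0.2)
#' @export
allocation_vector <- function(a_f, a_w, a_r, a_rep = 0) {
  a <- c(a_f = a_f, a_w = a_w, a_r = a_r, a_rep = a_rep)
  if (!all(is.finite(a))) invalid_argument("allocation_vector: fractions must be finite")
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    invalid_argument("allocation_vector: each fraction must lie in [0, 1]")
  if (abs(sum(a) - 1) > 1e-9)
    invalid_argument(sprintf(
      "allocation_vector: fractions must sum to 1 (got %.12f)", sum(a)))
  a <- pmin(pmax(a, 0), 1)
  structure(a, class = "allocation_vector")
}

#' Turnover rates and lifespans
#'
#' First-order turnover rates (yr-1) of the foliage, wood and fine-root
#' pools. The implied lifespan of a component is `1/u` (infinite when
#' `u = 0`); reproduction has no turnover.
#'
#' @param u_f,u_w,u_r Non-negative rates (yr-1).
#' @return Named numeric of class `"turnover_vector"`.
#' @examples
#' u <- turnover_vector(u_f = 0.5, u_w = 0.02, u_r = 0.7)
#' lifespans(u)
#' @export
turnover_vector <- function(u_f, u_w, u_r) {
  u <- c(u_f = u_f, u_w = u_w, u_r = u_r)
  if (!all(is.finite(u)) || any(u < 0))
    invalid_argument("turnover_vector: rates must be finite and non-negative")
  structure(u, class = "turnover_vector")
}

#' @rdname turnover_vector
#' @param u A [turnover_vector()].
#' @export
lifespans <- function(u) {
  out <- ifelse(u > 0, 1 / u, Inf)
  names(out) <- sub("^u_", "lifespan_", names(u))
  out
}

#' Environmental drivers read by allocation schemes
#'
#' @param co2 CO2 concentration (umol mol-1), positive.
#' @param W Soil water availability scalar in \[0, 1\].
#' @param Nfac Nitrogen availability scalar in \[0, 1\].
#' @param L Light availability scalar in \[0, 1\] (1 = no shading).
#' @param t_day Day of year (1-based, no leap days).
#' @param degree_days Accumulated temperature sum since 1 January (degC d).
#' @return Named list of class `"env_state"`.
#' @export
env_state <- function(co2, W = 1, Nfac = 1, L = 1, t_day = 1, degree_days = 0) {
  if (!is.finite(co2) || co2 <= 0) invalid_argument("env_state: co2 must be positive")
  for (nm in c("W", "Nfac", "L")) {
    v <- get(nm)
    if (!is.finite(v) || v < -1e-12 || v > 1 + 1e-12)
      invalid_argument(sprintf("env_state: %s must lie in [0, 1]", nm))
  }
  structure(list(co2 = co2, W = min(max(W, 0), 1), Nfac = min(max(Nfac, 0), 1),
                 L = min(max(L, 0), 1), t_day = t_day, degree_days = degree_days),
            class = "env_state")
}

## Pool stepping -------------------------------------------------------------

#' Advance the biomass pools one explicit-Euler step
#'
#' Core pool dynamics: each structural pool gains its allocation share of NPP
#' and loses first-order turnover, `B_i' = B_i + (a_i npp - u_i B_i) dt`;
#' reproduction accumulates without turnover. Shed carbon is returned as
#' litter so that each step conserves mass exactly:
#' `total(B') - total(B) = npp dt - sum(litter)`.
#'
#' @param state A [pool_state()].
#' @param npp NPP available for growth (kg C m-2 yr-1), non-negative.
#' @param alloc An [allocation_vector()].
#' @param turnover A [turnover_vector()].
#' @param dt Time step (yr), positive; `dt * u_i` must stay below 1 for every
#'   component (explicit-Euler stability guard).
#' @return List with elements `state` (the updated [pool_state()]) and
#'   `litter_f`, `litter_w`, `litter_r` (kg C m-2 shed this step).
#' @examples
#' s <- pool_state(B_w = 10)
#' step_pools(s, npp = 1, alloc = allocation_vector(0.3, 0.5, 0.2),
#'            turnover = turnover_vector(0.5, 0.02, 0.7), dt = 1 / 365)
#' @export
step_pools <- function(state, npp, alloc, turnover, dt) {
  if (!is.finite(npp) || npp < 0) invalid_argument("step_pools: npp must be non-negative")
  if (!is.finite(dt) || dt <= 0) invalid_argument("step_pools: dt must be positive")
  bad <- which(dt * turnover >= 1)
  if (length(bad))
    abort(sprintf(
      "step_pools: dt * %s = %.3f >= 1; reduce dt or the turnover rate",
      names(turnover)[bad[1]], dt * turnover[[bad[1]]]),
      "allocsim_stability_error")

  litter <- unname(turnover) * unname(state)[1:3] * dt
  gain <- unname(alloc) * npp * dt
  new <- unname(state)
  new[1:3] <- new[1:3] + gain[1:3] - litter
  new[4] <- new[4] + gain[4]
  list(
    state = structure(c(B_f = new[1], B_w = new[2], B_r = new[3], B_rep = new[4]),
                      class = "pool_state"),
    litter_f = litter[1], litter_w = litter[2], litter_r = litter[3]
  )
}

## Phenology -----------------------------------------------------------------

#' Default phenology thresholds
#'
#' Budburst is triggered by an accumulated temperature sum; the canopy enters
#' steady growth once LAI reaches half the biome maximum, senescence once LAI
#' falls below 95% of that maximum after midseason, and dormancy once the
#' canopy is nearly bare.
#'
#' @param deciduous Logical; evergreen canopies stay in steady growth.
#' @param lai_max Biome maximum LAI against which the thresholds are taken.
#' @param budburst_gdd Degree-day sum (degC d) at which leaf expansion starts.
#' @param steady_frac LAI fraction of `lai_max` ending leaf expansion.
#' @param senescence_frac LAI fraction of `lai_max` below which senescence
#'   starts (only after `midseason_doy`, so the spring crossing is ignored).
#' @param midseason_doy Day of year after which the senescence trigger is
#'   armed (stands in for "after the annual LAI peak").
#' @param dormancy_frac LAI fraction of `lai_max` below which the stand is
#'   dormant.
#' @param shed_rate Additional foliage turnover applied during senescence
#'   (yr-1), emulating autumn leaf drop.
#' @param winter_lai Minimum LAI retained over winter (m2 m-2); 0 for a fully
#'   bare canopy, a small positive value emulates schemes that keep an
#'   overwintering canopy.
#' @return Named list of thresholds.
#' @export
phenology_params <- function(deciduous = FALSE, lai_max = 5,
                             budburst_gdd = 150, steady_frac = 0.5,
                             senescence_frac = 0.95, midseason_doy = 180,
                             dormancy_frac = 0.05, shed_rate = 30,
                             winter_lai = 0) {
  if (lai_max <= 0) invalid_argument("phenology_params: lai_max must be positive")
  list(deciduous = deciduous, lai_max = lai_max, budburst_gdd = budburst_gdd,
       steady_frac = steady_frac, senescence_frac = senescence_frac,
       midseason_doy = midseason_doy, dormancy_frac = dormancy_frac,
       shed_rate = shed_rate, winter_lai = winter_lai)
}

#' Advance the phenological phase clock
#'
#' Deterministic phase transitions driven by LAI relative to the biome
#' maximum and by degree days: dormant stands leaf out once the budburst
#' temperature sum is reached; leaf expansion ends when LAI reaches
#' `steady_frac * lai_max`; steady growth ends when LAI falls below
#' `senescence_frac * lai_max` after midseason; senescence ends in dormancy
#' once the canopy is nearly bare. Evergreen parameterisations always return
#' `"STEADY_GROWTH"`.
#'
#' @param env An [env_state()] (supplies `t_day` and `degree_days`).
#' @param lai Current LAI (m2 m-2), non-negative.
#' @param lai_max Biome maximum LAI, positive.
#' @param params A [phenology_params()] list.
#' @param prev Previous phase, one of [PHENO_PHASES].
#' @return One of [PHENO_PHASES].
#' @export
advance_phenology <- function(env, lai, lai_max, params, prev) {
  if (!is.finite(lai_max) || lai_max <= 0)
    invalid_argument("advance_phenology: lai_max must be positive")
  if (!is.finite(lai) || lai < 0)
    invalid_argument("advance_phenology: lai must be non-negative")
  prev <- match.arg(prev, PHENO_PHASES)
  if (!isTRUE(params$deciduous)) return("STEADY_GROWTH")

  switch(prev,
    DORMANT = if (env$degree_days >= params$budburst_gdd &&
                  env$t_day <= params$midseason_doy) "LEAF_EXPANSION" else "DORMANT",
    LEAF_EXPANSION = if (lai >= params$steady_frac * lai_max) "STEADY_GROWTH" else "LEAF_EXPANSION",
    STEADY_GROWTH = if (env$t_day > params$midseason_doy &&
                        lai < params$senescence_frac * lai_max) "SENESCENCE" else "STEADY_GROWTH",
    SENESCENCE = if (lai <= params$dormancy_frac * lai_max) "DORMANT" else "SENESCENCE"
  )
}

#' @export
print.pool_state <- function(x, ...) {
  cat("Biomass pools (kg C m-2):\n")
  print(round(unclass(x), 4))
  cat("total:", round(total_biomass(x), 4), "\n")
  invisible(x)
}

#' @export
print.allocation_vector <- function(x, ...) {
  cat("Allocation coefficients:\n")
  print(round(unclass(x), 4))
  invisible(x)
}
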