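## Canopy-optimisation scheme ------------------------------------------------

#' Canopy-optimisation scheme
#'
#' LAI is chosen so that the lowest canopy layer just breaks even: light
#' decays through the canopy by Beer's law, each layer's gross C gain is
#' `a0 * co2_scalar * exp(-k_ext * LAI)` per unit leaf area, and a layer is
#' viable while that gain covers the annual leaf cost (construction plus
#' respiration, folded into `leaf_cost`). Foliage allocation in a year
#' realises the optimal LAI found for the *previous* year; the non-foliage
#' remainder is split between wood and roots at a fixed ratio, so the scheme
#' can change foliage allocation under elevated CO2 but wood and root
#' fractions only move together.
#'
#' @param k_ext Light extinction coefficient, positive.
#' @param a0 Top-of-canopy gross C gain per unit leaf area
#'   (kg C m-2 leaf yr-1), positive.
#' @param leaf_cost Annual C cost per unit leaf area (kg C m-2 leaf yr-1).
#' @param wood_root_split Fixed wood fraction of non-foliage C, in \[0, 1\].
#' @param layer_dlai LAI discretisation step (<= 0.1).
#' @param lai_cap Hard upper bound on the optimised LAI.
#' @param initial_lai LAI target used in the first simulated year (the
#'   one-year lag has no predecessor then).
#' @param co2_ref Reference CO2 (umol mol-1) at which `co2_scalar = 1`.
#' @param beta_canopy Log-response coefficient of canopy C gain to CO2:
#'   `co2_scalar = 1 + beta_canopy * log(co2 / co2_ref)`. Photosynthetic
#'   gain saturates with CO2, so this is smaller than the NPP response
#'   would suggest at the leaf level.
#' @return An allocation scheme object.
#' @examples
#' sch <- sdgvm_scheme(a0 = 2, k_ext = 0.5, leaf_cost = 0.4)
#' optimal_lai(sch)                       # close to log(2 / 0.4) / 0.5
#' @export
sdgvm_scheme <- function(k_ext = 0.5, a0 = 2.0, leaf_cost = 0.4,
                         wood_root_split = 0.7, layer_dlai = 0.01,
                         lai_cap = 10, initial_lai = 3, co2_ref = 380,
                         beta_canopy = 0.4) {
  if (any(c(k_ext, a0, leaf_cost, layer_dlai, lai_cap) <= 0))
    config_error("sdgvm_scheme: k_ext, a0, leaf_cost, layer_dlai, lai_cap must be positive")
  if (layer_dlai > 0.1) config_error("sdgvm_scheme: layer_dlai must be <= 0.1")
  if (wood_root_split < 0 || wood_root_split > 1)
    config_error("sdgvm_scheme: wood_root_split must lie in [0, 1]")
  new_scheme(list(k_ext = k_ext, a0 = a0, leaf_cost = leaf_cost,
                  wood_root_split = wood_root_split, layer_dlai = layer_dlai,
                  lai_cap = lai_cap, initial_lai = initial_lai,
                  co2_ref = co2_ref, beta_canopy = beta_canopy),
             "sdgvm_scheme", "annual")
}

#' Optimal LAI under the break-even criterion
#'
#' The largest LAI, in `layer_dlai` increments, whose deepest layer still
#' has a non-negative net C balance:
#' `a0 * co2_scalar * exp(-k_ext * LAI) >= leaf_cost`. Returns 0 when even
#' the top layer cannot pay its cost, and the configured cap when foliage
#' is effectively costless.
#'
#' @param params An [sdgvm_scheme()].
#' @param co2_scalar Multiplier on `a0` representing CO2 fertilisation of
#'   canopy C gain, positive.
#' @return Optimal LAI (m2 m-2).
#' @export
optimal_lai <- function(params, co2_scalar = 1) {
  if (!is.finite(co2_scalar) || co2_scalar <= 0)
    invalid_argument("optimal_lai: co2_scalar must be positive")
  gain0 <- params$a0 * co2_scalar
  if (gain0 <= params$leaf_cost) return(0)
  grid <- seq(0, params$lai_cap, by = params$layer_dlai)
  viable <- gain0 * exp(-params$k_ext * grid) >= params$leaf_cost
  grid[max(which(viable))]
}

#' Allocate under the canopy-optimisation scheme
#'
#' Foliage receives the C needed to realise the previous year's optimal LAI
#' (rebuilding turnover losses and closing any LAI deficit at the given
#' SLA), capped at all of NPP; the remainder is split
#' `wood_root_split : (1 - wood_root_split)` between wood and roots.
#'
#' @param prev_year_lai_target Optimal LAI carried over from the previous
#'   year (m2 m-2).
#' @param annual_npp Year's NPP (kg C m-2 yr-1), positive.
#' @param pools A [pool_state()].
#' @param params An [sdgvm_scheme()].
#' @param sla Specific leaf area (m2 kg-1 C).
#' @param u_f Foliage turnover rate (yr-1), whose annual losses must be
#'   rebuilt to hold the target LAI.
#' @return An [allocation_vector()].
#' @export
sdgvm_alloc <- function(prev_year_lai_target, annual_npp, pools, params, sla,
                        u_f = 0) {
  if (!is.finite(annual_npp) || annual_npp <= 0)
    invalid_argument("sdgvm_alloc: annual_npp must be positive")
  target_bf <- prev_year_lai_target / sla
  need <- max(0, target_bf - pools[["B_f"]]) + u_f * min(pools[["B_f"]], target_bf)
  a_f <- min(1, need / annual_npp)
  rest <- 1 - a_f
  allocation_vector(a_f, rest * params$wood_root_split,
                    rest * (1 - params$wood_root_split), 0)
}

sdgvm_co2_scalar <- function(scheme, co2) {
  max(1e-6, 1 + scheme$beta_canopy * log(co2 / scheme$co2_ref))
}

#' @export
scheme_allocate.sdgvm_scheme <- function(scheme, ctx) {
  mem <- ctx$memory
  if (is.null(mem$lai_target)) mem$lai_target <- scheme$initial_lai
  if (ctx$growth_c <= 0) {
    mem$lai_target <- optimal_lai(scheme, sdgvm_co2_scalar(scheme, ctx$env$co2))
    return(alloc_result(allocation_vector(0, 1, 0, 0), memory = mem,
                        flags = "no_growth"))
  }
  a <- sdgvm_alloc(mem$lai_target, ctx$growth_c, ctx$pools, scheme, ctx$sla,
                   u_f = ctx$turnover[["u_f"]])
  ## store this year's optimum for use next year (one-year lag)
  mem$lai_target <- optimal_lai(scheme, sdgvm_co2_scalar(scheme, ctx$env$co2))
  alloc_result(a, memory = mem)
}
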