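## Scheme-class signature presets --------------------------------------------

#' Preset paired experiments exhibiting the scheme-class CO2 signatures
#'
#' Each preset bundles a scheme, turnover rates, a noise-free scenario and
#' (where needed) a phenology clock into ready-to-run study conditions under
#' which the scheme class shows its characteristic elevated-CO2 allocation
#' response:
#'
#' * `"fixed_null"` — a pure fixed-coefficient scheme: no allocation
#'   response at all.
#' * `"phased_drought"` — fixed coefficients per phenological phase plus a
#'   drought year whose stress is partly relieved under elevated CO2: the
#'   annual wood fraction rises because the NPP enhancement peaks in the
#'   wood-heavy phase.
#' * `"functional_pnl"` — the allometric functional-balance scheme under
#'   progressive nitrogen limitation: wood fraction rises early, root
#'   fraction rises late.
#' * `"isam_deciduous"` — the light/water scheme with deciduous phases: the
#'   larger elevated canopy stays above the 95%-of-maximum LAI senescence
#'   threshold longer, so foliage allocation continues later and the annual
#'   foliage fraction rises.
#' * `"teco_water"` — the capped demand scheme with less water stress under
#'   elevated CO2 (stomatal savings): the root fraction falls.
#' * `"sdgvm_optim"` — canopy optimisation: the NPP enhancement outpaces the
#'   optimal-LAI enhancement, so the foliage fraction falls.
#'
#' @param name One of the preset names above.
#' @param seed Scenario seed (the presets are noise-free, so this only
#'   matters if noise is added via `...`).
#' @param ... Scenario overrides forwarded to [face_scenario()].
#' @return Named list of arguments for [run_experiment()].
#' @examples
#' exp <- do.call(run_experiment, signature_preset("fixed_null"))
#' max(abs(exp$responses$alloc_response_true[, -1]))  # exactly 0
#' @export
signature_preset <- function(name = c("fixed_null", "phased_drought",
                                      "functional_pnl", "isam_deciduous",
                                      "teco_water", "sdgvm_optim"),
                             seed = 1, ...) {
  name <- match.arg(name)
  scn <- function(...) face_scenario(...)
  switch(name,
    fixed_null = list(
      scheme = fixed_scheme(allocation_vector(0.3, 0.5, 0.2)),
      turnover = turnover_vector(0.5, 0.02, 0.7),
      scenario = scn(n_years = 6, npp0 = 0.8, seed = seed, ...)),
    phased_drought = list(
      scheme = fixed_scheme(
        base = allocation_vector(0.30, 0.50, 0.20),
        phase_table = list(
          LEAF_EXPANSION = allocation_vector(0.80, 0.10, 0.10),
          STEADY_GROWTH = allocation_vector(0.30, 0.50, 0.20),
          SENESCENCE = allocation_vector(0, 0.55, 0.45),
          DORMANT = allocation_vector(0, 0.55, 0.45))),
      turnover = turnover_vector(1.7, 0.02, 0.7),
      scenario = scn(n_years = 4, npp0 = 0.9, deciduous = TRUE,
                     drought_years = 3L, drought_w = 0.35,
                     drought_mitigation_eco2 = 0.4, sla = 15, seed = seed, ...),
      phenology = phenology_params(deciduous = TRUE, lai_max = 4),
      init = pool_state(B_f = 0.01, B_w = 5, B_r = 0.1)),
    functional_pnl = {
      sch <- lpj_scheme(sla = 8)
      list(scheme = sch,
           turnover = turnover_vector(0.5, 0.02, 0.7),
           scenario = scn(n_years = 10, npp0 = 0.8, n_decline = 0.05,
                          sla = 8, seed = seed, ...),
           init = lpj_initial_state(sch, lai = 3))
    },
    isam_deciduous = list(
      scheme = isam_scheme(omega = 0.5, k_ext = 0.35, deciduous = TRUE,
                           lai_max = 2.0),
      turnover = turnover_vector(3.5, 0.02, 1.0),
      scenario = scn(n_years = 6, co2_ambient = 395, co2_elevated = 547,
                     npp0 = 0.9, deciduous = TRUE, sla = 15, seed = seed, ...),
      phenology = phenology_params(deciduous = TRUE, lai_max = 2.0,
                                   steady_frac = 0.35),
      init = pool_state(B_f = 0.01, B_w = 5, B_r = 0.1)),
    teco_water = list(
      scheme = teco_scheme(),
      turnover = turnover_vector(0.5, 0.02, 0.7),
      scenario = scn(n_years = 6, npp0 = 0.8, w_ambient = 0.7,
                     w_elevated = 0.85, seed = seed, ...)),
    sdgvm_optim = list(
      scheme = sdgvm_scheme(co2_ref = 380),
      turnover = turnover_vector(0.5, 0.02, 0.7),
      scenario = scn(n_years = 6, npp0 = 0.8, seed = seed, ...))
  )
}
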