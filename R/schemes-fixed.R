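## Fixed-coefficient schemes -------------------------------------------------

#' Fixed-coefficient allocation scheme
#'
#' The simplest class of allocation model: prescribed fractions of NPP per
#' component. Two optional elaborations are supported. A `phase_table` gives
#' a different fixed vector per phenological phase, so the annual-mean
#' coefficients can respond to anything that changes the seasonal pattern of
#' NPP (the mechanism behind unintended CO2 x phenology interactions). A
#' `treatment_override` replaces the coefficients under the elevated
#' treatment from `override_start_year` onwards, emulating models whose
#' coefficients were re-fitted per treatment; the default start in year 2
#' reflects deciduous parameterisations in which growth follows the previous
#' year's productivity.
#'
#' @param base An [allocation_vector()] used when no phase entry applies.
#' @param phase_table Optional named list mapping phase names (a subset of
#'   [PHENO_PHASES]) to [allocation_vector()]s. Phases without an entry fall
#'   back to `base`; with `strict_phases = TRUE` a missing entry is an error.
#' @param treatment_override Optional [allocation_vector()] applied under the
#'   elevated treatment from `override_start_year` on.
#' @param override_start_year First simulation year (1-based) in which the
#'   override applies.
#' @param strict_phases Require `phase_table` to cover every phase queried.
#' @param timestep `"daily"` or `"annual"` (annual for models that allocate
#'   a whole year's NPP at once).
#' @return An allocation scheme object.
#' @examples
#' sch <- fixed_scheme(allocation_vector(0.3, 0.5, 0.2))
#' fixed_alloc(sch, phase = "STEADY_GROWTH", treatment = "ambient", year = 1)
#' @export
fixed_scheme <- function(base, phase_table = NULL, treatment_override = NULL,
                         override_start_year = 2, strict_phases = FALSE,
                         timestep = "daily") {
  base <- as_allocation(base)
  if (!is.null(phase_table)) {
    if (!all(names(phase_table) %in% PHENO_PHASES))
      config_error("fixed_scheme: phase_table names must be phenological phases")
    phase_table <- lapply(phase_table, as_allocation)
  }
  if (!is.null(treatment_override)) treatment_override <- as_allocation(treatment_override)
  new_scheme(list(base = base, phase_table = phase_table,
                  treatment_override = treatment_override,
                  override_start_year = override_start_year,
                  strict_phases = strict_phases),
             "fixed_scheme", timestep)
}

as_allocation <- function(x) {
  if (inherits(x, "allocation_vector")) return(x)
  x <- unname(unlist(x))
  if (length(x) == 3) x <- c(x, 0)
  if (length(x) != 4) config_error("allocation vectors need 3 or 4 fractions")
  allocation_vector(x[1], x[2], x[3], x[4])
}

#' Evaluate a fixed scheme
#'
#' Returns the stored coefficients for a (phase, treatment, year)
#' combination; pool state and environment are never consulted, which is
#' what makes the pure variant's CO2 allocation response exactly zero.
#'
#' @param params A [fixed_scheme()].
#' @param phase One of [PHENO_PHASES].
#' @param treatment `"ambient"` or `"elevated"`.
#' @param year Simulation year index (1-based).
#' @return An [allocation_vector()].
#' @export
fixed_alloc <- function(params, phase = "STEADY_GROWTH",
                        treatment = c("ambient", "elevated"), year = 1) {
  treatment <- match.arg(treatment)
  if (treatment == "elevated" && !is.null(params$treatment_override) &&
      year >= params$override_start_year)
    return(params$treatment_override)
  if (!is.null(params$phase_table)) {
    entry <- params$phase_table[[phase]]
    if (!is.null(entry)) return(entry)
    if (isTRUE(params$strict_phases))
      config_error(sprintf("fixed_alloc: no allocation entry for phase '%s'", phase))
  }
  params$base
}

#' @export
scheme_allocate.fixed_scheme <- function(scheme, ctx) {
  alloc_result(fixed_alloc(scheme, ctx$phase, ctx$treatment, ctx$year),
               memory = ctx$memory)
}

## EALCO-style tissue-ratio scheme -------------------------------------------

#' Fixed-ratio scheme with a prescribed annual maximum LAI
#'
#' Early in the season all growth C builds foliage, because leaf biomass is
#' small relative to the prescribed foliage:sapwood:fine-root tissue ratio.
#' Once LAI reaches the maximum prescribed for that year and treatment,
#' foliage allocation stops and the remaining C is split between wood and
#' fine roots at fixed fractions, maintaining the tissue ratio. The annual
#' outcome is that foliage allocation realises the prescribed LAI whenever
#' enough C is fixed.
#'
#' @param tissue_ratio Positive length-3 target ratio
#'   foliage : sapwood : fine root (kept for reference; the operational rule
#'   is the LAI threshold plus `post_max_split`).
#' @param post_max_split Length-2 wood/root fractions applied after the LAI
#'   maximum; must sum to 1.
#' @param lai_max_by_year Prescribed maximum LAI: either a single number, or
#'   a data.frame with columns `year`, `treatment`, `lai_max`.
#' @return An allocation scheme object.
#' @examples
#' sch <- ealco_scheme(lai_max_by_year = 5.5)
#' ealco_alloc(sch, lai = 2, year = 1, treatment = "ambient")
#' @export
ealco_scheme <- function(tissue_ratio = c(1, 0.75, 0.5),
                         post_max_split = c(0.60, 0.40),
                         lai_max_by_year = 5.5) {
  if (length(tissue_ratio) != 3 || any(tissue_ratio <= 0))
    config_error("ealco_scheme: tissue_ratio must be 3 positive numbers")
  if (length(post_max_split) != 2 || abs(sum(post_max_split) - 1) > 1e-9 ||
      any(post_max_split < 0))
    config_error("ealco_scheme: post_max_split must be 2 fractions summing to 1")
  new_scheme(list(tissue_ratio = tissue_ratio, post_max_split = post_max_split,
                  lai_max_by_year = lai_max_by_year),
             "ealco_scheme", "daily")
}

ealco_lai_max <- function(params, year, treatment) {
  tab <- params$lai_max_by_year
  if (is.numeric(tab) && length(tab) == 1) return(tab)
  if (is.data.frame(tab)) {
    hit <- tab$lai_max[tab$year == year & tab$treatment == treatment]
    if (length(hit) == 1) return(hit)
    config_error(sprintf(
      "ealco_scheme: no prescribed maximum LAI for year %d, treatment '%s'",
      year, treatment))
  }
  config_error("ealco_scheme: lai_max_by_year must be a number or a data.frame")
}

#' Evaluate the tissue-ratio scheme
#'
#' @param params An [ealco_scheme()].
#' @param lai Current LAI (m2 m-2), non-negative.
#' @param year Simulation year index.
#' @param treatment `"ambient"` or `"elevated"`.
#' @return An [allocation_vector()]: all-foliage below the prescribed annual
#'   maximum LAI, the fixed wood/root split at or above it.
#' @export
ealco_alloc <- function(params, lai, year = 1,
                        treatment = c("ambient", "elevated")) {
  treatment <- match.arg(treatment)
  if (!is.finite(lai) || lai < 0) invalid_argument("ealco_alloc: lai must be non-negative")
  lmax <- ealco_lai_max(params, year, treatment)
  if (lai < lmax) allocation_vector(1, 0, 0, 0)
  else allocation_vector(0, params$post_max_split[1], params$post_max_split[2], 0)
}

#' @export
scheme_allocate.ealco_scheme <- function(scheme, ctx) {
  alloc_result(ealco_alloc(scheme, ctx$lai, ctx$year, ctx$treatment),
               memory = ctx$memory)
}
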