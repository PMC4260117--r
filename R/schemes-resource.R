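## Resource-limitation schemes ----------------------------------------------

#' Light/water resource-limitation scheme
#'
#' Allocation coefficients computed from light and water limitation in the
#' Arora & Boer (2005) form:
#' `a_w = (eps_w + omega (1 - L)) / (1 + omega (2 - L - W))`,
#' `a_r = (eps_r + omega (1 - W)) / (1 + omega (2 - L - W))`,
#' `a_f = 1 - a_w - a_r`, with light availability `L = exp(-k_ext * LAI)`.
#' Dense canopies (low `L`) shift allocation to wood to compete for light;
#' water stress (low `W`) shifts it to roots; foliage takes the residual.
#' In deciduous mode three phenological phases override the formula: all C
#' to leaves during leaf expansion, none during senescence or dormancy
#' (wood and roots then renormalised to sum to 1).
#'
#' @param omega Sensitivity parameter, non-negative.
#' @param eps_w,eps_r Base wood and root parameters, non-negative with
#'   `eps_w + eps_r < 1`.
#' @param k_ext Light extinction coefficient, positive.
#' @param lai_max Biome maximum LAI (used by the phenology thresholds).
#' @param deciduous Apply the three-phase overrides.
#' @return An allocation scheme object.
#' @examples
#' sch <- isam_scheme(omega = 0.8, eps_w = 0.3, eps_r = 0.25)
#' isam_alloc(env_state(co2 = 395, W = 1), lai = 1.5, params = sch)
#' @export
isam_scheme <- function(omega = 0.8, eps_w = 0.30, eps_r = 0.25,
                        k_ext = 0.5, lai_max = 5, deciduous = FALSE) {
  if (omega < 0 || eps_w < 0 || eps_r < 0)
    config_error("isam_scheme: omega, eps_w, eps_r must be non-negative")
  if (eps_w + eps_r >= 1) config_error("isam_scheme: eps_w + eps_r must be < 1")
  if (k_ext <= 0) config_error("isam_scheme: k_ext must be positive")
  new_scheme(list(omega = omega, eps_w = eps_w, eps_r = eps_r,
                  k_ext = k_ext, lai_max = lai_max, deciduous = deciduous),
             "isam_scheme", "daily")
}

#' Evaluate the light/water resource-limitation scheme
#'
#' @param env An [env_state()] (supplies `W`).
#' @param lai Current LAI (m2 m-2), non-negative.
#' @param params An [isam_scheme()].
#' @param phase Phenological phase; overrides apply only in deciduous mode.
#' @return An [allocation_vector()]. Parameterisations whose residual
#'   foliage share would be negative are clipped to 0 and renormalised, with
#'   a warning.
#' @export
isam_alloc <- function(env, lai, params, phase = "STEADY_GROWTH") {
  if (!is.finite(lai) || lai < 0) invalid_argument("isam_alloc: lai must be non-negative")
  if (isTRUE(params$deciduous)) {
    if (phase == "LEAF_EXPANSION") return(allocation_vector(1, 0, 0, 0))
    if (phase %in% c("SENESCENCE", "DORMANT")) {
      base <- isam_raw(env, lai, params)
      tot <- base[["a_w"]] + base[["a_r"]]
      if (tot <= 0) return(allocation_vector(0, 0.5, 0.5, 0))
      return(allocation_vector(0, base[["a_w"]] / tot, base[["a_r"]] / tot, 0))
    }
  }
  a <- isam_raw(env, lai, params)
  if (a[["a_f"]] < 0) {
    warning("isam_alloc: negative residual foliage share clipped to 0")
    tot <- a[["a_w"]] + a[["a_r"]]
    return(allocation_vector(0, a[["a_w"]] / tot, a[["a_r"]] / tot, 0))
  }
  allocation_vector(a[["a_f"]], a[["a_w"]], a[["a_r"]], 0)
}

isam_raw <- function(env, lai, params) {
  L <- exp(-params$k_ext * lai)
  denom <- 1 + params$omega * (2 - L - env$W)
  a_w <- (params$eps_w + params$omega * (1 - L)) / denom
  a_r <- (params$eps_r + params$omega * (1 - env$W)) / denom
  c(a_f = 1 - a_w - a_r, a_w = a_w, a_r = a_r)
}

#' @export
scheme_allocate.isam_scheme <- function(scheme, ctx) {
  alloc_result(isam_alloc(ctx$env, ctx$lai, scheme, ctx$phase), memory = ctx$memory)
}

## Demand-and-cap priority scheme -------------------------------------------

#' Capped demand-driven scheme
#'
#' Foliage and roots are prioritised: foliage demand is the C needed to
#' reach the maximum LAI at the given SLA, expressed as a fraction of the C
#' available this step and capped at `cap_f` (40% by default); root demand
#' rises from a baseline as water availability falls, saturating at `cap_r`
#' (30% by default); wood receives the remainder. The root demand is
#' `root_base + (cap_r - root_base) * (1 + k) s / (k + s)` with stress
#' `s = 1 - W` and shape `k = bmR / bmL`, which reaches the cap exactly at
#' full water stress. The maximum LAI is a constant here (it does not grow
#' with the stand).
#'
#' @param lai_max Maximum LAI (m2 m-2), constant.
#' @param sla Specific leaf area (m2 kg-1 C).
#' @param bmL,bmR Parameters defining the root:foliage demand ratio (shape
#'   of the root-demand saturation), positive.
#' @param cap_f,cap_r Foliage and root caps as fractions of available C,
#'   with `cap_f + cap_r < 1`.
#' @param root_base Root share at zero water stress, in \[0, cap_r\].
#' @return An allocation scheme object.
#' @export
teco_scheme <- function(lai_max = 4.5, sla = 12, bmL = 1, bmR = 1,
                        cap_f = 0.40, cap_r = 0.30, root_base = 0.12) {
  if (cap_f + cap_r >= 1) config_error("teco_scheme: cap_f + cap_r must be < 1")
  if (bmL <= 0 || bmR <= 0) config_error("teco_scheme: bmL and bmR must be positive")
  if (root_base < 0 || root_base > cap_r)
    config_error("teco_scheme: root_base must lie in [0, cap_r]")
  new_scheme(list(lai_max = lai_max, sla = sla, bmL = bmL, bmR = bmR,
                  cap_f = cap_f, cap_r = cap_r, root_base = root_base),
             "teco_scheme", "daily")
}

#' Evaluate the capped demand-driven scheme
#'
#' @param growth_c C available this step (kg C m-2), non-negative.
#' @param lai Current LAI (m2 m-2).
#' @param env An [env_state()] (supplies `W`).
#' @param params A [teco_scheme()].
#' @return An [allocation_vector()]; on a zero-C step a placeholder vector
#'   with attribute `flags = "no_growth"`.
#' @export
teco_alloc <- function(growth_c, lai, env, params) {
  if (!is.finite(growth_c) || growth_c < 0)
    invalid_argument("teco_alloc: growth_c must be non-negative")
  if (growth_c == 0) {
    out <- allocation_vector(0, 1, 0, 0)
    attr(out, "flags") <- "no_growth"
    return(out)
  }
  demand_f <- max(0, params$lai_max - lai) / (params$sla * growth_c)
  a_f <- min(params$cap_f, demand_f)
  s <- 1 - env$W
  k <- params$bmR / params$bmL
  a_r <- if (s <= 0) params$root_base else
    min(params$cap_r, params$root_base +
          (params$cap_r - params$root_base) * (1 + k) * s / (k + s))
  allocation_vector(a_f, 1 - a_f - a_r, a_r, 0)
}

#' @export
scheme_allocate.teco_scheme <- function(scheme, ctx) {
  a <- teco_alloc(ctx$growth_c, ctx$lai, ctx$env, scheme)
  alloc_result(a, memory = ctx$memory, flags = attr(a, "flags") %||% character())
}

## Strict priority scheme ----------------------------------------------------

#' Strict-priority scheme: roots, then foliage, then wood
#'
#' Fine roots have first claim: their share varies between `root_min` and
#' `root_max` of NPP with the stronger of the water and nutrient
#' limitations, `a_r = root_min + (root_max - root_min) * max(1 - W,
#' 1 - Nfac)`. Remaining C builds foliage until the maximum LAI is reached;
#' that maximum grows allometrically with wood biomass,
#' `lai_max = c1 * B_w^c2`. Wood receives C only once the LAI demand is met.
#'
#' @param root_min,root_max Bounds of the root share, `0 <= root_min <=
#'   root_max < 1`. Defaults 0.05 and 0.18.
#' @param lai_max_coef Length-2 coefficients `c(c1, c2)` of the
#'   wood-to-maximum-LAI allometry.
#' @return An allocation scheme object.
#' @export
daycent_scheme <- function(root_min = 0.05, root_max = 0.18,
                           lai_max_coef = c(2.0, 0.25)) {
  if (root_min < 0 || root_max < root_min || root_max >= 1)
    config_error("daycent_scheme: need 0 <= root_min <= root_max < 1")
  new_scheme(list(root_min = root_min, root_max = root_max,
                  lai_max_coef = lai_max_coef),
             "daycent_scheme", "daily")
}

daycent_lai_max <- function(params, B_w) {
  params$lai_max_coef[1] * max(B_w, 0)^params$lai_max_coef[2]
}

#' Evaluate the strict-priority scheme
#'
#' @param env An [env_state()] (supplies `W` and `Nfac`).
#' @param lai Current LAI (m2 m-2).
#' @param B_w Wood biomass (kg C m-2), sets the maximum LAI.
#' @param params A [daycent_scheme()].
#' @param growth_c C available this step (kg C m-2); needed to express the
#'   foliage demand as a fraction.
#' @param sla Specific leaf area (m2 kg-1 C) converting the LAI deficit to C.
#' @return An [allocation_vector()].
#' @export
daycent_alloc <- function(env, lai, B_w, params, growth_c, sla) {
  if (any(c(lai, B_w, growth_c) < 0)) invalid_argument("daycent_alloc: inputs must be non-negative")
  a_r <- params$root_min +
    (params$root_max - params$root_min) * max(1 - env$W, 1 - env$Nfac)
  if (growth_c == 0) {
    out <- allocation_vector(0, 1 - a_r, a_r, 0)
    attr(out, "flags") <- "no_growth"
    return(out)
  }
  lmax <- daycent_lai_max(params, B_w)
  demand_f <- max(0, lmax - lai) / (sla * growth_c)
  a_f <- min(1 - a_r, demand_f)
  allocation_vector(a_f, 1 - a_r - a_f, a_r, 0)
}

#' @export
scheme_allocate.daycent_scheme <- function(scheme, ctx) {
  a <- daycent_alloc(ctx$env, ctx$lai, ctx$pools[["B_w"]], scheme,
                     ctx$growth_c, ctx$sla)
  alloc_result(a, memory = ctx$memory, flags = attr(a, "flags") %||% character())
}
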