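## Functional-relationship schemes ------------------------------------------

#' Deficit-filling functional-balance scheme
#'
#' Leaf and fine-root pools are driven towards targets set by structural
#' proportionality: peak leaf biomass is the share of active biomass implied
#' by the leaf:sapwood ratio per unit height (`q_sw * h`), the current leaf
#' target is the phenology scalar `e_t` times that peak, and the root target
#' is `q` times the peak, where `q = q_base + q_stress_gain * (1 - min(W,
#' Nfac))` rises under water or nitrogen limitation. Growth C first fills
#' the leaf and root deficits (pro rata if it cannot cover both); any
#' remaining "reserve" C is split between wood and reproduction at a fixed
#' ratio (70:30 by default).
#'
#' @param q_sw Leaf:sapwood proportionality per unit height (m-1), positive.
#' @param q_base Baseline root:peak-leaf ratio, positive.
#' @param q_stress_gain Increase of `q` per unit `(1 - min(W, Nfac))`.
#' @param reserve_split_wood Fraction of reserve C to wood (rest to
#'   reproduction), in \[0, 1\].
#' @param height Tree height (m), a prescribed constant.
#' @param active_wood_frac Fraction of the (lumped) wood pool counted as
#'   sapwood in the active biomass; the rest is structural and takes no
#'   part in the proportionality.
#' @return An allocation scheme object.
#' @export
ed2_scheme <- function(q_sw = 0.1, q_base = 0.3, q_stress_gain = 0.8,
                       reserve_split_wood = 0.70, height = 18,
                       active_wood_frac = 0.3) {
  if (q_sw <= 0 || q_base <= 0) config_error("ed2_scheme: q_sw and q_base must be positive")
  if (reserve_split_wood < 0 || reserve_split_wood > 1)
    config_error("ed2_scheme: reserve_split_wood must lie in [0, 1]")
  if (active_wood_frac < 0 || active_wood_frac > 1)
    config_error("ed2_scheme: active_wood_frac must lie in [0, 1]")
  new_scheme(list(q_sw = q_sw, q_base = q_base, q_stress_gain = q_stress_gain,
                  reserve_split_wood = reserve_split_wood, height = height,
                  active_wood_frac = active_wood_frac),
             "ed2_scheme", "daily")
}

#' Evaluate the deficit-filling functional-balance scheme
#'
#' @param state A [pool_state()].
#' @param env An [env_state()] (supplies `W` and `Nfac`).
#' @param e_t Phenology scalar in \[0, 1\]; 0 means no leaf growth.
#' @param params An [ed2_scheme()].
#' @param growth_c C available this step (kg C m-2), non-negative.
#' @return An [allocation_vector()], with attribute `flags` containing
#'   `"no_growth"` when `growth_c` is zero.
#' @export
ed2_alloc <- function(state, env, e_t, params, growth_c) {
  if (!is.finite(e_t) || e_t < 0 || e_t > 1)
    invalid_argument("ed2_alloc: e_t must lie in [0, 1]")
  if (!is.finite(growth_c) || growth_c < 0)
    invalid_argument("ed2_alloc: growth_c must be non-negative")
  if (growth_c == 0) {
    out <- allocation_vector(0, 1, 0, 0)  # placeholder; nothing is allocated
    attr(out, "flags") <- "no_growth"
    return(out)
  }
  q <- params$q_base + params$q_stress_gain * (1 - min(env$W, env$Nfac))
  active <- state[["B_f"]] + params$active_wood_frac * state[["B_w"]] + state[["B_r"]]
  peak_leaf <- active / (1 + q + params$q_sw * params$height)
  target_leaf <- e_t * peak_leaf
  target_root <- q * peak_leaf
  d_f <- max(0, target_leaf - state[["B_f"]])
  d_r <- max(0, target_root - state[["B_r"]])
  need <- d_f + d_r
  if (need >= growth_c && need > 0) {
    c_f <- growth_c * d_f / need
    c_r <- growth_c * d_r / need
    reserve <- 0
  } else {
    c_f <- d_f; c_r <- d_r
    reserve <- growth_c - need
  }
  c_w <- reserve * params$reserve_split_wood
  c_rep <- reserve * (1 - params$reserve_split_wood)
  allocation_vector(c_f / growth_c, c_w / growth_c, c_r / growth_c, c_rep / growth_c)
}

#' @export
scheme_allocate.ed2_scheme <- function(scheme, ctx) {
  e_t <- if (is.null(ctx$e_t)) 1 else ctx$e_t
  a <- ed2_alloc(ctx$pools, ctx$env, e_t, scheme, ctx$growth_c)
  alloc_result(a, memory = ctx$memory, flags = attr(a, "flags") %||% character())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Pipe-model / allometric scheme -------------------------------------------

#' Allometric functional-balance scheme
#'
#' Allocation is whatever division of NPP keeps the biomass stocks on three
#' structural relationships after growth: (i) pipe model, LAI proportional
#' to sapwood area (`LAI = k_la_sa * SA`); (ii) height-diameter allometry
#' (`H = k_allom2 * D^k_allom3`), so taller canopies need disproportionately
#' more wood per unit leaf; and (iii) functional balance, a maximum
#' leaf:root mass ratio scaled down by nutrient or water limitation
#' (`C_f / C_r = lr_max * min(N, W)` by default, `lr_max * N * W` with
#' `stress_combine = "product"`). A fixed fraction of NPP goes to
#' reproduction first. The annual variant solves the constraints once per
#' year; the daily variant ([ocn_scheme()]) approaches the same targets each
#' day.
#'
#' Wood is represented as a cylinder of the configured density: sapwood area
#' `SA` and height `H` satisfy `C_w = wood_density * SA * H`, with the
#' representative-tree diameter `D = sqrt(4 SA / (pi * stems))`.
#'
#' @param k_la_sa LAI per unit sapwood area (dimensionless), positive.
#' @param k_allom2,k_allom3 Height-diameter constants, `H = k2 * D^k3`.
#' @param lr_max Maximum leaf:root mass ratio.
#' @param sla Specific leaf area (m2 kg-1 C) used to convert leaf C to LAI.
#' @param repro_fraction Fraction of NPP to reproduction, in \[0, 1).
#' @param wood_density Wood carbon density (kg C m-3).
#' @param stems Stem density (stems m-2): the representative-tree diameter
#'   is taken from the per-stem sapwood area, `D = sqrt(4 SA / (pi stems))`.
#' @param stress_combine How N and W combine to scale `lr_max`: `"min"`
#'   (default) or `"product"`.
#' @return An allocation scheme object.
#' @export
lpj_scheme <- function(k_la_sa = 4000, k_allom2 = 40, k_allom3 = 0.67,
                       lr_max = 1.0, sla = 10, repro_fraction = 0.10,
                       wood_density = 200, stems = 0.05,
                       stress_combine = c("min", "product")) {
  stress_combine <- match.arg(stress_combine)
  vals <- c(k_la_sa, k_allom2, k_allom3, lr_max, sla, wood_density, stems)
  if (any(!is.finite(vals)) || any(vals <= 0))
    config_error("lpj_scheme: allometric constants must be positive")
  if (repro_fraction < 0 || repro_fraction >= 1)
    config_error("lpj_scheme: repro_fraction must lie in [0, 1)")
  new_scheme(list(k_la_sa = k_la_sa, k_allom2 = k_allom2, k_allom3 = k_allom3,
                  lr_max = lr_max, sla = sla, repro_fraction = repro_fraction,
                  wood_density = wood_density, stems = stems,
                  stress_combine = stress_combine),
             "lpj_scheme", "annual")
}

#' @rdname lpj_scheme
#' @param ... Arguments passed to [lpj_scheme()].
#' @export
ocn_scheme <- function(...) {
  sch <- lpj_scheme(...)
  class(sch) <- c("ocn_scheme", class(sch))
  attr(sch, "timestep") <- "daily"
  sch
}

stress_scalar <- function(params, N, W) {
  s <- if (params$stress_combine == "product") N * W else min(N, W)
  max(s, 1e-6)
}

#' Tree geometry implied by the wood pool
#'
#' Inverts the cylinder + height-diameter allometry to recover sapwood area,
#' diameter and height from a wood carbon stock.
#'
#' @param C_w Wood carbon (kg C m-2), non-negative.
#' @param params An [lpj_scheme()].
#' @return Named list `SA` (m2 m-2), `D` (m), `H` (m).
#' @export
geometry_from_wood <- function(C_w, params) {
  if (C_w <= 0) return(list(SA = 0, D = 0, H = 0))
  ## C_w = rho * SA * H, H = k2 * D^k3, D = sqrt(4 SA / (pi * stems))
  ## =>  C_w = rho * k2 * (4 / (pi * stems))^(k3/2) * SA^(1 + k3/2)
  c0 <- params$wood_density * params$k_allom2 *
    (4 / (pi * params$stems))^(params$k_allom3 / 2)
  SA <- (C_w / c0)^(1 / (1 + params$k_allom3 / 2))
  D <- sqrt(4 * SA / (pi * params$stems))
  list(SA = SA, D = D, H = params$k_allom2 * D^params$k_allom3)
}

#' Wood carbon required to support a leaf carbon stock
#'
#' The pipe model fixes the sapwood area needed for a given LAI, and the
#' height-diameter allometry then fixes the wood volume: this returns the
#' wood C stock consistent with leaf stock `C_f`.
#'
#' @param C_f Leaf carbon (kg C m-2).
#' @param params An [lpj_scheme()].
#' @return Wood carbon (kg C m-2).
#' @export
wood_required <- function(C_f, params) {
  if (C_f <= 0) return(0)
  SA <- params$sla * C_f / params$k_la_sa
  D <- sqrt(4 * SA / (pi * params$stems))
  params$wood_density * SA * params$k_allom2 * D^params$k_allom3
}

#' Pool state on allometry for a target LAI
#'
#' Builds a [pool_state()] whose stocks satisfy the scheme's three
#' structural constraints at the given LAI and stress level: leaf C from
#' LAI and SLA, wood C from [wood_required()], root C from the leaf:root
#' ratio.
#'
#' @param params An [lpj_scheme()].
#' @param lai Target LAI (m2 m-2).
#' @param N,W Availability scalars setting the leaf:root ratio.
#' @return A [pool_state()].
#' @export
lpj_initial_state <- function(params, lai = 4, N = 1, W = 1) {
  C_f <- lai / params$sla
  pool_state(B_f = C_f, B_w = wood_required(C_f, params),
             B_r = C_f / (params$lr_max * stress_scalar(params, N, W)))
}

lpj_increments <- function(pools, avail, N, W, params,
                           tol = 1e-10, max_iter = 200L) {
  s <- stress_scalar(params, N, W)
  C_f <- pools[["B_f"]]; C_w <- pools[["B_w"]]; C_r <- pools[["B_r"]]
  root_req <- function(x) (C_f + x) / (params$lr_max * s)
  residual <- function(x) {
    x + max(0, root_req(x) - C_r) + max(0, wood_required(C_f + x, params) - C_w) - avail
  }
  flags <- character()
  if (avail <= 0) return(list(d_f = 0, d_w = 0, d_r = 0, flags = "no_growth"))
  r0 <- residual(0)
  if (r0 >= 0) {
    ## Even with no leaf growth the wood/root deficits absorb all C: the
    ## stand is off allometry (e.g. after a mortality event). Fill the two
    ## deficits pro rata; never disinvest.
    d_w0 <- max(0, wood_required(C_f, params) - C_w)
    d_r0 <- max(0, root_req(0) - C_r)
    tot <- d_w0 + d_r0
    if (tot <= 0) {  # degenerate: nothing to fill, park C in wood
      return(list(d_f = 0, d_w = avail, d_r = 0, flags = "off_allometry"))
    }
    if (r0 > tol * max(1, avail)) flags <- "off_allometry"
    sc <- avail / tot
    return(list(d_f = 0, d_w = sc * d_w0, d_r = sc * d_r0, flags = flags))
  }
  lo <- 0; hi <- avail
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    if (residual(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  x <- (lo + hi) / 2
  d_r <- max(0, root_req(x) - C_r)
  ## absorb the bisection remainder into wood so mass balances exactly;
  ## if that would push wood (just) negative, take it out of roots instead
  d_w <- avail - x - d_r
  if (d_w < 0) { d_r <- max(0, d_r + d_w); d_w <- 0 }
  list(d_f = x, d_w = d_w, d_r = d_r, flags = flags)
}

#' Annual allometric allocation
#'
#' Sends `repro_fraction` of the year's NPP to reproduction, then divides
#' the remainder into non-negative increments to foliage, wood and fine
#' roots such that the post-growth stocks satisfy the pipe-model,
#' height-diameter and leaf:root constraints. The leaf increment is found by
#' bisection (the residual is monotone); when no non-negative solution
#' exists (pools far off allometry, e.g. after mortality) the constrained
#' best solution is returned with flag `"off_allometry"`.
#'
#' @param pools A [pool_state()].
#' @param annual_npp Year's NPP (kg C m-2 yr-1), non-negative.
#' @param N,W Annual-mean nitrogen and water availability scalars in
#'   \[0, 1\].
#' @param params An [lpj_scheme()].
#' @return List with `alloc` (an [allocation_vector()]), `increments`
#'   (named kg C m-2), `geometry` (post-growth [geometry_from_wood()]),
#'   and `flags`.
#' @export
lpj_alloc_annual <- function(pools, annual_npp, N, W, params) {
  if (!is.finite(annual_npp) || annual_npp < 0)
    invalid_argument("lpj_alloc_annual: annual_npp must be non-negative")
  rep_c <- params$repro_fraction * annual_npp
  inc <- lpj_increments(pools, annual_npp - rep_c, N, W, params)
  alloc <- if (annual_npp > 0)
    allocation_vector(inc$d_f / annual_npp, inc$d_w / annual_npp,
                      inc$d_r / annual_npp, rep_c / annual_npp)
  else allocation_vector(0, 1, 0, 0)
  list(alloc = alloc,
       increments = c(d_f = inc$d_f, d_w = inc$d_w, d_r = inc$d_r, d_rep = rep_c),
       geometry = geometry_from_wood(pools[["B_w"]] + inc$d_w, params),
       flags = if (annual_npp > 0) inc$flags else "no_growth")
}

#' @export
scheme_allocate.lpj_scheme <- function(scheme, ctx) {
  res <- lpj_alloc_annual(ctx$pools, ctx$growth_c, ctx$env$Nfac, ctx$env$W, scheme)
  alloc_result(res$alloc, memory = ctx$memory, flags = res$flags)
}

#' Daily allometric allocation
#'
#' The daily variant of [lpj_alloc_annual()]: the same constraint targets
#' are approached incrementally with each day's growth C.
#'
#' @inheritParams lpj_alloc_annual
#' @param growth_c C available this day (kg C m-2).
#' @return As [lpj_alloc_annual()]; flag `"no_growth"` on a zero-NPP day.
#' @export
ocn_daily_alloc <- function(pools, growth_c, N, W, params) {
  lpj_alloc_annual(pools, growth_c, N, W, params)
}

#' @export
scheme_allocate.ocn_scheme <- function(scheme, ctx) {
  res <- ocn_daily_alloc(ctx$pools, ctx$growth_c, ctx$env$Nfac, ctx$env$W, scheme)
  alloc_result(res$alloc, memory = ctx$memory, flags = res$flags)
}
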