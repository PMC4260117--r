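## Common allocation-scheme interface ----------------------------------------

new_scheme <- function(params, class, timestep = c("daily", "annual")) {
  timestep <- match.arg(timestep)
  structure(params, class = c(class, "alloc_scheme"), timestep = timestep)
}

#' Timestep at which a scheme allocates
#'
#' Daily schemes partition each day's NPP as it arrives; annual schemes bank
#' the year's NPP and partition it once at the end of the simulated year.
#'
#' @param scheme An allocation scheme object.
#' @return `"daily"` or `"annual"`.
#' @export
scheme_timestep <- function(scheme) attr(scheme, "timestep")

#' Compute allocation coefficients for one step
#'
#' Generic dispatched on the scheme class. `ctx` is the simulation context
#' assembled by [simulate_stand()]: a list with the current `pools`
#' ([pool_state()]), `env` ([env_state()]), `lai`, `phase` (one of
#' [PHENO_PHASES]), `growth_c` (C available this step, kg C m-2), `year`,
#' `treatment` (`"ambient"` or `"elevated"`), `sla`, `turnover`, `dt` and
#' the scheme's private `memory` list.
#'
#' @param scheme An allocation scheme object.
#' @param ctx Simulation context list (see Details).
#' @return List with `alloc` (an [allocation_vector()]), the possibly updated
#'   `memory`, and a character vector `flags`.
#' @export
scheme_allocate <- function(scheme, ctx) UseMethod("scheme_allocate")

alloc_result <- function(alloc, memory = list(), flags = character()) {
  list(alloc = alloc, memory = memory, flags = flags)
}

#' Construct an allocation scheme from a name and parameter list
#'
#' Convenience dispatcher used by the experiment configuration layer. The
#' parameter list is passed to the matching constructor.
#'
#' @param name One of `"fixed"`, `"ealco"`, `"ed2"`, `"lpj"`, `"ocn"`,
#'   `"isam"`, `"teco"`, `"daycent"`, `"sdgvm"`.
#' @param params Named list of constructor arguments.
#' @return An allocation scheme object.
#' @export
make_scheme <- function(name, params = list()) {
  ctor <- switch(name,
    fixed = fixed_scheme, ealco = ealco_scheme, ed2 = ed2_scheme,
    lpj = lpj_scheme, ocn = ocn_scheme, isam = isam_scheme,
    teco = teco_scheme, daycent = daycent_scheme, sdgvm = sdgvm_scheme,
    config_error(sprintf("unknown allocation scheme '%s'", name)))
  do.call(ctor, params)
}
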