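## Assumption-centred diagnostics -------------------------------------------

annual_record_cols <- c("year", "npp_f", "npp_w", "npp_r", "npp_rep",
                        "litter_f", "litter_w", "litter_r",
                        "bmax_f", "bmax_w", "bmax_r", "lai_max")

#' Annual allocation fractions from an observation-style table
#'
#' Component NPP divided by total NPP, per year. Years with zero total NPP
#' are flagged missing and excluded from the means.
#'
#' @param records Annual records (see [write_annual_records()] for columns).
#' @return Data frame with per-year fractions `a_f`, `a_w`, `a_r`, `a_rep`
#'   and a logical `missing` column; attribute `mean` holds the across-year
#'   means over non-missing years and attribute `n_dropped` the count of
#'   dropped years.
#' @examples
#' rec <- data.frame(year = 1, npp_f = 0.2, npp_w = 0.6, npp_r = 0.2,
#'                   npp_rep = 0)
#' attr(allocation_fractions(rec), "mean")
#' @export
allocation_fractions <- function(records) {
  tot <- records$npp_f + records$npp_w + records$npp_r +
    if (is.null(records$npp_rep)) 0 else records$npp_rep
  missing <- !is.finite(tot) | tot <= 0
  frac <- function(x) ifelse(missing, NA_real_, x / tot)
  out <- data.frame(
    year = records$year,
    a_f = frac(records$npp_f), a_w = frac(records$npp_w),
    a_r = frac(records$npp_r),
    a_rep = frac(if (is.null(records$npp_rep)) 0 * tot else records$npp_rep),
    missing = missing
  )
  attr(out, "mean") <- colMeans(out[!missing, c("a_f", "a_w", "a_r", "a_rep")])
  attr(out, "n_dropped") <- sum(missing)
  out
}

#' Turnover rate and lifespan of one component
#'
#' Annual turnover rate is litter (plus mortality) divided by the annual
#' maximum of the biomass pool; annual lifespan is the inverse (maximum
#' biomass over litter). The multi-year lifespan is the mean of the annual
#' lifespans. Zero-litter years give an infinite lifespan, which is flagged
#' and dropped from the mean, never a division crash.
#'
#' @param records Annual records.
#' @param component One of `"f"` (foliage), `"w"` (wood), `"r"` (fine root).
#' @return List with per-year `rate` (yr-1) and `lifespan` (yr), the
#'   across-year `mean_rate` and `mean_lifespan` (mean of finite annual
#'   lifespans), and `n_dropped`.
#' @examples
#' rec <- data.frame(year = 1, litter_w = 1, bmax_w = 2)
#' turnover_lifespan(rec, "w")$mean_lifespan  # 2 yr
#' @export
turnover_lifespan <- function(records, component = c("f", "w", "r")) {
  component <- match.arg(component)
  litter <- records[[paste0("litter_", component)]]
  bmax <- records[[paste0("bmax_", component)]]
  if (is.null(litter) || is.null(bmax))
    schema_error("turnover_lifespan: records lack litter/bmax columns")
  ok <- is.finite(bmax) & bmax > 0
  rate <- ifelse(ok & is.finite(litter), litter / bmax, NA_real_)
  lifespan <- ifelse(is.finite(rate) & rate > 0, 1 / rate,
                     ifelse(is.finite(rate), Inf, NA_real_))
  finite <- is.finite(lifespan)
  list(rate = rate, lifespan = lifespan,
       mean_rate = mean(rate[is.finite(rate)]),
       mean_lifespan = if (any(finite)) mean(lifespan[finite]) else Inf,
       n_dropped = sum(!finite))
}

#' Whole-canopy specific leaf area
#'
#' LAI divided by foliage biomass, both taken at the annual peak.
#'
#' @param lai_max Annual maximum LAI (m2 m-2).
#' @param b_f_at_peak Foliage biomass at the peak (kg C m-2), positive.
#' @return SLA (m2 kg-1 C); vectorised over years.
#' @export
canopy_sla <- function(lai_max, b_f_at_peak) {
  if (any(!is.finite(b_f_at_peak)) || any(b_f_at_peak <= 0))
    invalid_argument("canopy_sla: foliage biomass must be positive")
  lai_max / b_f_at_peak
}

#' CO2 response ratio of an annual series
#'
#' Mean of the elevated annual values over the mean of the paired ambient
#' annual values. For biomass and LAI the annual value is the within-year
#' maximum, so pass the `bmax_*` / `lai_max` columns.
#'
#' @param series_elev,series_amb Equal-length paired annual series.
#' @return The ratio (dimensionless).
#' @export
co2_response_ratio <- function(series_elev, series_amb) {
  if (length(series_elev) != length(series_amb))
    invalid_argument("co2_response_ratio: series lengths differ")
  m_a <- mean(series_amb)
  if (!is.finite(m_a) || m_a <= 0)
    invalid_argument("co2_response_ratio: ambient mean must be positive")
  mean(series_elev) / m_a
}

#' NPP retention rate
#'
#' The percentage of the CO2-induced extra cumulative NPP still present in
#' live biomass at the end of the experiment:
#' `100 * (dB_elev - dB_amb) / (cumNPP_elev - cumNPP_amb)`. May legitimately
#' exceed 100 (e.g. if elevated CO2 also lengthens tissue lifespan) or fall
#' below 0.
#'
#' @param cum_npp_amb,cum_npp_elev Cumulative NPP over the experiment
#'   (kg C m-2); elevated must exceed ambient or the statistic is undefined.
#' @param d_biomass_amb,d_biomass_elev Biomass increment over the experiment
#'   (kg C m-2).
#' @return Retention (percent).
#' @export
npp_retention <- function(cum_npp_amb, cum_npp_elev,
                          d_biomass_amb, d_biomass_elev) {
  if (!(cum_npp_elev > cum_npp_amb))
    invalid_argument("npp_retention: cumulative NPP must be larger under elevated CO2")
  100 * (d_biomass_elev - d_biomass_amb) / (cum_npp_elev - cum_npp_amb)
}

#' Full diagnostics table for one treatment
#'
#' Bundles the per-year allocation fractions, the turnover/lifespan
#' estimates per component, the per-year canopy SLA, cumulative NPP and the
#' biomass increment (end-minus-start totals of the annual-maximum biomass).
#'
#' @param records Annual records for one treatment.
#' @return List of class `"diagnostics_table"`.
#' @export
diagnose_records <- function(records) {
  fr <- allocation_fractions(records)
  turn <- lapply(c(f = "f", w = "w", r = "r"),
                 function(k) turnover_lifespan(records, k))
  sla_y <- ifelse(records$bmax_f > 0, records$lai_max / records$bmax_f, NA_real_)
  btot <- records$bmax_f + records$bmax_w + records$bmax_r
  npp_tot <- records$npp_f + records$npp_w + records$npp_r +
    if (is.null(records$npp_rep)) 0 else records$npp_rep
  out <- list(
    fractions = fr,
    mean_fractions = attr(fr, "mean"),
    turnover = turn,
    lifespan = vapply(turn, `[[`, numeric(1), "mean_lifespan"),
    canopy_sla = sla_y,
    mean_canopy_sla = mean(sla_y, na.rm = TRUE),
    cum_npp = sum(npp_tot),
    biomass_increment = btot[length(btot)] - btot[1],
    n_years = nrow(records)
  )
  class(out) <- "diagnostics_table"
  out
}

#' @export
print.diagnostics_table <- function(x, ...) {
  cat(sprintf("Diagnostics over %d years\n", x$n_years))
  cat("mean allocation fractions:\n")
  print(round(x$mean_fractions, 3))
  cat("mean lifespans (yr):\n")
  print(round(x$lifespan, 2))
  cat(sprintf("mean canopy SLA: %.2f m2 kg-1 C\n", x$mean_canopy_sla))
  cat(sprintf("cumulative NPP: %.3f kg C m-2; biomass increment: %.3f kg C m-2\n",
              x$cum_npp, x$biomass_increment))
  invisible(x)
}
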