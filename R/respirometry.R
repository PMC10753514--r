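## Gas-exchange math for multiplexed flow-through respirometry.
##
## Analyzer train (matching the emulated system): excurrent air passes the
## water-vapour meter, then the CO2 analyzer, then chemical H2O/CO2 scrubbers,
## then the O2 analyzer. So FeCO2 is measured on wet air (mathematically
## dried here), while FeO2 is measured on dry, CO2-free air. Baselines sample
## animal-free incurrent air through the same train.

#' Mathematically scrub water vapour from a gas fraction
#'
#' Converts a fraction measured in wet air to its dry-air equivalent by
#' removing the diluting water vapour: `f_dry = f_wet * bp / (bp - wvp)`.
#'
#' @param f_wet fraction measured upstream of the scrubbers.
#' @param wvp water-vapour pressure (kPa), `0 <= wvp < bp`.
#' @param bp barometric pressure (kPa).
#' @return dry-equivalent fraction(s).
#' @export
scrub_water_math <- function(f_wet, wvp, bp) {
  if (any(wvp < 0)) stop("water-vapour pressure must be non-negative")
  if (any(wvp >= bp)) stop("water-vapour pressure must be below barometric pressure")
  f_wet * bp / (bp - wvp)
}

#' Rates of O2 consumption and CO2 production
#'
#' Flow-through gas-exchange equations for a system metering dry incurrent
#' air upstream (FRi, ml min^-1 STPD), with O2 measured on dry CO2-free air
#' and CO2 measured upstream of the scrubbers (already dried mathematically).
#' From the dry mass balance (excurrent dry flow = FRi - VO2 + VCO2):
#'
#'   VO2  = FRi (1 - FiCO2) (FiO2 - FeO2) / (1 - FeO2)
#'   VCO2 = (FRi (FeCO2 - FiCO2) - FeCO2 VO2) / (1 - FeCO2)
#'
#' where FiO2/FeO2 are on the O2 analyzer's dry CO2-free basis and
#' FiCO2/FeCO2 are dry fractions.
#'
#' @param fri incurrent dry flow (ml min^-1 STPD), positive.
#' @param fio2,feo2 incurrent/excurrent O2 fractions (dry, CO2-free basis).
#' @param fico2,feco2 incurrent/excurrent CO2 fractions (dry).
#' @return list with `vo2` and `vco2` (ml min^-1 STPD).
#' @export
compute_gas_rates <- function(fri, fio2, feo2, fico2, feco2) {
  if (any(fri <= 0)) stop("incurrent flow must be positive")
  fr <- range(c(fio2, feo2, fico2, feco2))
  if (fr[1] < 0 || fr[2] >= 1) stop("gas fractions must lie in [0, 1)")
  vo2 <- fri * (1 - fico2) * (fio2 - feo2) / (1 - feo2)
  vco2 <- (fri * (feco2 - fico2) - feco2 * vo2) / (1 - feco2)
  list(vo2 = vo2, vco2 = vco2)
}

#' Convert O2 consumption to metabolic power
#'
#' Oxy-joule equivalent conversion: `(16 + 5.164 * RQ)` J per ml O2, divided
#' by 60 to yield watts from ml O2 min^-1. A warning (no clamping) is issued
#' when RQ falls outside the physiological 0.7-1.0 range.
#'
#' @param vo2 O2 consumption (ml min^-1 STPD), non-negative.
#' @param rq respiratory quotient (VCO2/VO2), finite.
#' @return metabolic power (W).
#' @export
to_watts <- function(vo2, rq) {
  if (any(vo2 < 0)) stop("oxygen consumption must be non-negative")
  if (any(!is.finite(rq))) stop("RQ must be finite")
  out_of_range <- rq < 0.7 | rq > 1.0
  if (any(out_of_range)) {
    warning(sprintf("%d RQ value(s) outside [0.7, 1.0]; not clamped",
                    sum(out_of_range)))
  }
  vo2 * (16 + 5.164 * rq) / 60
}

#' Baseline drift correction by bracketing-baseline interpolation
#'
#' Each measurement cycle starts and ends with a baseline sampling
#' animal-free incurrent air. The incurrent reference fractions (`FiO2`,
#' `FiCO2`) at every instant of the cycle are linearly interpolated between
#' the (trimmed) means of the two bracketing baselines, anchored at the
#' baseline midpoints. Animal-segment excurrent values are untouched. CO2
#' baselines are mathematically water-scrubbed before averaging, so `FiCO2`
#' is a dry fraction.
#'
#' @param trace gas trace `data.table` with columns `run`, `t`, `cycle`,
#'   `channel` (0 = baseline), `FeO2`, `FeCO2_wet`, `wvp_kpa`, `bp_kpa`,
#'   `fri` (a single-run table without `run` is also accepted).
#' @param trim_s seconds discarded at each end of a baseline before averaging
#'   (washout guard).
#' @return the trace with added columns `FiO2` and `FiCO2` (dry) and
#'   `FeCO2` (dry-corrected excurrent CO2).
#' @export
correct_baseline_drift <- function(trace, trim_s = 60) {
  dt <- data.table::as.data.table(trace)
  if (!"run" %in% names(dt)) dt[, run := 1L]
  dt[, feco2_dry := scrub_water_math(FeCO2_wet, wvp_kpa, bp_kpa)]
  ## trimmed baseline means, per contiguous baseline segment
  base <- dt[channel == 0L]
  base[, seg := cumsum(c(1L, (diff(t) != 1L) | (diff(cycle) != 0L) |
                           (diff(as.integer(run)) != 0L)))]
  seg_stats <- base[, {
    tt <- t
    keep <- tt >= (min(tt) + trim_s) & tt <= (max(tt) - trim_s)
    if (!any(keep)) keep <- rep(TRUE, length(tt))  # short baseline: no trim
    list(run = run[1], cycle = cycle[1], t_mid = mean(tt),
         o2 = mean(FeO2[keep]), co2 = mean(feco2_dry[keep]))
  }, by = seg]
  n_base <- seg_stats[, .N, by = list(run, cycle)]
  if (any(n_base$N < 2)) {
    bad <- n_base[N < 2][1]
    stop(sprintf("cycle %d of run %d lacks bracketing baselines",
                 bad$cycle, bad$run))
  }
  ## linear interpolation between the two bracketing baselines of each cycle
  data.table::setorder(seg_stats, run, cycle, t_mid)
  interp <- seg_stats[, {
    list(t_lo = t_mid[1], t_hi = t_mid[.N],
         o2_lo = o2[1], o2_hi = o2[.N],
         co2_lo = co2[1], co2_hi = co2[.N])
  }, by = list(run, cycle)]
  dt <- merge(dt, interp, by = c("run", "cycle"), sort = FALSE)
  dt[, frac := pmin(1, pmax(0, (t - t_lo) / (t_hi - t_lo)))]
  dt[, FiO2 := o2_lo + frac * (o2_hi - o2_lo)]
  dt[, FiCO2 := co2_lo + frac * (co2_hi - co2_lo)]
  dt[, FeCO2 := feco2_dry]
  dt[, c("t_lo", "t_hi", "o2_lo", "o2_hi", "co2_lo", "co2_hi", "frac",
         "feco2_dry") := NULL]
  data.table::setorder(dt, run, t)
  dt[]
}

#' Per-second metabolic rate series from a drift-corrected trace
#'
#' Applies the gas-exchange equations to every animal-channel sample of a
#' drift-corrected trace, yielding per-second VO2, VCO2, RQ and watts.
#' RQ warnings from extreme per-second noise are suppressed here; RQ is
#' evaluated over extraction windows downstream.
#'
#' @param corrected output of [correct_baseline_drift()].
#' @return `data.table` of animal-channel rows with columns `run`, `t`,
#'   `setpoint`, `cycle`, `channel`, `seg_id` (if present), `vo2`, `vco2`,
#'   `rq`, `watts`.
#' @export
compute_rate_series <- function(corrected) {
  dt <- data.table::as.data.table(corrected)[channel != 0L]
  rates <- compute_gas_rates(dt$fri, dt$FiO2, dt$FeO2, dt$FiCO2, dt$FeCO2)
  dt[, vo2 := rates$vo2]
  dt[, vco2 := rates$vco2]
  dt[, rq := ifelse(vo2 > 0, vco2 / vo2, NA_real_)]
  dt[, watts := suppressWarnings(to_watts(pmax(vo2, 0), ifelse(is.na(rq), 0.75, rq)))]
  keep <- intersect(c("run", "t", "setpoint", "cycle", "channel", "seg_id",
                      "vo2", "vco2", "rq", "watts"), names(dt))
  dt[, keep, with = FALSE]
}
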