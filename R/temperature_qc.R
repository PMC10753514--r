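## Quality control of body-temperature streams: misread-spike removal,
## recording-range enforcement, rounding and 1-min binning.

#' Remove isolated PIT-tag misread spikes
#'
#' A reading above `threshold` is a misread when it occurs in isolation
#' inside an otherwise normal stretch: every other sample within
#' `neighbor_window_s` seconds must be at or below `neighbor_max`. Sustained
#' high stretches (genuine hyperthermia) are never removed. Removed samples
#' are flagged `"misread_removed"` and their value set missing, not dropped.
#'
#' @param series temperature series (`bird_id`, `t`, `temp`, optional
#'   `flag`); multiple birds are handled per bird.
#' @param threshold spike threshold (degC), readings strictly above are
#'   candidates.
#' @param neighbor_window_s half-width (s) of the neighbourhood checked.
#' @param neighbor_max maximum neighbouring temperature (degC) for a
#'   candidate to count as isolated.
#' @return the series with a `flag` column (`"ok"` or `"misread_removed"`);
#'   the number removed is available via `attr(, "n_removed")`.
#' @export
remove_misreads <- function(series, threshold = 45, neighbor_window_s = 60,
                            neighbor_max = 42) {
  dt <- data.table::as.data.table(series)
  if (!"flag" %in% names(dt)) dt[, flag := "ok"]
  if (nrow(dt) == 0) {
    attr(dt, "n_removed") <- 0L
    return(dt[])
  }
  if (!"bird_id" %in% names(dt)) dt[, bird_id := "unknown"]
  n_removed <- 0L
  for (b in unique(dt$bird_id)) {
    rows <- which(dt$bird_id == b & dt$flag == "ok")
    tt <- dt$t[rows]
    temp <- dt$temp[rows]
    cand <- which(!is.na(temp) & temp > threshold)
    for (i in cand) {
      nb <- which(abs(tt - tt[i]) <= neighbor_window_s)
      nb <- setdiff(nb, i)
      if (all(temp[nb] <= neighbor_max, na.rm = TRUE)) {
        dt$flag[rows[i]] <- "misread_removed"
        dt$temp[rows[i]] <- NA_real_
        n_removed <- n_removed + 1L
      }
    }
  }
  attr(dt, "n_removed") <- n_removed
  dt[]
}

#' Enforce the thermocouple recording window
#'
#' Values outside the closed range become missing with flag
#' `"out_of_range"`; in-range values are never altered.
#'
#' @param series temperature series.
#' @param range closed recording window (degC).
#' @return the series with out-of-range values flagged and set missing;
#'   count via `attr(, "n_out_of_range")`.
#' @export
enforce_range <- function(series, range = c(30, 50)) {
  dt <- data.table::as.data.table(series)
  if (!"flag" %in% names(dt)) dt[, flag := "ok"]
  bad <- which(dt$flag == "ok" & !is.na(dt$temp) &
                 (dt$temp < range[1] | dt$temp > range[2]))
  dt$flag[bad] <- "out_of_range"
  dt$temp[bad] <- NA_real_
  attr(dt, "n_out_of_range") <- length(bad)
  dt[]
}

#' Round to sensor resolution and bin into fixed-width means
#'
#' Readings are first rounded to 0.1 degC (the PIT-tag resolution, applied to
#' all sensors for comparability) and then averaged within non-overlapping
#' bins anchored at integer multiples of `bin_s` from recording start. Bins
#' with no retained samples are absent from the output (missing).
#'
#' @param series cleaned temperature series (`bird_id`, `t`, `temp`, `flag`).
#' @param bin_s bin width in seconds (default 60).
#' @param resolution rounding resolution in degC (default 0.1).
#' @return `data.table` with columns `bird_id` (and `method` if present),
#'   `bin` (0-based bin index), `t` (bin start, s), `temp` (bin mean),
#'   `n` (samples in bin).
#' @export
round_and_bin <- function(series, bin_s = 60, resolution = 0.1) {
  if (bin_s <= 0) stop("bin width must be positive")
  dt <- data.table::as.data.table(series)
  if (!"flag" %in% names(dt)) dt[, flag := "ok"]
  dt <- dt[flag == "ok" & !is.na(temp)]
  dt[, temp_r := round(temp / resolution) * resolution]
  dt[, bin := floor(t / bin_s)]
  by_cols <- intersect(c("bird_id", "method"), names(dt))
  out <- dt[, list(temp = mean(temp_r), n = .N), by = c(by_cols, "bin")]
  out[, t := bin * bin_s]
  data.table::setorderv(out, c(by_cols, "bin"))
  data.table::setcolorder(out, c(by_cols, "bin", "t", "temp", "n"))
  out[]
}
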