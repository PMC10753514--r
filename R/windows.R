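## Resting-metabolic-rate extraction: the most-stable 2-min window per
## measurement cycle, the minimum across cycles per ambient temperature, and
## time-matched mean body temperature.

#' Find the most stable contiguous window of a rate series
#'
#' Scans all contiguous windows of `width_s` samples (1 Hz, stride 1 s) and
#' returns the one minimizing the sample standard deviation; ties are broken
#' by the earliest start.
#'
#' @param x per-second rate series (watts or VO2) for one sample segment.
#' @param width_s window width in samples/seconds (default 120).
#' @return list with `start` and `end` (1-based sample indices, closed),
#'   `mean` and `sd` over the window.
#' @export
find_stablest_window <- function(x, width_s = 120) {
  n <- length(x)
  if (n < width_s) stop("segment shorter than the window width")
  if (width_s < 2) stop("window width must be at least 2 samples")
  xc <- x - mean(x)  # centring improves the numerical stability of cumsums
  cs <- cumsum(c(0, xc))
  cs2 <- cumsum(c(0, xc^2))
  w <- width_s
  starts <- seq_len(n - w + 1)
  sums <- cs[starts + w] - cs[starts]
  sums2 <- cs2[starts + w] - cs2[starts]
  vars <- pmax(0, (sums2 - sums^2 / w) / (w - 1))
  best <- which.min(vars)  # which.min takes the earliest on exact ties
  list(start = best, end = best + w - 1L,
       mean = sums[best] / w + mean(x), sd = sqrt(vars[best]))
}

#' Extract RMR estimates per bird and ambient temperature
#'
#' For every bird sample segment, finds the most stable 2-min window of the
#' metabolic power series; per bird and ambient temperature, RMR is the
#' lowest of those window means across cycles. Gas quantities are averaged
#' over the selected window.
#'
#' @param rates per-second rate series from [compute_rate_series()].
#' @param birds bird table (`run`, `channel`, `bird_id`, `method`).
#' @param width_s window width (s).
#' @param search_on series the stability search runs on: `"watts"` (default)
#'   or `"vo2"`.
#' @return `data.table` with one row per bird x ambient temperature:
#'   `bird_id`, `method`, `t_air`, `cycle`, `win_start`, `win_end` (absolute
#'   seconds, closed interval), `vo2`, `vco2`, `rq`, `rmr_w`, `n_cycles`.
#' @export
extract_rmr <- function(rates, birds, width_s = 120, search_on = "watts") {
  stopifnot(search_on %in% c("watts", "vo2"))
  dt <- data.table::as.data.table(rates)
  b <- data.table::as.data.table(birds)[, list(run, channel, bird_id, method)]
  dt <- merge(dt, b, by = c("run", "channel"))
  data.table::setorder(dt, run, t)
  wins <- dt[, {
    y <- if (search_on == "watts") watts else vo2
    win <- find_stablest_window(y, width_s)
    idx <- win$start:win$end
    list(bird_id = bird_id[1], method = method[1], t_air = setpoint[1],
         win_start = t[win$start], win_end = t[win$end],
         vo2 = mean(vo2[idx]), vco2 = mean(vco2[idx]),
         watts_mean = mean(watts[idx]))
  }, by = list(run, cycle, seg_id)]
  est <- wins[, {
    k <- which.min(watts_mean)
    list(cycle = cycle[k],
         win_start = win_start[k], win_end = win_end[k],
         vo2 = vo2[k], vco2 = vco2[k], rq = vco2[k] / vo2[k],
         rmr_w = watts_mean[k], n_cycles = .N)
  }, by = list(bird_id, method, t_air)]
  data.table::setorder(est, bird_id, -t_air)
  est[]
}

#' Time-match mean body temperature to the RMR window
#'
#' Adds to each metabolic estimate the mean of the calibrated, QC'd 1 Hz
#' body-temperature readings whose timestamps fall inside the RMR window
#' (closed on both ends). When no reading falls inside the window, the
#' single reading closest in time to the window is used and flagged as a
#' fallback.
#'
#' @param estimates output of [extract_rmr()].
#' @param series calibrated, QC'd 1 Hz temperature series (`bird_id`, `t`,
#'   `temp`, `flag`).
#' @return the estimates with added `tb_mean`, `tb_fallback`, `tb_n`.
#' @export
match_tb <- function(estimates, series) {
  est <- data.table::as.data.table(estimates)
  ser <- data.table::as.data.table(series)
  if ("flag" %in% names(ser)) ser <- ser[flag == "ok" & !is.na(temp)]
  est[, tb_mean := NA_real_]
  est[, tb_fallback := FALSE]
  est[, tb_n := 0L]
  ser_split <- split(ser, by = "bird_id", keep.by = FALSE)
  for (i in seq_len(nrow(est))) {
    s <- ser_split[[est$bird_id[i]]]
    if (is.null(s) || nrow(s) == 0) next
    inside <- s$temp[s$t >= est$win_start[i] & s$t <= est$win_end[i]]
    if (length(inside) > 0) {
      data.table::set(est, i, "tb_mean", mean(inside))
      data.table::set(est, i, "tb_n", length(inside))
    } else {
      d <- pmin(abs(s$t - est$win_start[i]), abs(s$t - est$win_end[i]))
      k <- which.min(d)
      data.table::set(est, i, "tb_mean", s$temp[k])
      data.table::set(est, i, "tb_fallback", TRUE)
      data.table::set(est, i, "tb_n", 1L)
    }
  }
  est[]
}
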