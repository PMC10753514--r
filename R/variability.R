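## Temporal-variability indices of 1-min-binned body-temperature profiles.

#' Coefficient of variation (%)
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation.
#'
#' @param x numeric series, `n >= 2`, positive mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("CV requires at least 2 values")
  m <- mean(x)
  if (m <= 0) stop("CV requires a positive mean")
  100 * stats::sd(x) / m
}

#' Consecutive disparity index
#'
#' Order-sensitive variability: the mean absolute natural logarithm of the
#' ratio of consecutive values,
#' `D = sum(|ln(x[t+1]/x[t])|) / (n - 1)`.
#' Unlike the CV, D is sensitive to the chronological order of the series.
#' When `bin` indices are supplied, pairs spanning a gap in the binned series
#' are skipped and the divisor is the number of valid consecutive pairs.
#'
#' @param x positive numeric series (1-min bin means).
#' @param bin optional integer bin indices aligned with `x`; consecutive
#'   pairs are those with `diff(bin) == 1`.
#' @return D (dimensionless, >= 0).
#' @export
disparity_index <- function(x, bin = NULL) {
  keep <- !is.na(x)
  x <- x[keep]
  if (!is.null(bin)) bin <- bin[keep]
  if (length(x) < 2) stop("D requires at least 2 values")
  if (any(x <= 0)) stop("D requires strictly positive values")
  lr <- abs(diff(log(x)))
  if (!is.null(bin)) {
    lr <- lr[diff(bin) == 1]
    if (length(lr) == 0) stop("no consecutive pairs after gap removal")
  }
  sum(lr) / length(lr)
}

#' Per-bird variability of binned night profiles
#'
#' Computes the CV (%) and consecutive disparity index D of each bird's
#' 1-min-binned body-temperature profile.
#'
#' @param binned output of [round_and_bin()] (`bird_id`, `method`, `bin`,
#'   `temp`).
#' @return `data.table`: `bird_id`, `method`, `cv`, `d_index`, `n_bins`.
#' @export
variability_table <- function(binned) {
  dt <- data.table::as.data.table(binned)
  out <- dt[, list(cv = coefficient_of_variation(temp),
                   d_index = disparity_index(temp, bin = bin),
                   n_bins = .N),
            by = list(bird_id, method)]
  data.table::setorder(out, bird_id)
  out[]
}
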