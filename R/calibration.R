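## Linear sensor calibration against the climate-chamber reference.

#' Fit linear calibrations from a bench fixture
#'
#' Ordinary least squares of the chamber reference temperature on the raw
#' sensor reading, per group (by default per measurement method, pooling
#' sensor units). The fitted map is the one used downstream: predicted true
#' temperature = intercept + slope * reading.
#'
#' @param table calibration fixture with columns `reading`, `reference_c`,
#'   and the grouping column.
#' @param grouping name of the grouping column (default `"method"`).
#' @return `data.table` with one row per group: `group`, `slope`,
#'   `intercept`, `r2`, `n`. Warns when a slope falls outside (0.8, 1.2).
#' @export
fit_calibration <- function(table, grouping = "method") {
  dt <- data.table::as.data.table(table)
  if (!grouping %in% names(dt)) stop("grouping column not found: ", grouping)
  fits <- dt[, {
    if (length(unique(reference_c)) < 2) {
      stop("degenerate regression: a single reference level in group ",
           .BY[[1]])
    }
    fit <- stats::lm(reference_c ~ reading)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = summary(fit)$r.squared,
         n = .N)
  }, by = grouping]
  data.table::setnames(fits, grouping, "group")
  if (any(fits$slope <= 0.8 | fits$slope >= 1.2)) {
    warning("calibration slope outside (0.8, 1.2) for group(s): ",
            paste(fits$group[fits$slope <= 0.8 | fits$slope >= 1.2],
                  collapse = ", "))
  }
  fits[]
}

#' Apply a linear calibration to a temperature series
#'
#' Replaces each reading by `intercept + slope * reading` using the fit for
#' the series' group; any QC flag column is preserved.
#'
#' @param series temperature series with columns `temp` and the grouping
#'   column (`method` by default).
#' @param fits output of [fit_calibration()].
#' @param grouping grouping column in `series` matched against `fits$group`.
#' @return the series with calibrated `temp`.
#' @export
apply_calibration <- function(series, fits, grouping = "method") {
  dt <- data.table::as.data.table(series)
  groups <- unique(dt[[grouping]])
  missing_fit <- setdiff(groups, fits$group)
  if (length(missing_fit) > 0) {
    stop("missing calibration fit for sensor group(s): ",
         paste(missing_fit, collapse = ", "))
  }
  idx <- match(dt[[grouping]], fits$group)
  dt[, temp := fits$intercept[idx] + fits$slope[idx] * temp]
  dt[]
}
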