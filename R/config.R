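#' Experiment configuration
#'
#' Builds and validates the configuration of a synthetic overnight
#' respirometry + body-temperature experiment. Defaults describe the study
#' design the package emulates: five measurement groups (intraperitoneal and
#' subcutaneous PIT tags, cloacal and cutaneous thermocouples, and an
#' un-instrumented control), five birds multiplexed per night through an
#' 80-min stop-flow cycle (15 min baseline + 5 x 10 min bird channels +
#' 15 min baseline), and a chamber program of 25, 5, -15, 5, 25 degC held for
#' 160, 160, 160, 160 and 80 min.
#'
#' Effect-size defaults encode the contrasts the pipeline is expected to
#' recover: resting metabolic rate (RMR) rises by a factor `rmr_ratio_5v25`
#' (1.29) from 25 to 5 degC and by `rmr_ratio_m15v5` (1.53) from 5 to -15
#' degC; RMR gains `mass_slope` W per gram of body mass; cutaneous (skin)
#' temperature sits `cu_deficit_5` / `cu_deficit_m15` degC below core
#' temperature at 5 / -15 degC. Absolute baselines (`rmr_base_25`,
#' `tb_core_25`) are free choices of the generator, plausible for a ~17 g
#' nocturnal passerine; only ratios and differences matter downstream.
#'
#' @param n_birds_per_method birds per measurement group (one bird of each
#'   group per overnight run, so this is also the number of runs).
#' @param methods measurement group labels.
#' @param chamber_program data.frame with columns `setpoint` (degC) and
#'   `duration_min`; each duration must be a whole number of 80-min cycles.
#' @param baseline_min,birds_per_cycle,sample_min multiplexing cycle layout.
#' @param flow_mean,flow_sd incurrent dry flow (ml min^-1 STPD), per run.
#' @param fio2,fico2 incurrent O2 (dry, CO2-free analyzer basis) and CO2
#'   (dry) fractions.
#' @param bp_kpa barometric pressure (kPa).
#' @param rmr_base_25 true RMR (W) at 25 degC for a bird of `mass_ref` g.
#' @param rmr_ratio_5v25,rmr_ratio_m15v5 multiplicative temperature effects.
#' @param mass_slope additive mass effect on RMR (W g^-1).
#' @param mass_ref,mass_mean,mass_sd reference and generated body mass (g).
#' @param rmr_bird_sd between-bird SD of RMR (W), shared across setpoints.
#' @param rmr_cycle_cv within-bird between-cycle proportional SD of the
#'   quiescent metabolic level.
#' @param method_resid_scale named multipliers on `rmr_cycle_cv` per method
#'   (the heteroscedasticity the varIdent model structure targets).
#' @param rq_mean,rq_sd per-bird respiratory quotient distribution.
#' @param tb_core_25 true core body temperature (degC) at 25 degC.
#' @param tb_drop_subTNZ core temperature drop (degC) below thermoneutrality.
#' @param cu_deficit_5,cu_deficit_m15 cutaneous deficit below core (degC) at
#'   5 and -15 degC (0 at 25 degC).
#' @param tb_bird_sd between-bird SD of body temperature level (degC).
#' @param tb_slow_sd SD (degC) of the slow within-night temperature
#'   fluctuation (sum of 30-90 min period sinusoids).
#' @param tb_jitter_sd SD (degC) of minute-scale temperature jitter.
#' @param cl_jitter_scale multiplier on `tb_jitter_sd` for cloacal
#'   thermocouples (drives the consecutive-disparity contrast).
#' @param cu_noise_scale multiplier on `tb_slow_sd` for cutaneous
#'   thermocouples.
#' @param misread_rate per-sample probability of an isolated PIT-tag misread
#'   spike (>45 degC) in IP/SC streams.
#' @param tc_range thermocouple recording window (degC); values outside are
#'   never stored.
#' @param o2_noise_sd,co2_noise_sd analyzer noise SD (fraction units, 1 Hz).
#' @param drift_linear,drift_sine_amp,drift_sine_period_s baseline analyzer
#'   drift: linear total change over the night plus a sinusoid (fractions).
#' @param washout_tau_s chamber/analyzer washout time constant (s) applied at
#'   channel switches.
#' @param wvp_bird_kpa,wvp_baseline_kpa water-vapour pressure (kPa) of
#'   excurrent bird air and of the dry incurrent baseline.
#' @param plateau_min width (min) of the quiescent metabolic plateau placed
#'   at random inside each 10-min bird sample.
#' @param method_offset,method_gain named per-method systematic sensor
#'   miscalibration (reading = offset + gain * temperature + unit effects).
#' @param unit_offset_sd,unit_gain_sd between-sensor-unit SD of offset/gain.
#' @param calib_n_units number of bench calibration units (33 paired
#'   comparisons in the emulated design).
#' @param calib_refs chamber reference temperatures (degC) for calibration.
#' @param calib_noise_sd reading noise SD (degC) in the calibration fixture.
#' @param seed integer seed; the generator is fully reproducible given the
#'   seed and configuration.
#'
#' @return A validated list of class `"experiment_config"`.
#' @export
experiment_config <- function(n_birds_per_method = 13,
                              methods = c("IP", "CL", "SC", "CU", "C"),
                              chamber_program = data.frame(
                                setpoint = c(25, 5, -15, 5, 25),
                                duration_min = c(160, 160, 160, 160, 80)
                              ),
                              baseline_min = 15,
                              birds_per_cycle = 5,
                              sample_min = 10,
                              flow_mean = 594, flow_sd = 22,
                              fio2 = 0.2095, fico2 = 0.0004,
                              bp_kpa = 101.3,
                              rmr_base_25 = 0.18,
                              rmr_ratio_5v25 = 1.29,
                              rmr_ratio_m15v5 = 1.53,
                              mass_slope = 0.026,
                              mass_ref = 17, mass_mean = 17, mass_sd = 1.3,
                              rmr_bird_sd = 0.012,
                              rmr_cycle_cv = 0.02,
                              method_resid_scale = c(IP = 1, CL = 1.15,
                                                     SC = 0.9, CU = 1.1,
                                                     C = 1),
                              rq_mean = 0.75, rq_sd = 0.03,
                              tb_core_25 = 38.0,
                              tb_drop_subTNZ = 1.5,
                              cu_deficit_5 = 2.35, cu_deficit_m15 = 2.7,
                              tb_bird_sd = 0.25,
                              tb_slow_sd = 1.09,
                              tb_jitter_sd = 0.15,
                              cl_jitter_scale = 1.36,
                              cu_noise_scale = 1.0,
                              misread_rate = 2e-5,
                              tc_range = c(30, 50),
                              o2_noise_sd = 2e-5, co2_noise_sd = 5e-6,
                              drift_linear = 4e-4,
                              drift_sine_amp = 1e-4,
                              drift_sine_period_s = 28800,
                              washout_tau_s = 12,
                              wvp_bird_kpa = 0.20, wvp_baseline_kpa = 0.02,
                              plateau_min = 3,
                              method_offset = c(IP = -0.3, SC = -0.3,
                                                CL = 0.2, CU = 0.2),
                              method_gain = c(IP = 1.01, SC = 1.01,
                                              CL = 0.995, CU = 0.995),
                              unit_offset_sd = 0.1, unit_gain_sd = 0.005,
                              calib_n_units = 33,
                              calib_refs = c(35, 40, 45),
                              calib_noise_sd = 0.05,
                              seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

#' Validate an experiment configuration
#'
#' @param cfg a list as returned by [experiment_config()].
#' @return `cfg`, invisibly; stops with a configuration error otherwise.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (cfg$n_birds_per_method < 1) {
    stop("configuration error: n_birds_per_method must be a positive count")
  }
  if (any(cfg$chamber_program$duration_min <= 0) ||
      cfg$baseline_min <= 0 || cfg$sample_min <= 0) {
    stop("configuration error: all durations must be positive")
  }
  cyc <- cycle_length_min(cfg)
  if (cyc != 2 * cfg$baseline_min + cfg$birds_per_cycle * cfg$sample_min) {
    stop("configuration error: inconsistent cycle arithmetic")
  }
  if (any(cfg$chamber_program$duration_min %% cyc != 0)) {
    stop("configuration error: each chamber step must hold for a whole ",
         "number of ", cyc, "-min cycles")
  }
  if (cfg$rmr_ratio_5v25 <= 1 || cfg$rmr_ratio_m15v5 <= 1) {
    stop("configuration error: rmr ratios must exceed 1")
  }
  if (cfg$cu_deficit_5 < 0 || cfg$cu_deficit_m15 < 0) {
    stop("configuration error: cutaneous deficits must be >= 0")
  }
  if (cfg$flow_sd < 0 || cfg$flow_mean <= 0) {
    stop("configuration error: flow must be positive with sd >= 0")
  }
  if (cfg$misread_rate < 0 || cfg$misread_rate >= 1) {
    stop("configuration error: misread_rate must be in [0, 1)")
  }
  if (length(cfg$methods) != cfg$birds_per_cycle) {
    stop("configuration error: one bird of each method per cycle is assumed")
  }
  invisible(cfg)
}

#' Multiplexing cycle length in minutes
#'
#' @param cfg an experiment configuration.
#' @return cycle length (min): baseline + birds + baseline.
#' @export
cycle_length_min <- function(cfg) {
  2 * cfg$baseline_min + cfg$birds_per_cycle * cfg$sample_min
}

#' Read a configuration from a YAML file
#'
#' Scalar fields in the file override [experiment_config()] defaults; the
#' `chamber_program` entry, if present, must be a list with `setpoint` and
#' `duration_min` vectors.
#'
#' @param path YAML file path.
#' @return an `experiment_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$chamber_program)) {
    raw$chamber_program <- data.frame(
      setpoint = raw$chamber_program$setpoint,
      duration_min = raw$chamber_program$duration_min
    )
  }
  for (nm in c("method_resid_scale", "method_offset", "method_gain")) {
    if (!is.null(raw[[nm]])) raw[[nm]] <- unlist(raw[[nm]])
  }
  do.call(experiment_config, raw)
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Overnight respirometry experiment configuration\n")
  cat(sprintf("  %d birds per method; methods: %s\n",
              x$n_birds_per_method, paste(x$methods, collapse = ", ")))
  cat(sprintf("  chamber program: %s degC for %s min\n",
              paste(x$chamber_program$setpoint, collapse = "/"),
              paste(x$chamber_program$duration_min, collapse = "/")))
  cat(sprintf("  cycle: %d + %d x %d + %d = %d min\n",
              x$baseline_min, x$birds_per_cycle, x$sample_min,
              x$baseline_min, cycle_length_min(x)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
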