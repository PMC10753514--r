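## Synthetic overnight experiments: multiplexed stop-flow respirometry traces,
## per-sensor body-temperature streams, bird metadata and a bench calibration
## fixture, with full ground truth retained for recovery testing.

#' Multiplexing schedule for one overnight run
#'
#' Expands the chamber program into a 1 Hz schedule: each chamber step is a
#' whole number of measurement cycles, and each cycle starts and ends with a
#' baseline, bracketing one sample per bird channel.
#'
#' @param cfg an [experiment_config()].
#' @return `data.table` with columns `t` (s from start), `setpoint` (degC),
#'   `cycle` (1-based cycle index), `channel` (0 = baseline, otherwise the
#'   bird channel 1..`birds_per_cycle`), and `seg_id` (unique contiguous
#'   segment identifier).
#' @export
make_schedule <- function(cfg) {
  validate_config(cfg)
  base_s <- cfg$baseline_min * 60
  samp_s <- cfg$sample_min * 60
  cyc_s <- cycle_length_min(cfg) * 60
  # within-cycle channel pattern: baseline, birds 1..k, baseline
  pattern <- c(rep(0L, base_s),
               rep(seq_len(cfg$birds_per_cycle), each = samp_s),
               rep(0L, base_s))
  seg_pattern <- c(rep(1L, base_s),
                   rep(1L + seq_len(cfg$birds_per_cycle), each = samp_s),
                   rep(cfg$birds_per_cycle + 2L, base_s))
  n_cycles_per_step <- cfg$chamber_program$duration_min / cycle_length_min(cfg)
  n_cycles <- sum(n_cycles_per_step)
  setpoint_per_cycle <- rep(cfg$chamber_program$setpoint, n_cycles_per_step)
  dt <- data.table::data.table(
    t = seq_len(n_cycles * cyc_s) - 1L,
    setpoint = rep(setpoint_per_cycle, each = cyc_s),
    cycle = rep(seq_len(n_cycles), each = cyc_s),
    channel = rep(pattern, n_cycles),
    seg_id = rep(seg_pattern, n_cycles) +
      rep((seq_len(n_cycles) - 1L) * (cfg$birds_per_cycle + 2L), each = cyc_s)
  )
  dt
}

# Ornstein-Uhlenbeck noise at 1 Hz: stationary sd 1, correlation time tau_s.
ou_noise <- function(n, tau_s) {
  phi <- exp(-1 / tau_s)
  innov <- stats::rnorm(n, 0, sqrt(1 - phi^2))
  innov[1] <- stats::rnorm(1)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

# First-order washout (mixing) filter with time constant tau_s, seeded at the
# first equilibrium value.
washout_filter <- function(x, tau_s) {
  if (tau_s <= 0) return(x)
  phi <- exp(-1 / tau_s)
  as.numeric(stats::filter((1 - phi) * x, phi, method = "recursive",
                           init = x[1]))
}

# Sum of K random-period sinusoids: a smooth stationary fluctuation with
# sd `sd_c` and periods drawn uniformly on `period_range_min`.
slow_fluctuation <- function(t, sd_c, k = 6, period_range_min = c(30, 90)) {
  periods <- stats::runif(k, period_range_min[1], period_range_min[2]) * 60
  phases <- stats::runif(k, 0, 2 * pi)
  amp <- sd_c * sqrt(2 / k)
  out <- numeric(length(t))
  for (i in seq_len(k)) {
    out <- out + amp * sin(2 * pi * t / periods[i] + phases[i])
  }
  out
}

# Oxy-joule equivalent (J per ml O2) / 60 -> W per (ml O2 min^-1)
oxyjoule_w_per_ml_min <- function(rq) (16 + 5.164 * rq) / 60

# True RMR (W) for a bird: multiplicative temperature chain on the mass-
# referenced baseline, additive mass and bird effects.
true_rmr_w <- function(cfg, setpoint, mass, bird_intercept) {
  ratio <- ifelse(setpoint == 25, 1,
                  ifelse(setpoint == 5, cfg$rmr_ratio_5v25,
                         cfg$rmr_ratio_5v25 * cfg$rmr_ratio_m15v5))
  cfg$rmr_base_25 * ratio + cfg$mass_slope * (mass - cfg$mass_ref) +
    bird_intercept
}

# True body-temperature level (degC) by method and chamber setpoint,
# excluding bird intercepts and fluctuations.
true_tb_level <- function(cfg, method, setpoint) {
  n <- max(length(method), length(setpoint))
  method <- rep_len(method, n)
  setpoint <- rep_len(setpoint, n)
  core <- ifelse(setpoint == 25, cfg$tb_core_25,
                 cfg$tb_core_25 - cfg$tb_drop_subTNZ)
  deficit <- numeric(n)
  cu <- method == "CU"
  deficit[cu & setpoint == 5] <- cfg$cu_deficit_5
  deficit[cu & setpoint == -15] <- cfg$cu_deficit_m15
  core - deficit
}

#' Generate the bench calibration fixture
#'
#' Emulates calibrating sensor units against the climate-chamber reference at
#' a small set of reference temperatures. Each unit carries its own offset and
#' gain; readings are `offset + gain * reference` plus noise.
#'
#' @param cfg an [experiment_config()].
#' @param units optional `data.frame` with columns `unit_id`, `method`,
#'   `offset`, `gain` describing the sensor units; when `NULL`,
#'   `calib_n_units` units are drawn from the configured per-method
#'   populations using the current RNG state (assigned to the four sensed
#'   methods in rotation).
#' @param noise_sd reading noise SD (degC); defaults to `cfg$calib_noise_sd`.
#' @return `data.table` with columns `unit_id`, `method`, `reference_c`,
#'   `reading` (one row per unit x reference temperature).
#' @export
generate_calibration_fixture <- function(cfg, units = NULL,
                                         noise_sd = cfg$calib_noise_sd) {
  sensed <- setdiff(cfg$methods, "C")
  if (is.null(units)) {
    if (cfg$calib_n_units < 1) stop("empty sensor list")
    m <- rep(sensed, length.out = cfg$calib_n_units)
    units <- data.frame(
      unit_id = sprintf("U%02d", seq_len(cfg$calib_n_units)),
      method = m,
      offset = cfg$method_offset[m] + stats::rnorm(cfg$calib_n_units, 0, cfg$unit_offset_sd),
      gain = stats::rnorm(cfg$calib_n_units, cfg$method_gain[m], cfg$unit_gain_sd)
    )
  }
  if (nrow(units) == 0) stop("empty sensor list")
  grid <- data.table::CJ(unit_id = units$unit_id, reference_c = cfg$calib_refs)
  grid <- merge(grid, data.table::as.data.table(units), by = "unit_id")
  grid[, `:=`(reading = offset + gain * reference_c +
                stats::rnorm(.N, 0, noise_sd))]
  out <- grid[, list(unit_id, method, reference_c, reading)]
  data.table::setorder(out, unit_id, reference_c)
  out[]
}

#' Generate a complete synthetic experiment
#'
#' Produces everything one field season of the emulated study would yield:
#' per-bird metadata, 1 Hz multiplexed gas-analyzer traces for every
#' overnight run (one bird per method per night), 1 Hz body-temperature
#' streams per instrumented bird, and the bench calibration fixture. Ground
#' truth (true RMR per bird and ambient temperature, true temperature levels,
#' injected misread times, sensor miscalibrations, quiescent-plateau
#' placements, analyzer drift) is retained for recovery testing.
#'
#' Gas streams carry analyzer noise, slow baseline drift (linear + sinusoid)
#' and a first-order washout at channel switches. PIT-tag streams (IP/SC) are
#' recorded at 0.1 degC resolution and may contain isolated misread spikes
#' >45 degC; thermocouple streams (CL/CU) are continuous but only store
#' values inside the configured recording window. Control birds emit no
#' temperature stream.
#'
#' @param cfg an [experiment_config()]; `cfg$seed` fixes all randomness.
#' @return list of class `"tb_experiment"` with elements `birds`, `gas`,
#'   `temps`, `calib`, `truth`, `config`.
#' @export
generate_experiment <- function(cfg = experiment_config()) {
  validate_config(cfg)
  set.seed(cfg$seed)
  n_runs <- cfg$n_birds_per_method
  methods <- cfg$methods
  sensed <- setdiff(methods, "C")

  ## ---- birds ----
  birds <- data.table::rbindlist(lapply(seq_len(n_runs), function(r) {
    data.table::data.table(run = r, method = methods,
                           channel = sample(cfg$birds_per_cycle))
  }))
  data.table::setorder(birds, run, channel)
  birds[, bird_id := sprintf("B%03d", .I)]
  n_birds <- nrow(birds)
  ## capture mass sits ~0.3 g above the measurement (pre-respirometry) mass,
  ## which is centred on mass_mean — the reference scale of the RMR model
  birds[, mass_capture := round(pmin(24.5, pmax(10.5,
    stats::rnorm(n_birds, cfg$mass_mean + 0.3, cfg$mass_sd))), 1)]
  birds[, mass_pre := round(mass_capture - abs(stats::rnorm(n_birds, 0.3, 0.1)), 1)]
  birds[, mass_post := round(mass_pre - stats::rnorm(n_birds, 0.8, 0.15), 1)]
  birds[, age := sample(c("2cy", "3cy+"), n_birds, replace = TRUE)]
  birds[, sex := sample(c("F", "M"), n_birds, replace = TRUE)]

  ## ---- bird-level latent parameters ----
  lat <- data.table::data.table(
    bird_id = birds$bird_id,
    method = birds$method,
    rmr_intercept = stats::rnorm(n_birds, 0, cfg$rmr_bird_sd),
    tb_intercept = stats::rnorm(n_birds, 0, cfg$tb_bird_sd),
    rq = pmin(1.0, pmax(0.70, stats::rnorm(n_birds, cfg$rq_mean, cfg$rq_sd)))
  )
  is_sensed <- lat$method %in% sensed
  m_off <- ifelse(is_sensed, cfg$method_offset[lat$method], 0)
  m_gain <- ifelse(is_sensed, cfg$method_gain[lat$method], 1)
  lat[, sensor_offset := m_off + stats::rnorm(n_birds, 0, cfg$unit_offset_sd)]
  lat[, sensor_gain := stats::rnorm(n_birds, m_gain, cfg$unit_gain_sd)]
  lat[!is_sensed, `:=`(sensor_offset = NA_real_, sensor_gain = NA_real_)]

  ## ---- true RMR per bird x ambient temperature ----
  setpoints <- unique(cfg$chamber_program$setpoint)
  rmr_truth <- data.table::CJ(bird_id = birds$bird_id, t_air = setpoints)
  rmr_truth <- merge(rmr_truth, birds[, list(bird_id, method, mass_pre)],
                     by = "bird_id")
  rmr_truth <- merge(rmr_truth, lat[, list(bird_id, rmr_intercept)],
                     by = "bird_id")
  rmr_truth[, rmr_true_w := true_rmr_w(cfg, t_air, mass_pre, rmr_intercept)]

  ## ---- calibration fixture ----
  calib <- generate_calibration_fixture(cfg)

  ## ---- gas traces ----
  sched <- make_schedule(cfg)
  n_sec <- nrow(sched)
  g_i_fact <- 1 - cfg$fico2
  gas_list <- vector("list", n_runs)
  plateau_list <- vector("list", n_runs)
  drift_list <- vector("list", n_runs)
  oxy <- oxyjoule_w_per_ml_min(lat$rq)
  names(oxy) <- lat$bird_id
  for (r in seq_len(n_runs)) {
    fri <- max(50, stats::rnorm(1, cfg$flow_mean, cfg$flow_sd))
    gi <- fri * g_i_fact
    run_birds <- birds[run == r]
    ## per-cycle quiescent levels and plateau placement
    segs <- unique(sched[channel > 0L, list(cycle, setpoint, channel, seg_id)])
    segs <- merge(segs, run_birds[, list(channel, bird_id, method)],
                  by = "channel")
    segs <- merge(segs,
                  rmr_truth[, list(bird_id, t_air, rmr_true_w)],
                  by.x = c("bird_id", "setpoint"), by.y = c("bird_id", "t_air"))
    data.table::setorder(segs, cycle, channel)
    resid_scale <- cfg$rmr_cycle_cv * cfg$method_resid_scale[segs$method]
    segs[, level_w := rmr_true_w * (1 + stats::rnorm(.N, 0, resid_scale))]
    samp_s <- cfg$sample_min * 60
    plat_s <- cfg$plateau_min * 60
    segs[, plateau_start := 60L + sample.int(samp_s - plat_s - 60L, .N,
                                             replace = TRUE) - 1L]
    ## per-second true metabolic signal of the active bird
    seg_start <- sched[, list(t0 = min(t)), by = seg_id]
    segs <- merge(segs, seg_start, by = "seg_id")
    act <- 0.10 + 0.25 * abs(ou_noise(n_sec, 30))
    vo2 <- numeric(n_sec)  # ml O2 min^-1, 0 during baselines
    rqv <- rep(cfg$rq_mean, n_sec)
    for (i in seq_len(nrow(segs))) {
      idx <- segs$t0[i] + seq_len(samp_s) - 1L  # 0-based t == row-1
      rows <- idx + 1L
      w <- segs$level_w[i] * (1 + act[rows])
      pl <- segs$plateau_start[i] + seq_len(plat_s)
      w[pl] <- segs$level_w[i]
      vo2[rows] <- w / oxy[segs$bird_id[i]]
      rqv[rows] <- lat$rq[match(segs$bird_id[i], lat$bird_id)]
    }
    vco2 <- rqv * vo2
    active <- sched$channel > 0L
    ## equilibrium analyzer-basis fractions
    feo2_eq <- ifelse(active, (gi * cfg$fio2 - vo2) / (gi - vo2), cfg$fio2)
    feco2_dry_eq <- ifelse(active,
                           (fri * cfg$fico2 + vco2) / (fri - vo2 + vco2),
                           cfg$fico2)
    wvp_eq <- ifelse(active, cfg$wvp_bird_kpa, cfg$wvp_baseline_kpa)
    feco2_wet_eq <- feco2_dry_eq * (cfg$bp_kpa - wvp_eq) / cfg$bp_kpa
    ## washout, drift, noise
    feo2_s <- washout_filter(feo2_eq, cfg$washout_tau_s)
    feco2_s <- washout_filter(feco2_wet_eq, cfg$washout_tau_s)
    wvp_s <- washout_filter(wvp_eq, cfg$washout_tau_s)
    ph_o2 <- stats::runif(1, 0, 2 * pi)
    ph_co2 <- stats::runif(1, 0, 2 * pi)
    tt <- sched$t
    d_o2 <- cfg$drift_linear * (tt / n_sec - 0.5) +
      cfg$drift_sine_amp * sin(2 * pi * tt / cfg$drift_sine_period_s + ph_o2)
    d_co2 <- 0.25 * cfg$drift_linear * (tt / n_sec - 0.5) +
      0.25 * cfg$drift_sine_amp *
        sin(2 * pi * tt / cfg$drift_sine_period_s + ph_co2)
    gas_list[[r]] <- data.table::data.table(
      run = r, t = tt, setpoint = sched$setpoint, cycle = sched$cycle,
      channel = sched$channel, seg_id = sched$seg_id,
      FeO2 = feo2_s + d_o2 + stats::rnorm(n_sec, 0, cfg$o2_noise_sd),
      FeCO2_wet = feco2_s + d_co2 + stats::rnorm(n_sec, 0, cfg$co2_noise_sd),
      wvp_kpa = pmax(0, wvp_s + stats::rnorm(n_sec, 0, 0.002)),
      bp_kpa = cfg$bp_kpa,
      fri = fri
    )
    plateau_list[[r]] <- segs[, list(run = r, cycle, setpoint, channel,
                                     bird_id, seg_id, t0, plateau_start,
                                     level_w, rmr_true_w)]
    drift_list[[r]] <- data.table::data.table(run = r, phase_o2 = ph_o2,
                                              phase_co2 = ph_co2, fri = fri)
  }
  gas <- data.table::rbindlist(gas_list)

  ## ---- temperature streams ----
  tb_levels <- data.table::CJ(bird_id = birds$bird_id, t_air = setpoints)
  tb_levels <- merge(tb_levels, birds[, list(bird_id, method)], by = "bird_id")
  tb_levels <- merge(tb_levels, lat[, list(bird_id, tb_intercept)],
                     by = "bird_id")
  tb_levels <- tb_levels[method != "C"]
  tb_levels[, tb_true := true_tb_level(cfg, method, t_air) + tb_intercept]

  setpoint_sec <- sched$setpoint
  temp_list <- list()
  misread_list <- list()
  for (b in which(is_sensed)) {
    bid <- birds$bird_id[b]
    m <- birds$method[b]
    r <- birds$run[b]
    sensor <- if (m %in% c("IP", "SC")) "PIT" else "thermocouple"
    slow_sd <- cfg$tb_slow_sd * if (m == "CU") cfg$cu_noise_scale else 1
    jit_sd <- cfg$tb_jitter_sd * if (m == "CL") cfg$cl_jitter_scale else 1
    level <- true_tb_level(cfg, m, setpoint_sec) + lat$tb_intercept[b]
    slow <- slow_fluctuation(sched$t, slow_sd)
    n_min <- ceiling(n_sec / 60)
    jitter <- rep(stats::rnorm(n_min, 0, jit_sd), each = 60)[seq_len(n_sec)]
    tb_true_sec <- level + slow + jitter
    reading <- lat$sensor_offset[b] + lat$sensor_gain[b] * tb_true_sec
    if (sensor == "PIT") {
      reading <- round(reading, 1)
      keep <- rep(TRUE, n_sec)
      mis_t <- integer(0)
      if (cfg$misread_rate > 0) {
        cand <- which(stats::runif(n_sec) < cfg$misread_rate)
        if (length(cand) > 1) {  # enforce isolation: >120 s apart
          cand <- cand[c(TRUE, diff(cand) > 120)]
        }
        if (length(cand) > 0) {
          reading[cand] <- round(stats::runif(length(cand), 46, 50), 1)
          mis_t <- sched$t[cand]
        }
      }
      dt <- data.table::data.table(run = r, bird_id = bid, method = m,
                                   sensor = sensor, t = sched$t,
                                   temp = reading)
      if (length(mis_t) > 0) {
        misread_list[[bid]] <- data.table::data.table(bird_id = bid,
                                                      t = mis_t)
      }
    } else {
      keep <- reading >= cfg$tc_range[1] & reading <= cfg$tc_range[2]
      dt <- data.table::data.table(run = r, bird_id = bid, method = m,
                                   sensor = sensor, t = sched$t[keep],
                                   temp = reading[keep])
    }
    temp_list[[bid]] <- dt
  }
  temps <- data.table::rbindlist(temp_list)
  misreads <- if (length(misread_list)) data.table::rbindlist(misread_list)
              else data.table::data.table(bird_id = character(0), t = integer(0))

  out <- list(
    birds = birds[],
    gas = gas,
    temps = temps,
    calib = calib,
    truth = list(
      rmr = rmr_truth[, list(bird_id, method, t_air, mass_pre, rmr_true_w)],
      tb_levels = tb_levels[, list(bird_id, method, t_air, tb_true)],
      plateaus = data.table::rbindlist(plateau_list),
      misreads = misreads,
      sensors = lat[, list(bird_id, method, sensor_offset, sensor_gain)],
      runs = data.table::rbindlist(drift_list),
      latent = lat[]
    ),
    config = cfg
  )
  class(out) <- "tb_experiment"
  out
}

#' @export
print.tb_experiment <- function(x, ...) {
  cat(sprintf("Synthetic overnight experiment: %d birds (%d per method), %d runs\n",
              nrow(x$birds), x$config$n_birds_per_method,
              max(x$birds$run)))
  cat(sprintf("  gas samples: %s; temperature samples: %s\n",
              format(nrow(x$gas), big.mark = ","),
              format(nrow(x$temps), big.mark = ",")))
  cat(sprintf("  seed: %d\n", x$config$seed))
  invisible(x)
}
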