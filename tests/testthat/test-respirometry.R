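test_that("mathematical water scrubbing matches the dilution formula", {
  expect_equal(scrub_water_math(0.004, 0, 101), 0.004)
  expect_equal(scrub_water_math(0.004, 1.0, 101.0), 0.004 * 101 / 100,
               tolerance = 1e-12)
  expect_equal(scrub_water_math(0, 2.2, 101.3), 0)
  # exact inverse of wet dilution
  f_dry <- 0.0037
  f_wet <- f_dry * (101.3 - 1.8) / 101.3
  expect_equal(scrub_water_math(f_wet, 1.8, 101.3), f_dry, tolerance = 1e-12)
  expect_error(scrub_water_math(0.004, 101.3, 101.3), "below barometric")
  expect_error(scrub_water_math(0.004, -1, 101.3), "non-negative")
})

test_that("gas-exchange equations match an independent transcription", {
  # no gas exchange: every flow-through variant returns zero
  r0 <- compute_gas_rates(600, 0.2095, 0.2095, 0.0004, 0.0004)
  expect_equal(r0$vo2, 0)
  expect_equal(r0$vco2, 0)
  # hand transcription of the printed equations, written out literally
  fri <- 600; fio2 <- 0.2095; fico2 <- 0; feo2 <- 0.2065; feco2 <- 0.0030
  vo2_hand <- 600 * (1 - 0) * (0.2095 - 0.2065) / (1 - 0.2065)
  vco2_hand <- (600 * (0.0030 - 0) - 0.0030 * vo2_hand) / (1 - 0.0030)
  r <- compute_gas_rates(fri, fio2, feo2, fico2, feco2)
  expect_equal(r$vo2, vo2_hand, tolerance = 1e-9)
  expect_equal(r$vco2, vco2_hand, tolerance = 1e-9)
  # linearity in flow
  r2 <- compute_gas_rates(2 * fri, fio2, feo2, fico2, feco2)
  expect_equal(r2$vo2, 2 * r$vo2, tolerance = 1e-12)
  expect_equal(r2$vco2, 2 * r$vco2, tolerance = 1e-12)
  expect_error(compute_gas_rates(-1, fio2, feo2, fico2, feco2), "positive")
  expect_error(compute_gas_rates(600, 1.2, feo2, fico2, feco2), "fractions")
})

test_that("oxy-joule conversion behaves as printed", {
  expect_equal(to_watts(0, 0.8), 0)
  expect_equal(suppressWarnings(to_watts(0, 1.4)), 0)  # zero consumption, any RQ
  # 1 ml O2 / min at RQ = 1: (16 + 5.164) J/ml / 60 s
  expect_equal(to_watts(1, 1.0), (16 + 5.164) / 60, tolerance = 1e-12)
  v <- seq(0.1, 2, by = 0.1)
  expect_true(all(diff(to_watts(v, 0.75)) > 0))
  expect_warning(to_watts(1, 1.3), "outside")
  expect_warning(to_watts(1, 0.6), "outside")
  expect_error(to_watts(-0.1, 0.8), "non-negative")
})

test_that("baseline interpolation is exact for constant and linear drift", {
  # hand-built single cycle: two constant baselines around one bird segment
  base1 <- 0.2095; base2 <- 0.2093
  n <- 4800
  channel <- c(rep(0L, 900), rep(1:5, each = 600), rep(0L, 900))
  trace <- data.frame(
    t = 0:(n - 1), cycle = 1L, channel = channel, setpoint = 25,
    FeO2 = 0.2065, FeCO2_wet = 0.003, wvp_kpa = 0, bp_kpa = 101.3,
    fri = 600)
  # first baseline samples base1, second base2
  trace$FeO2[trace$channel == 0L & trace$t < 900] <- base1
  trace$FeO2[trace$channel == 0L & trace$t >= 3900] <- base2
  corr <- correct_baseline_drift(trace)
  # baseline midpoints (full 15 min, trimmed 60 s each end -> same midpoint)
  t_lo <- mean(0:899); t_hi <- mean(3900:4799)
  at <- function(tt) base1 + (tt - t_lo) / (t_hi - t_lo) * (base2 - base1)
  for (tt in c(1500, 2400, 3000)) {
    expect_equal(corr$FiO2[corr$t == tt], at(tt), tolerance = 1e-12)
  }
  # constant-baseline case: identical baselines give a constant reference
  trace2 <- trace
  trace2$FeO2[trace2$channel == 0L] <- base1
  corr2 <- correct_baseline_drift(trace2)
  expect_equal(unique(corr2$FiO2), base1, tolerance = 1e-12)
})

test_that("drift correction recovers the injected analyzer drift", {
  cfg <- small_config(seed = 31)
  exp <- generate_experiment(cfg)
  corr <- correct_baseline_drift(exp$gas)
  # truth: configured linear + sinusoid drift on the incurrent O2 reading
  n_sec <- nrow(make_schedule(cfg))
  runs <- exp$truth$runs
  bird_rows <- corr[corr$channel != 0L, ]
  ph <- runs$phase_o2[match(bird_rows$run, runs$run)]
  fio2_true <- cfg$fio2 + cfg$drift_linear * (bird_rows$t / n_sec - 0.5) +
    cfg$drift_sine_amp * sin(2 * pi * bird_rows$t / cfg$drift_sine_period_s + ph)
  resid <- bird_rows$FiO2 - fio2_true
  expect_lt(max(abs(resid)), cfg$o2_noise_sd)  # within analyzer noise amplitude
})

test_that("missing bracketing baselines are reported with the cycle", {
  trace <- data.frame(t = 0:1199, cycle = 2L, run = 1L,
                      channel = c(rep(0L, 600), rep(1L, 600)),
                      setpoint = 25, FeO2 = 0.2095, FeCO2_wet = 3e-4,
                      wvp_kpa = 0, bp_kpa = 101.3, fri = 600)
  expect_error(correct_baseline_drift(trace), "cycle 2.*baselines")
})

test_that("noise-free end-to-end gas recovery is exact to within 0.1%", {
  cfg <- small_config(seed = 17, o2_noise_sd = 0, co2_noise_sd = 0,
                      drift_linear = 0, drift_sine_amp = 0,
                      rmr_cycle_cv = 0, misread_rate = 0)
  exp <- generate_experiment(cfg)
  proc <- process_experiment(exp)
  est <- merge(proc$estimates, exp$truth$rmr[, c("bird_id", "t_air",
                                                 "rmr_true_w")],
               by = c("bird_id", "t_air"))
  expect_lt(max(abs(est$rmr_w / est$rmr_true_w - 1)), 1e-3)
})
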