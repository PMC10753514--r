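test_that("multiplexing schedule has the stated cycle structure", {
  cfg <- experiment_config()
  sched <- make_schedule(cfg)
  expect_equal(cycle_length_min(cfg), 80)
  # whole night: 4 x 160 min + 80 min = 9 cycles of 80 min at 1 Hz
  expect_equal(nrow(sched), 9 * 80 * 60)
  expect_equal(max(sched$cycle), 9)
  one <- sched[sched$cycle == 1, ]
  # exactly two baseline segments bracketing five 10-min bird segments
  segs <- rle(one$channel)
  expect_equal(segs$values, c(0L, 1:5, 0L))
  expect_equal(segs$lengths, c(900L, rep(600L, 5), 900L))
  # chamber program order and durations
  sp <- rle(sched$setpoint)
  expect_equal(sp$values, c(25, 5, -15, 5, 25))
  expect_equal(sp$lengths / 60, c(160, 160, 160, 160, 80))
})

test_that("generation is reproducible for a fixed seed and varies across seeds", {
  a <- generate_experiment(small_config(seed = 11))
  b <- generate_experiment(small_config(seed = 11))
  c <- generate_experiment(small_config(seed = 12))
  expect_identical(a$gas, b$gas)
  expect_identical(a$temps, b$temps)
  expect_identical(a$birds, b$birds)
  expect_identical(a$calib, b$calib)
  expect_false(identical(a$gas$FeO2, c$gas$FeO2))
  expect_false(identical(a$temps$temp, c$temps$temp))
})

test_that("misread channel can be disabled and is bookkept when active", {
  clean <- generate_experiment(small_config(seed = 3, misread_rate = 0))
  pit <- clean$temps[clean$temps$sensor == "PIT", ]
  expect_true(all(pit$temp <= 45))
  expect_equal(nrow(clean$truth$misreads), 0)

  spiky <- generate_experiment(small_config(seed = 3, misread_rate = 2e-4))
  expect_gt(nrow(spiky$truth$misreads), 0)
  pit2 <- data.table::as.data.table(spiky$temps)[sensor == "PIT"]
  n_high <- nrow(pit2[temp > 45])
  expect_equal(n_high, nrow(spiky$truth$misreads))
  expect_true(all(spiky$truth$misreads$t %in% pit2[temp > 45]$t))
})

test_that("retained ground truth follows the configured physiological model", {
  exp <- generate_experiment(small_config(seed = 21))
  cfg <- exp$config
  tr <- merge(exp$truth$rmr, exp$truth$latent[, c("bird_id", "rmr_intercept")],
              by = "bird_id")
  ratio <- ifelse(tr$t_air == 25, 1,
                  ifelse(tr$t_air == 5, cfg$rmr_ratio_5v25,
                         cfg$rmr_ratio_5v25 * cfg$rmr_ratio_m15v5))
  expected <- cfg$rmr_base_25 * ratio +
    cfg$mass_slope * (tr$mass_pre - cfg$mass_ref) + tr$rmr_intercept
  expect_equal(tr$rmr_true_w, expected, tolerance = 1e-12)
  # cutaneous deficit below thermoneutrality, relative to same-bird core level
  tb <- exp$truth$tb_levels
  lat <- exp$truth$latent
  for (i in which(tb$method == "CU" & tb$t_air != 25)) {
    core <- cfg$tb_core_25 - cfg$tb_drop_subTNZ +
      lat$tb_intercept[lat$bird_id == tb$bird_id[i]]
    deficit <- if (tb$t_air[i] == 5) cfg$cu_deficit_5 else cfg$cu_deficit_m15
    expect_equal(tb$tb_true[i], core - deficit, tolerance = 1e-12)
  }
})

test_that("thermocouple streams only contain values inside the recording window", {
  exp <- generate_experiment(small_config(seed = 9))
  tc <- exp$temps[exp$temps$sensor == "thermocouple", ]
  expect_true(all(tc$temp >= 30 & tc$temp <= 50))
  # control birds emit no temperature stream
  ctrl <- exp$birds$bird_id[exp$birds$method == "C"]
  expect_false(any(exp$temps$bird_id %in% ctrl))
})

test_that("calibration fixture has the designed layout and honest sensors", {
  cfg <- experiment_config(seed = 2)
  set.seed(2)
  fx <- generate_calibration_fixture(cfg)
  expect_equal(nrow(fx), 33 * 3)
  expect_equal(length(unique(fx$unit_id)), 33)
  expect_setequal(unique(fx$reference_c), c(35, 40, 45))

  ident <- data.frame(unit_id = "U1", method = "IP", offset = 0, gain = 1)
  fx0 <- generate_calibration_fixture(cfg, units = ident, noise_sd = 0)
  expect_equal(fx0$reading, fx0$reference_c)

  off <- data.frame(unit_id = "U1", method = "IP", offset = 0.5, gain = 1)
  fx1 <- generate_calibration_fixture(cfg, units = off, noise_sd = 0)
  expect_equal(fx1$reading, fx1$reference_c + 0.5)

  expect_error(generate_calibration_fixture(cfg, units = ident[0, ]),
               "empty sensor list")
})

test_that("invalid configurations are rejected", {
  expect_error(experiment_config(baseline_min = -1), "positive")
  expect_error(experiment_config(rmr_ratio_5v25 = 0.9), "ratios")
  expect_error(experiment_config(cu_deficit_5 = -1), "deficits")
  expect_error(experiment_config(misread_rate = 1.5), "misread_rate")
  expect_error(experiment_config(n_birds_per_method = 0), "positive count")
  expect_error(
    experiment_config(chamber_program = data.frame(setpoint = 25,
                                                   duration_min = 90)),
    "whole")
})
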