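test_that("stablest window matches exhaustive search on short segments", {
  set.seed(99)
  for (n in c(150, 300, 480, 600)) {
    x <- 0.2 + 0.05 * abs(rnorm(n)) + 0.01 * sin(seq_len(n) / 40)
    got <- find_stablest_window(x, 120)
    oracle <- brute_force_window(x, 120)
    expect_identical(got$start, oracle$start)
    expect_equal(got$mean, oracle$mean, tolerance = 1e-12)
    expect_equal(got$sd, oracle$sd, tolerance = 1e-10)
  }
})

test_that("an injected quiescent plateau is found", {
  set.seed(5)
  for (rep in 1:5) {
    x <- 0.25 * (1 + 0.1 + 0.25 * abs(rnorm(600)))
    start <- sample(60:420, 1)
    x[start:(start + 179)] <- 0.25
    win <- find_stablest_window(x, 120)
    expect_gte(win$start, start)
    expect_lte(win$end, start + 179)
    expect_equal(win$mean, 0.25, tolerance = 1e-12)
  }
})

test_that("window edge cases follow the tie-break and width rules", {
  const <- rep(0.3, 400)
  win <- find_stablest_window(const, 120)
  expect_equal(win$start, 1L)  # earliest window on ties
  expect_equal(win$mean, 0.3)
  expect_equal(win$sd, 0)
  exact <- rnorm(120)
  w2 <- find_stablest_window(exact, 120)
  expect_equal(w2$start, 1L)
  expect_equal(w2$mean, mean(exact), tolerance = 1e-12)
  expect_error(find_stablest_window(rnorm(119), 120), "shorter")
})

make_rates <- function(levels_by_cycle) {
  # one bird on channel 1, segments of 600 s, one per cycle
  do.call(rbind, lapply(seq_along(levels_by_cycle), function(cy) {
    data.frame(run = 1L, t = (cy - 1) * 4800 + 900 + 0:599, setpoint = 25,
               cycle = cy, channel = 1L, seg_id = cy,
               vo2 = levels_by_cycle[cy] * 60 / 20,
               vco2 = 0.8 * levels_by_cycle[cy] * 60 / 20,
               rq = 0.8, watts = levels_by_cycle[cy])
  }))
}

test_that("RMR is the minimum stable-window mean across cycles", {
  birds <- data.frame(run = 1L, channel = 1L, bird_id = "B1", method = "IP")
  est <- extract_rmr(make_rates(c(0.30, 0.28)), birds)
  expect_equal(nrow(est), 1)
  expect_equal(est$rmr_w, 0.28)
  expect_equal(est$cycle, 2)
  expect_equal(est$n_cycles, 2)
  expect_equal(est$win_end - est$win_start + 1, 120)
  # single cycle: that window is the estimate
  est1 <- extract_rmr(make_rates(0.31), birds)
  expect_equal(est1$rmr_w, 0.31)
  expect_equal(est1$n_cycles, 1)
})

test_that("lowering a sample never raises the extracted RMR", {
  set.seed(123)
  for (rep in 1:10) {
    x <- 0.3 + 0.05 * abs(rnorm(300))
    base <- brute_force_window(x, 120)
    i <- sample(300, 1)
    x2 <- x
    x2[i] <- x2[i] - runif(1, 0, 0.1)
    # min over all windows of the mean can only decrease or stay
    means <- function(v) {
      vapply(seq_len(181), function(s) mean(v[s:(s + 119)]), 0)
    }
    expect_lte(min(means(x2)), min(means(x)) + 1e-12)
  }
})

test_that("body temperature is matched over the closed window, with fallback", {
  est <- data.table::data.table(bird_id = "B1", method = "IP", t_air = 25,
                                cycle = 1L, win_start = 1000L,
                                win_end = 1119L, vo2 = 1, vco2 = 0.8,
                                rq = 0.8, rmr_w = 0.3, n_cycles = 1L)
  ser <- data.frame(bird_id = "B1", t = 1000:1119,
                    temp = rep(c(37.8, 38.0), 60), flag = "ok")
  out <- match_tb(est, ser)
  expect_equal(out$tb_mean, 37.9)
  expect_false(out$tb_fallback)
  expect_equal(out$tb_n, 120L)
  # boundary readings are included (closed interval)
  edge <- data.frame(bird_id = "B1", t = c(1000, 1119), temp = c(37, 39),
                     flag = "ok")
  out2 <- match_tb(est, edge)
  expect_equal(out2$tb_mean, 38)
  expect_equal(out2$tb_n, 2L)
  # no reading inside: nearest single measurement, flagged as fallback
  far <- data.frame(bird_id = "B1", t = 640, temp = 37.4, flag = "ok")
  out3 <- match_tb(est, far)  # 360 s before the window start
  expect_equal(out3$tb_mean, 37.4)
  expect_true(out3$tb_fallback)
  # empty series: missing
  none <- data.frame(bird_id = "B2", t = 1, temp = 37, flag = "ok")
  out4 <- match_tb(est, none)
  expect_true(is.na(out4$tb_mean))
})
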