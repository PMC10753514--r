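test_that("AICc matches the closed form and converges to AIC", {
  expect_equal(aicc(-50, 2, 100), 104 + 12 / 97, tolerance = 1e-12)
  # the small-sample correction vanishes as n grows
  aic <- -2 * (-50) + 2 * 2
  expect_lt(abs(aicc(-50, 2, 1e8) - aic), 1e-6)
  expect_true(all(diff(sapply(c(1e2, 1e4, 1e6), function(n)
    aicc(-50, 2, n) - aic)) < 0))
  expect_error(aicc(-50, 10, 11), "undefined")
})

test_that("Welch ANOVA matches oneway.test and the two-group t-test", {
  set.seed(6)
  vals <- c(rnorm(10, 0, 1), rnorm(12, 0.5, 2), rnorm(9, 1, 3),
            rnorm(11, 0, 0.5))
  grp <- rep(c("a", "b", "c", "d"), c(10, 12, 9, 11))
  ours <- welch_anova(vals, grp)
  ref <- oneway.test(vals ~ factor(grp), var.equal = FALSE)
  expect_equal(ours$F, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(ours$df2, unname(ref$parameter["denom df"]), tolerance = 1e-9)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  # k = 2 reduces to Welch's t: F = t^2
  two <- grp %in% c("a", "b")
  w2 <- welch_anova(vals[two], grp[two])
  tt <- t.test(vals[grp == "a"], vals[grp == "b"])
  expect_equal(w2$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(w2$p, tt$p.value, tolerance = 1e-9)
  # equal group means give F = 0
  null_vals <- rep(c(1, 2, 3), 4)
  null_grp <- rep(c("a", "b", "c", "d"), each = 3)
  expect_equal(welch_anova(null_vals, null_grp)$F, 0)
  expect_error(welch_anova(rep(1, 6), rep(c("a", "b"), 3)), "variance")
})

test_that("Games-Howell reduces to the Welch t-test for two groups", {
  set.seed(7)
  x <- rnorm(13, 0, 1); y <- rnorm(13, 0.8, 2.5)
  gh <- games_howell(c(x, y), rep(c("a", "b"), each = 13))
  tt <- t.test(x, y)
  expect_equal(nrow(gh), 1)
  expect_equal(gh$df, unname(tt$parameter), tolerance = 1e-9)
  expect_equal(gh$p, tt$p.value, tolerance = 1e-9)
  # near-identical groups: p close to 1
  same <- c(rnorm(10), rnorm(10), rnorm(10))
  gh3 <- games_howell(same, rep(c("a", "b", "c"), each = 10))
  expect_equal(nrow(gh3), 3)
  expect_true(all(gh3$df > 0))
})

test_that("balance checks agree with hand-computed chi-square and ANOVA", {
  birds <- data.frame(
    method = rep(c("IP", "CL", "SC", "CU", "C"), each = 4),
    mass_capture = rep(c(17, 17.5, 16.5, 17.2), 5),
    mass_pre = rep(c(16.8, 17.1, 16.2, 17.0), 5),
    mass_post = rep(c(16.0, 16.4, 15.5, 16.1), 5),
    age = rep(c("2cy", "2cy", "3cy+", "3cy+"), 5),
    sex = c(rep(c("F", "M"), 10)))
  rep_check <- balance_checks(birds)
  # identical mass distributions across methods: F = 0
  expect_equal(rep_check$mass$F, rep(0, 3), tolerance = 1e-12)
  expect_equal(rep_check$mass$p, rep(1, 3), tolerance = 1e-12)
  # perfectly balanced age x method table: chi-square = 0
  expect_equal(rep_check$age$statistic, 0, tolerance = 1e-12)
  expect_equal(rep_check$age$p, 1)
  # hand-computed Pearson chi-square for an unbalanced 2 x 5 table
  birds2 <- birds
  birds2$age <- c(rep("2cy", 7), rep("3cy+", 13))
  tab <- table(birds2$age, birds2$method)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  chi_hand <- sum((tab - expected)^2 / expected)
  expect_equal(suppressWarnings(balance_checks(birds2))$age$statistic,
               chi_hand, tolerance = 1e-9)
})

test_that("model selection finds the temperature-dependent method effect", {
  sel_tb <- cached_selection("tb_mean")
  expect_true(sel_tb$best %in% c("method_x_tair", "both_interactions"))
  # the method x ambient temperature interaction must be in the winner
  expect_true(grepl("method:t_air", deparse(sel_tb$formula)[
    length(deparse(sel_tb$formula))]) ||
      any(grepl("method:t_air", deparse(sel_tb$formula))))
  expect_true(all(sel_tb$aicc_table$converged))
  expect_equal(sel_tb$aicc_table$dAICc[which.min(sel_tb$aicc_table$aicc)], 0)
  # RMR was generated with no method effect: the no-interaction model is
  # never strongly rejected
  sel_rmr <- cached_selection("rmr_w")
  expect_lt(sel_rmr$aicc_table$dAICc[
    sel_rmr$aicc_table$model == "no_interaction"], 6)
  # AICc values agree with a direct computation from the ML logLik
  tab <- sel_rmr$aicc_table
  n <- nrow(sel_rmr$data)
  expect_equal(tab$aicc,
               -2 * tab$logLik + 2 * tab$k +
                 2 * tab$k * (tab$k + 1) / (n - tab$k - 1),
               tolerance = 1e-9)
})

test_that("marginal means and contrasts match the emmeans package", {
  skip_if_not_installed("emmeans")
  sel <- cached_selection("tb_mean")
  ours <- emmeans_grid(sel, c("method", "t_air"))
  ref <- as.data.frame(emmeans::emmeans(sel$fit, ~ method * t_air,
                                        data = sel$data,
                                        mode = "containment"))
  key_ours <- paste(ours$method, ours$t_air)
  key_ref <- paste(ref$method, ref$t_air)
  idx <- match(key_ours, key_ref)
  expect_equal(ours$emmean, ref$emmean[idx], tolerance = 1e-6)
  expect_equal(ours$se, ref$SE[idx], tolerance = 1e-6)
  # contrast estimates match emmeans pairwise within ambient temperature
  ctr <- pairwise_contrasts(ours, by = "t_air")
  ref_ctr <- as.data.frame(
    emmeans::contrast(emmeans::emmeans(sel$fit, ~ method | t_air,
                                       data = sel$data),
                      method = "pairwise", adjust = "none"))
  ref_key <- paste(gsub(" - ", " - ", ref_ctr$contrast), ref_ctr$t_air)
  our_key <- paste(ctr$contrast, ctr$t_air)
  idx2 <- match(our_key, ref_key)
  expect_false(any(is.na(idx2)))
  expect_equal(ctr$estimate, ref_ctr$estimate[idx2], tolerance = 1e-6)
  expect_equal(ctr$se, ref_ctr$SE[idx2], tolerance = 1e-6)
  # Bonferroni arithmetic: within-family m * p, capped at 1
  m <- sum(ctr$t_air == ctr$t_air[1])
  expect_equal(ctr$p_adj, pmin(1, m * ctr$p_raw), tolerance = 1e-12)
})

test_that("Wald chi-square tests match car::Anova on the additive model", {
  skip_if_not_installed("car")
  sel <- cached_selection("rmr_w")
  ours <- wald_chisq(sel)
  ref <- car::Anova(sel$fit, type = "III")
  idx <- match(ours$term, rownames(ref))
  keep <- !is.na(idx)
  expect_true(sum(keep) >= 4)
  expect_equal(ours$chisq[keep], ref$Chisq[idx[keep]], tolerance = 1e-6)
  expect_equal(ours$df[keep], ref$Df[idx[keep]])
})

test_that("the random bird intercept is supported by the LRT", {
  sel <- cached_selection("rmr_w")
  lrt <- random_effect_lrt(sel)
  expect_gt(lrt$stat, 0)
  expect_lt(lrt$p, 0.05)
})

test_that("marginal means recover the configured cutaneous deficit", {
  run <- cached_run()
  cfg <- run$cfg
  sel <- cached_selection("tb_mean")
  emm <- emmeans_grid(sel, c("method", "t_air"))
  at5 <- emm[emm$t_air == "5", ]
  cu <- at5$emmean[at5$method == "CU"]
  others <- at5$emmean[at5$method != "CU"]
  deficits <- others - cu
  se <- sqrt(at5$se[at5$method == "CU"]^2 + at5$se[at5$method != "CU"]^2)
  expect_true(all(abs(deficits - cfg$cu_deficit_5) < 4 * se + 0.3))
  # at thermoneutrality the methods agree
  at25 <- emm[emm$t_air == "25", ]
  expect_lt(diff(range(at25$emmean)), 1.0)
})
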