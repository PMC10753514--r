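## End-to-end orchestration: generate -> calibrate -> QC -> respirometry ->
## extract -> variability -> statistics.

#' Process a synthetic (or recorded) experiment
#'
#' Runs the data-processing chain on a generated experiment: baseline drift
#' correction and gas-exchange math on the analyzer traces; per-method
#' linear calibration of the temperature streams; misread removal (PIT) and
#' recording-range enforcement (thermocouples); rounding and 1-min binning;
#' RMR extraction via the most-stable-2-min rule with the per-ambient-
#' temperature minimum across cycles; time-matched mean body temperature;
#' and per-bird variability indices.
#'
#' @param exp a `tb_experiment` from [generate_experiment()].
#' @param keep_rates keep the per-second rate series in the output (large).
#' @return list of class `"tb_processed"`: `estimates` (the analysis table,
#'   one row per bird x ambient temperature, with `age`/`sex`/`mass`),
#'   `variability`, `binned`, `calib_fits`, `qc` (counters), and optionally
#'   `rates`.
#' @export
process_experiment <- function(exp, keep_rates = FALSE) {
  stopifnot(inherits(exp, "tb_experiment"))
  ## respirometry
  corrected <- correct_baseline_drift(exp$gas)
  rates <- compute_rate_series(corrected)
  ## temperature calibration + QC
  calib_fits <- fit_calibration(exp$calib, grouping = "method")
  temps <- apply_calibration(exp$temps, calib_fits, grouping = "method")
  pit <- remove_misreads(temps[sensor == "PIT"])
  tc <- enforce_range(temps[sensor == "thermocouple"])
  qc <- list(n_misreads_removed = attr(pit, "n_removed"),
             n_out_of_range = attr(tc, "n_out_of_range"),
             n_temp_samples = nrow(temps))
  temps_qc <- rbind(pit, tc)
  binned <- round_and_bin(temps_qc)
  ## extraction
  est <- extract_rmr(rates, exp$birds)
  est <- match_tb(est, temps_qc)
  est <- merge(est,
               data.table::as.data.table(exp$birds)[, list(bird_id, age, sex,
                                                           mass = mass_pre)],
               by = "bird_id")
  data.table::setorder(est, bird_id, -t_air)
  ## variability
  vari <- variability_table(binned)
  out <- list(estimates = est[], variability = vari, binned = binned,
              calib_fits = calib_fits, qc = qc)
  if (keep_rates) out$rates <- rates
  class(out) <- "tb_processed"
  out
}

#' Fit the study's statistical models on a processed experiment
#'
#' Model selection (AICc over the interaction candidate set) and REML
#' refits for RMR and body temperature; Wald chi-square tests; marginal
#' means and Bonferroni pairwise contrasts; random-intercept likelihood
#' ratio tests; Welch ANOVA + Games-Howell on the CV and consecutive
#' disparity index; and design balance checks.
#'
#' @param processed a `tb_processed` from [process_experiment()].
#' @param birds the bird metadata table of the experiment.
#' @return list of class `"tb_analysis"`.
#' @export
analyze_experiment <- function(processed, birds) {
  est <- processed$estimates
  sel_rmr <- fit_candidates_and_select(est, "rmr_w")
  sel_tb <- fit_candidates_and_select(est, "tb_mean")
  emm_rmr_method <- emmeans_grid(sel_rmr, "method")
  emm_rmr_tair <- emmeans_grid(sel_rmr, "t_air")
  emm_tb <- emmeans_grid(sel_tb, c("method", "t_air"))
  vari <- merge(processed$variability,
                data.table::as.data.table(birds)[, list(bird_id)],
                by = "bird_id")
  out <- list(
    rmr = list(selection = sel_rmr, wald = wald_chisq(sel_rmr),
               emmeans_method = emm_rmr_method,
               emmeans_tair = emm_rmr_tair,
               contrasts = pairwise_contrasts(emm_rmr_method),
               ranef_lrt = random_effect_lrt(sel_rmr)),
    tb = list(selection = sel_tb, wald = wald_chisq(sel_tb),
              emmeans = emm_tb,
              contrasts = pairwise_contrasts(emm_tb, by = "t_air"),
              ranef_lrt = random_effect_lrt(sel_tb)),
    variability = list(
      table = processed$variability,
      cv_welch = welch_anova(vari$cv, vari$method),
      cv_games_howell = games_howell(vari$cv, vari$method),
      d_welch = welch_anova(vari$d_index, vari$method),
      d_games_howell = games_howell(vari$d_index, vari$method)
    ),
    balance = balance_checks(birds)
  )
  class(out) <- "tb_analysis"
  out
}

#' Run the full pipeline and write result tables
#'
#' Generates (seeded), processes and analyzes one synthetic experiment and
#' writes the result tables as CSV plus a QC/manifest JSON under `out_dir`.
#' Identical configuration and seed give byte-identical result tables.
#'
#' @param cfg an [experiment_config()] or the path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional seed overriding `cfg$seed`.
#' @return the run manifest (list), invisibly; side effect: files under
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg = experiment_config(), out_dir = "results",
                         seed = NULL) {
  if (is.character(cfg)) cfg <- read_config(cfg)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  exp <- generate_experiment(cfg)
  proc <- process_experiment(exp)
  ana <- analyze_experiment(proc, exp$birds)
  paths <- c(
    birds = "birds.csv", estimates = "metabolic_estimates.csv",
    variability = "variability.csv", calib_fits = "calibration_fits.csv",
    aicc_rmr = "aicc_rmr.csv", aicc_tb = "aicc_tb.csv",
    wald_rmr = "wald_rmr.csv", wald_tb = "wald_tb.csv",
    emmeans_rmr_method = "emmeans_rmr_method.csv",
    emmeans_rmr_tair = "emmeans_rmr_tair.csv",
    emmeans_tb = "emmeans_tb.csv",
    contrasts_rmr = "contrasts_rmr.csv", contrasts_tb = "contrasts_tb.csv",
    variability_tests = "variability_tests.csv"
  )
  paths <- vapply(paths, function(p) file.path(out_dir, p), "")
  tables <- list(
    birds = exp$birds, estimates = proc$estimates,
    variability = proc$variability, calib_fits = proc$calib_fits,
    aicc_rmr = ana$rmr$selection$aicc_table,
    aicc_tb = ana$tb$selection$aicc_table,
    wald_rmr = ana$rmr$wald, wald_tb = ana$tb$wald,
    emmeans_rmr_method = ana$rmr$emmeans_method,
    emmeans_rmr_tair = ana$rmr$emmeans_tair,
    emmeans_tb = ana$tb$emmeans,
    contrasts_rmr = ana$rmr$contrasts, contrasts_tb = ana$tb$contrasts,
    variability_tests = variability_test_table(ana)
  )
  for (nm in names(tables)) {
    utils::write.csv(tables[[nm]], paths[[nm]], row.names = FALSE)
  }
  qc_path <- file.path(out_dir, "qc_summary.json")
  jsonlite::write_json(proc$qc, qc_path, auto_unbox = TRUE, pretty = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("tbmethods")),
    seed = cfg$seed,
    n_birds = nrow(exp$birds),
    selected_model_rmr = ana$rmr$selection$best,
    selected_model_tb = ana$tb$selection$best,
    qc = proc$qc,
    artifact_md5 = as.list(stats::setNames(unname(tools::md5sum(unname(paths))),
                                           basename(unname(paths)))),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# Flat table of the Welch/Games-Howell results on CV and D.
variability_test_table <- function(ana) {
  v <- ana$variability
  welch <- data.table::data.table(
    index = c("cv", "d_index"), test = "welch",
    group1 = NA_character_, group2 = NA_character_,
    statistic = c(v$cv_welch$F, v$d_welch$F),
    df1 = c(v$cv_welch$df1, v$d_welch$df1),
    df2 = c(v$cv_welch$df2, v$d_welch$df2),
    p = c(v$cv_welch$p, v$d_welch$p)
  )
  gh <- data.table::rbindlist(list(
    cbind(index = "cv", test = "games_howell",
          v$cv_games_howell[, list(group1, group2, statistic = q,
                                   df1 = NA_real_, df2 = df, p)]),
    cbind(index = "d_index", test = "games_howell",
          v$d_games_howell[, list(group1, group2, statistic = q,
                                  df1 = NA_real_, df2 = df, p)])
  ))
  rbind(welch, gh)
}

#' Recovery metrics from one end-to-end run
#'
#' Runs the full pipeline on one seeded default-configuration experiment and
#' returns the quantities the synthetic study is designed to recover: the
#' percent RMR increases across ambient temperatures (from marginal means),
#' the fitted mass slope, the minimum cutaneous body-temperature deficit at
#' 5 degC (from the method x ambient temperature marginal means), the
#' minimum percent CV excess of cutaneous profiles, and the percent D excess
#' of cloacal over pooled subcutaneous/intraperitoneal profiles.
#'
#' @param seed integer seed.
#' @param cfg base configuration (the seed is overridden).
#' @return one-row `data.table` of metrics.
#' @export
recovery_metrics <- function(seed, cfg = experiment_config()) {
  cfg$seed <- as.integer(seed)
  exp <- generate_experiment(cfg)
  proc <- process_experiment(exp)
  ana <- analyze_experiment(proc, exp$birds)
  emm_t <- ana$rmr$emmeans_tair
  r <- function(t_air) emm_t$emmean[emm_t$t_air == t_air]
  rmr_pct_5v25 <- 100 * (r("5") / r("25") - 1)
  rmr_pct_m15v5 <- 100 * (r("-15") / r("5") - 1)
  mass_slope <- unname(nlme::fixef(ana$rmr$selection$fit)["mass"])
  ## CU body-temperature deficit at 5 degC from the tb marginal means
  emm_tb <- emmeans_grid(ana$tb$selection, c("method", "t_air"))
  at5 <- emm_tb[t_air == "5"]
  cu <- at5$emmean[at5$method == "CU"]
  cu_deficit_5 <- min(at5$emmean[at5$method != "CU"]) - cu
  ## variability contrasts
  v <- merge(proc$variability,
             data.table::as.data.table(exp$birds)[, list(bird_id)],
             by = "bird_id")
  mean_cv <- tapply(v$cv, v$method, mean)
  cv_excess_pct <- 100 * (mean_cv[["CU"]] /
                            max(mean_cv[setdiff(names(mean_cv), "CU")]) - 1)
  mean_d <- tapply(v$d_index, v$method, mean)
  d_pooled <- mean(v$d_index[v$method %in% c("SC", "IP")])
  d_excess_pct <- 100 * (mean_d[["CL"]] / d_pooled - 1)
  data.table::data.table(
    seed = seed,
    rmr_pct_5v25 = rmr_pct_5v25,
    rmr_pct_m15v5 = rmr_pct_m15v5,
    mass_slope = mass_slope,
    cu_deficit_5 = cu_deficit_5,
    cv_excess_pct = as.numeric(cv_excess_pct),
    d_excess_pct = as.numeric(d_excess_pct),
    model_rmr = ana$rmr$selection$best,
    model_tb = ana$tb$selection$best,
    n_birds = nrow(exp$birds)
  )
}

#' Recovery metrics averaged over seeds
#'
#' @param seeds integer vector of seeds.
#' @param cfg base configuration.
#' @return list with `per_seed` (one row per seed) and `mean` (named means
#'   of the numeric metrics).
#' @export
recovery_summary <- function(seeds, cfg = experiment_config()) {
  per_seed <- data.table::rbindlist(lapply(seeds, recovery_metrics, cfg = cfg))
  num <- c("rmr_pct_5v25", "rmr_pct_m15v5", "mass_slope", "cu_deficit_5",
           "cv_excess_pct", "d_excess_pct")
  list(per_seed = per_seed,
       mean = vapply(per_seed[, num, with = FALSE], mean, 0))
}
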