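# Shared fixtures: generated once per session and cached.
.tb_cache <- new.env(parent = emptyenv())

# Small two-birds-per-method experiment for cheap structural tests.
small_config <- function(seed = 5, ...) {
  experiment_config(n_birds_per_method = 2, seed = seed, ...)
}

# One default-size generated + processed experiment shared across test files.
cached_run <- function(seed = 101) {
  key <- paste0("run", seed)
  if (!exists(key, envir = .tb_cache)) {
    cfg <- experiment_config(seed = seed)
    exp <- generate_experiment(cfg)
    proc <- process_experiment(exp)
    assign(key, list(cfg = cfg, exp = exp, proc = proc), envir = .tb_cache)
  }
  get(key, envir = .tb_cache)
}

# Model selections on the cached run.
cached_selection <- function(response) {
  key <- paste0("sel_", response)
  if (!exists(key, envir = .tb_cache)) {
    run <- cached_run()
    assign(key, fit_candidates_and_select(run$proc$estimates, response),
           envir = .tb_cache)
  }
  get(key, envir = .tb_cache)
}

# Ten-seed end-to-end recovery summary shared by the acceptance criteria and
# the parameter-recovery property test.
cached_recovery <- function() {
  if (!exists("recovery", envir = .tb_cache)) {
    assign("recovery", recovery_summary(1:10), envir = .tb_cache)
  }
  get("recovery", envir = .tb_cache)
}

# Exhaustive most-stable-window search: the brute-force oracle.
brute_force_window <- function(x, width) {
  starts <- seq_len(length(x) - width + 1)
  sds <- vapply(starts, function(s) stats::sd(x[s:(s + width - 1)]), 0)
  best <- which.min(sds)
  list(start = best, mean = mean(x[best:(best + width - 1)]),
       sd = sds[best])
}
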