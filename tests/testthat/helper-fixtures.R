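# Shared, lazily computed fixtures. Expensive objects (cohorts, trained
# models) are built once per test run and reused across test files.
.fx_env <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_env, inherits = FALSE)) {
    assign(name, force(expr), envir = .fx_env)
  }
  get(name, envir = .fx_env, inherits = FALSE)
}

# Small cohort + dataset for fast pipeline-level tests.
fx_small_ds <- function() {
  fx("small_ds", {
    coh <- generate_cohort(cohort_config(n_patients = 120, seed = 55))
    c(build_dataset(coh, seed = 55), list(cohort = coh))
  })
}

# Study-scale fixture: default strong-signal cohort, trained model and
# test-set relevance maps; one per training seed.
fx_main <- function(seed) {
  fx(paste0("main_", seed), {
    coh <- generate_cohort(cohort_config(n_patients = 500, seed = seed))
    ds <- build_dataset(coh, seed = seed)
    model <- lstm_train(ds$train, ds$val,
                        train_config(hidden_dim = 32, max_epochs = 40,
                                     patience = 10, seed = seed))
    rel <- explain_windows(model, ds$test)
    list(cohort = coh, ds = ds, model = model, rel = rel)
  })
}

# Cohort whose planted signal depends only on the most recent epoch
# (recency weight all on lag 1), driver = heart_rate_max_delta.
fx_recency <- function() {
  fx("recency", {
    cfg <- cohort_config(
      n_patients = 200, seed = 404,
      beta = c(history = 0, fentanyl_dose = 0, hr_delta = 1.8,
               midazolam_duration = 0, previous_epochs = 0),
      recency_weights = c(1, 0, 0, 0, 0, 0),
      beta0 = -1.3)
    coh <- generate_cohort(cfg)
    ds <- build_dataset(coh, seed = 404)
    model <- lstm_train(ds$train, ds$val,
                        train_config(hidden_dim = 16, max_epochs = 25,
                                     patience = 8, seed = 404))
    list(cohort = coh, ds = ds, model = model)
  })
}

# mean |per-window aggregated relevance| per feature: the statistic used
# for importance-recovery checks.
window_abs_importance <- function(rel) {
  agg_w <- apply(rel$maps, c(1, 3), sum)
  colMeans(abs(agg_w))
}
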