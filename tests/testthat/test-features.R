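test_that("feature schema has 66 uniquely named features in fixed order", {
  s <- feature_schema()
  expect_length(s, 66)
  expect_false(anyDuplicated(s) > 0)
  expect_identical(s[1:5], c("temperature_min", "temperature_max",
                             "temperature_max_delta", "temperature_mean",
                             "temperature_count"))
  expect_identical(tail(s, 4), c("age_months", "prior_withdrawal_epochs",
                                 "previous_epochs", "mech_vent_duration_h"))
  expect_error(feature_schema("v2"), "unknown")
})

test_that("vital epoch aggregation computes the five summary statistics", {
  a <- aggregate_vital_epoch(data.frame(timestamp_h = c(1, 2.5, 3.9),
                                        value = c(120, 140, 130)))
  expect_equal(a[c("vmin", "vmax", "max_delta", "mean", "count")],
               list(vmin = 120, vmax = 140, max_delta = 20, mean = 130,
                    count = 3L))
  e <- aggregate_vital_epoch(data.frame(timestamp_h = numeric(),
                                        value = numeric()))
  expect_true(all(is.na(unlist(e[c("vmin", "vmax", "max_delta", "mean")]))))
  expect_identical(e$count, 0L)
  s <- aggregate_vital_epoch(data.frame(timestamp_h = 0.2, value = 98.6))
  expect_equal(s$vmin, 98.6)
  expect_equal(s$vmax, 98.6)
  expect_equal(s$max_delta, 0)
  expect_equal(s$count, 1L)
})

test_that("medication epoch aggregation follows the per-kg conventions", {
  none <- aggregate_medication_epoch(NULL, weight_kg = 10, epoch_index = 2)
  expect_equal(none$current_avg_dose_per_kg, 0)
  expect_equal(none$cumulative_duration_h, 0)

  adm <- data.frame(timestamp_h = c(4.5, 6.2), dose_mg = c(2, 2))
  cur <- aggregate_medication_epoch(adm, weight_kg = 10, epoch_index = 2)
  expect_equal(cur$current_avg_dose_per_kg, 4 / (10 * 4))

  # prior epochs total 8 mg, current epoch 4 mg, weight 10 kg
  adm2 <- data.frame(timestamp_h = c(0.5, 1, 5, 6, 9.1), dose_mg = c(4, 4, 2, 2, 99))
  cum <- aggregate_medication_epoch(adm2[1:4, ], weight_kg = 10, epoch_index = 3)
  expect_equal(cum$cumulative_dose_per_kg, 1.2)
  expect_equal(cum$previous_epoch_dose_per_kg, 0.4)
  expect_equal(cum$cumulative_duration_h, 8)  # two dosed epochs x 4 h

  expect_error(
    aggregate_medication_epoch(data.frame(timestamp_h = 1, dose_mg = -1),
                               10, 1),
    "negative dose")
})

test_that("imputation carries one epoch forward, then uses the patient mean", {
  mk <- function(means, counts) {
    data.frame(patient_id = "A", variable = "heart_rate",
               epoch = seq_along(means), vmin = means, vmax = means,
               max_delta = 0, mean = means, count = counts)
  }
  # epoch 2 missing, epoch 1 observed mean 110 -> carried forward
  d <- mk(c(110, NA, 120), c(3L, 0L, 2L))
  r <- impute_vitals(d)
  expect_equal(r$mean[2], 110)
  # epochs 2 and 3 missing: 2 gets carry-forward, 3 the patient mean
  d2 <- mk(c(100, NA, NA), c(4L, 0L, 0L))
  r2 <- impute_vitals(d2)
  expect_equal(r2$mean[2], 100)
  expect_equal(r2$mean[3], 100)  # patient mean = 100 (only source epoch)
  # count-weighted patient mean when carry-forward unavailable
  d3 <- mk(c(90, NA, NA, 120), c(1L, 0L, 0L, 3L))
  r3 <- impute_vitals(d3)
  expect_equal(r3$mean[3], (90 * 1 + 120 * 3) / 4)
  # no missing epochs -> identity
  d4 <- mk(c(95, 100), c(2L, 2L))
  r4 <- impute_vitals(d4)
  expect_equal(r4$mean, d4$mean)
  expect_equal(r4$count, d4$count)
})

test_that("imputation leaves zero missing sentinels under random missingness", {
  set.seed(31)
  for (rep in 1:15) {
    n_ep <- sample(3:12, 1)
    means <- round(rnorm(n_ep, 100, 10), 1)
    counts <- rep(2L, n_ep)
    drop <- runif(n_ep) < 0.4
    if (all(drop)) drop[1] <- FALSE
    means[drop] <- NA
    counts[drop] <- 0L
    d <- data.frame(patient_id = "P", variable = "map", epoch = seq_len(n_ep),
                    vmin = means, vmax = means, max_delta = 0, mean = means,
                    count = counts)
    r <- impute_vitals(d)
    expect_false(anyNA(r$mean))
    expect_false(anyNA(r$vmin))
  }
})

test_that("patients lacking a variable fall back to the cohort mean with a warning", {
  d <- data.frame(patient_id = "P", variable = "map", epoch = 1:3,
                  vmin = NA_real_, vmax = NA_real_, max_delta = NA_real_,
                  mean = NA_real_, count = 0L)
  expect_warning(r <- impute_vitals(d, fallback_means = c(map = 72)),
                 "fallback")
  expect_true(all(r$mean == 72))
})

test_that("window count is max(0, K - 6) for K in 0..20", {
  for (K in 0:20) {
    f <- matrix(runif(K * 66), K, 66)
    lab <- rbinom(K, 1, 0.3)
    w <- build_windows(f, lab, lookback = 6)
    expect_equal(dim(w$x)[1], max(0, K - 6))
    if (K >= 7) {
      expect_equal(w$window_start, seq_len(K - 6))
      # window j takes its label from epoch j + 6
      expect_equal(w$label, lab[seq_len(K - 6) + 6])
      # window 1 covers epochs 1..6
      expect_equal(w$x[1, , ], f[1:6, ])
    }
  }
})

test_that("feature vectors assemble to length 66 in schema order", {
  vit_names <- attr(feature_schema(), "vitals")
  vs <- setNames(lapply(vit_names,
                        function(v) list(vmin = 1, vmax = 2, max_delta = 1,
                                         mean = 1.5, count = 3)),
                 vit_names)
  ms <- setNames(lapply(attr(feature_schema(), "drugs"), function(d) {
    list(current_avg_dose_per_kg = 0, cumulative_dose_per_kg = 0,
         previous_epoch_dose_per_kg = 0, cumulative_duration_h = 0)
  }), attr(feature_schema(), "drugs"))
  v <- assemble_feature_vector(vs, ms, list(age_months = 24,
                                            mech_vent_duration_h = 100),
                               epoch_index = 6, prior_withdrawal_epochs = 2)
  expect_length(v, 66)
  expect_identical(names(v), as.character(feature_schema()))
  # a patient with no medications: all 32 dose features are zero
  expect_true(all(v[31:62] == 0))
  expect_equal(unname(v["previous_epochs"]), 6)
  expect_equal(unname(v["prior_withdrawal_epochs"]), 2)
  expect_error(assemble_feature_vector(vs[-1], ms, list(age_months = 1,
                                                        mech_vent_duration_h = 1),
                                       1, 0),
               "schema mismatch")
})

test_that("epoch labels match a brute-force WAT-1 scan", {
  set.seed(91)
  coh <- generate_cohort(cohort_config(n_patients = 8, seed = 9))
  w1 <- coh$wat1
  gt <- coh$ground_truth$labels
  for (k in sample(nrow(gt), 50)) {
    pid <- gt$patient_id[k]
    expect_identical(
      gt$label[k] == 1L,
      brute_epoch_label(w1[w1$patient_id == pid, ], gt$epoch[k]))
  }
})

test_that("min-max scaling maps train data into [0,1] and inverts exactly", {
  set.seed(7)
  m <- cbind(a = c(2, 4, 6), b = rnorm(3), const = rep(5, 3))
  sc <- fit_minmax(m)
  s <- apply_minmax(m, sc)
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(unname(s[2, "a"]), 0.5)        # midpoint
  expect_equal(unname(apply_minmax(cbind(a = 8, b = 0, const = 5), sc)[1, "a"]),
               1.0)                            # clipped above train max
  expect_true(all(s[, "const"] == 0))          # degenerate feature -> 0
  inv <- invert_minmax(s, sc)
  expect_equal(inv[, 1:2], m[, 1:2], tolerance = 1e-12)
  expect_error(apply_minmax(m, list(min = 0)), "fitted")
})

test_that("cumulative dose and duration features are non-decreasing per patient", {
  ds <- fx_small_ds()
  coh <- ds$cohort
  w <- prepare_windows(coh)
  sch <- w$feature_names
  cum_idx <- grep("(cumulative_dose_per_kg|cumulative_duration_h)$", sch)
  # within each window, epochs are consecutive: check monotonicity across
  # the 6 epochs of every window for every cumulative feature
  for (f in cum_idx) {
    d <- apply(w$x[, , f, drop = FALSE], 1, diff)
    expect_true(all(d >= -1e-12))
  }
})

test_that("prepared windows are complete, scaled and correctly shaped", {
  ds <- fx_small_ds()
  for (split in c("train", "val", "test")) {
    w <- ds[[split]]
    expect_false(anyNA(w$x))
    expect_true(all(w$x >= 0 & w$x <= 1))
    expect_equal(dim(w$x)[2:3], c(6L, 66L))
    expect_true(all(w$label %in% 0:1))
  }
  # patient-level disjointness
  expect_length(intersect(ds$train$patient_id, ds$test$patient_id), 0)
  expect_length(intersect(ds$train$patient_id, ds$val$patient_id), 0)
})

test_that("ingest rejects invalid records and reports them", {
  coh <- generate_cohort(cohort_config(n_patients = 4, seed = 21))
  d <- list(vitals = coh$vitals, meds = coh$meds, wat1 = coh$wat1,
            patients = coh$patients)
  d$patients$weight_kg[1] <- 0
  d$meds <- rbind(d$meds,
                  data.frame(patient_id = d$patients$patient_id[2],
                             timestamp_h = 1, drug = "fentanyl",
                             dose_mg = -5))
  d$vitals <- rbind(d$vitals, d$vitals[1, ])  # duplicate timestamp record
  w <- prepare_windows(d)
  expect_equal(w$validation$patients_rejected_nonpositive_weight, 1)
  expect_equal(w$validation$meds_rejected_negative_dose, 1)
  expect_gte(w$validation$vitals_rejected_duplicate_timestamp, 1)
  expect_false(d$patients$patient_id[1] %in% w$patient_id)
})
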