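#' Configuration for the synthetic PICU cohort generator
#'
#' Defines the statistical structure of a simulated post-extubation cohort:
#' irregularly sampled vital signs with per-variable missingness, per-kg
#' opioid/sedative dosing schedules with tapering, and per-epoch IWS labels
#' drawn from a planted, recency-weighted logistic risk mechanism. The
#' default missingness rates are the per-feature missing proportions of the
#' development data (respiratory rate 0.16\% up to mean arterial pressure
#' 17.19\%) and the default target prevalence is 0.23.
#'
#' The planted risk mechanism, in decreasing order of effect, uses: the
#' running count of prior IWS-positive epochs, cumulative fentanyl dose per
#' kg, recency-weighted heart-rate max-delta, cumulative midazolam exposure
#' duration, and the epoch index. These map one-to-one onto schema features,
#' so explanation- and permutation-recovery tests have a known ground truth.
#'
#' @param n_patients Number of patients to simulate.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @param epochs_range Integer range (inclusive) from which each patient's
#'   number of observed 4-hour epochs is drawn uniformly. The default
#'   `c(7, 40)` guarantees every patient yields at least one window.
#' @param prevalence Target epoch-level IWS prevalence; `beta0` defaults to
#'   a value tuned (by [tune_intercept()]) to reach it.
#' @param missingness Named per-vital probabilities that a (patient, epoch,
#'   vital) block of measurements is missing entirely.
#' @param beta0 Risk-model intercept.
#' @param beta Named coefficients of the planted drivers, on standardized
#'   covariates: `history`, `fentanyl_dose`, `hr_delta`,
#'   `midazolam_duration`, `previous_epochs`.
#' @param recency_weights Weights on heart-rate max-delta at lags 1..6
#'   epochs (lag 1 = most recent) in the risk covariate.
#' @param noise_sd Standard deviation of the Gaussian noise added to the
#'   risk logit.
#' @param epoch_hours Epoch length in hours (4 by default).
#' @return A list of class `iws_cohort_config`.
#' @export
cohort_config <- function(n_patients = 500,
                          seed = 0,
                          epochs_range = c(7L, 40L),
                          prevalence = 0.23,
                          missingness = c(temperature = 0.0022,
                                          heart_rate = 0.0074,
                                          sbp = 0.1265,
                                          dbp = 0.1266,
                                          respiratory_rate = 0.0016,
                                          map = 0.1719),
                          beta0 = -1.445,
                          beta = c(history = 3.0,
                                   fentanyl_dose = 0.9,
                                   hr_delta = 0.4,
                                   midazolam_duration = 0.3,
                                   previous_epochs = 0.15),
                          recency_weights = c(0.35, 0.25, 0.15, 0.10, 0.08, 0.07),
                          noise_sd = 0.4,
                          epoch_hours = 4) {
  stopifnot(n_patients >= 1, prevalence > 0, prevalence < 1,
            all(missingness >= 0 & missingness <= 1),
            length(recency_weights) == 6, epoch_hours > 0)
  cfg <- list(
    n_patients = as.integer(n_patients), seed = seed,
    epochs_range = as.integer(epochs_range), prevalence = prevalence,
    missingness = missingness[schema_vitals()],
    beta0 = beta0, beta = beta, recency_weights = recency_weights,
    noise_sd = noise_sd, epoch_hours = epoch_hours,
    # Standardization constants for the risk covariates (generator
    # constants, fixed at design time from the covariate distributions).
    standardize = list(history = c(2.0, 2.0),
                       fentanyl = c(0.020, 0.012),
                       hr = c(25, 7),
                       midazolam = c(40, 30),
                       previous = c(12, 8))
  )
  class(cfg) <- "iws_cohort_config"
  cfg
}

# Physiologic base values by age band (generator constants, not data facts).
.vital_base <- function(vital, age_months) {
  age_y <- age_months / 12
  f <- function(lo, hi) lo + (hi - lo) * pmin(age_y, 16) / 16
  switch(vital,
    temperature = rep(37, length(age_months)),
    heart_rate = f(135, 78),
    respiratory_rate = f(38, 16),
    sbp = f(72, 115),
    dbp = f(42, 65),
    map = f(52, 80),
    stop("unknown vital ", vital))
}

.vital_rates <- c(temperature = 4, heart_rate = 8, sbp = 4, dbp = 4,
                  respiratory_rate = 8, map = 4)
.vital_within_sd <- c(temperature = 0.25, heart_rate = NA, sbp = 6, dbp = 5,
                      respiratory_rate = 3, map = 5)
.vital_between_sd <- c(temperature = 0.15, heart_rate = 8, sbp = 4, dbp = 3,
                       respiratory_rate = 2.5, map = 3)

.drug_use_prob <- c(fentanyl = 0.92, morphine = 0.78, hydromorphone = 0.26,
                    methadone = 0.58, midazolam = 0.96,
                    dexmedetomidine = 0.72, lorazepam = 0.65,
                    propofol = 0.54)
.drug_dose_per_kg <- c(fentanyl = 0.001, morphine = 0.05,
                       hydromorphone = 0.01, methadone = 0.1,
                       midazolam = 0.05, dexmedetomidine = 0.0005,
                       lorazepam = 0.05, propofol = 1.0)

# Simulate everything upstream of the labels. Called inside with_seed().
.sim_covariates <- function(cfg) {
  n <- cfg$n_patients
  eh <- cfg$epoch_hours
  # demographics: age bands weighted like a mixed PICU population
  band_p <- c(0.122, 0.466, 0.171, 0.128, 0.113)
  band_lo <- c(0, 1, 24, 72, 156); band_hi <- c(1, 24, 72, 156, 264)
  band <- sample.int(5, n, replace = TRUE, prob = band_p)
  age <- stats::runif(n, band_lo[band], band_hi[band])
  age_y <- age / 12
  wt_mu <- ifelse(age < 12, 3.4 + 0.55 * age,
                  ifelse(age_y < 10, 2.2 * age_y + 9, 3.1 * age_y + 3))
  weight <- pmax(2, wt_mu * exp(stats::rnorm(n, 0, 0.12)))
  K <- sample(seq(cfg$epochs_range[1], cfg$epochs_range[2]), n, replace = TRUE)
  patients <- data.table::data.table(
    patient_id = sprintf("P%04d", seq_len(n)),
    weight_kg = round(weight, 2),
    age_months = round(age, 1),
    mech_vent_duration_h = round(exp(stats::rnorm(n, log(194), 0.6)), 1),
    prior_withdrawal_history = stats::rbinom(n, 3, 0.3),
    n_epochs = K)

  # (patient, epoch, vital) grid
  pe <- data.table::data.table(
    pidx = rep(seq_len(n), K),
    epoch = sequence(K))
  vitals <- schema_vitals()
  vg <- pe[rep(seq_len(nrow(pe)), each = length(vitals))]
  vg[, vital := rep(vitals, times = nrow(pe))]
  vg[, age_months := patients$age_months[pidx]]
  vg[, base := 0]
  for (v in vitals) {
    vg[vital == v, base := .vital_base(v, age_months)]
  }
  # patient-level offset + AR(1) epoch drift
  pv <- unique(vg[, .(pidx, vital)])
  pv[, offset := stats::rnorm(.N) * .vital_between_sd[vital]]
  vg <- merge(vg, pv, by = c("pidx", "vital"), sort = FALSE)
  data.table::setorder(vg, pidx, vital, epoch)
  vg[, innov := stats::rnorm(.N) * 0.4 * .vital_between_sd[vital]]
  vg[, drift := as.numeric(stats::filter(innov, 0.8, method = "recursive")),
     by = .(pidx, vital)]
  vg[, emean := base + offset + drift]
  # within-epoch spread; heart rate gets an epoch-varying spread so that
  # max-delta carries real between-epoch signal
  vg[, wsd := .vital_within_sd[vital]]
  vg[vital == "heart_rate", wsd := stats::rgamma(.N, shape = 4, scale = 2.2)]
  vg[, n_meas := 1L + stats::rpois(.N, .vital_rates[vital] - 1)]
  vg[, miss := stats::runif(.N) < cfg$missingness[vital]]

  idx <- rep(seq_len(nrow(vg)), vg$n_meas)
  meas <- vg[idx, .(pidx, epoch, vital, emean, wsd, miss)]
  meas[, timestamp_h := (epoch - 1) * eh + stats::runif(.N, 0, eh)]
  meas[, value := emean + stats::rnorm(.N) * wsd]
  meas[vital == "temperature", value := round(value, 1)]
  meas[vital != "temperature", value := round(value, 0)]

  # true heart-rate max-delta per (patient, epoch), pre-missingness
  hrD <- matrix(0, n, max(K))
  hr_agg <- meas[vital == "heart_rate",
                 .(delta = max(value) - min(value)), by = .(pidx, epoch)]
  hrD[cbind(hr_agg$pidx, hr_agg$epoch)] <- hr_agg$delta

  # medications
  drugs <- schema_drugs()
  pd <- data.table::CJ(pidx = seq_len(n), drug = drugs, sorted = FALSE)
  pd[, used := stats::runif(.N) < .drug_use_prob[drug]]
  pd[, taper := stats::runif(.N, 5, 20)]
  pd <- pd[used == TRUE]
  dg <- pd[rep(seq_len(nrow(pd)), K[pd$pidx]),
           .(pidx, drug, taper)]
  dg[, epoch := sequence(K[pd$pidx])]
  dg[, n_admin := stats::rpois(.N, 2 * exp(-(epoch - 1) / taper))]
  dg <- dg[n_admin > 0]
  dg[, weight_kg := patients$weight_kg[pidx]]
  dg[, total_mg := n_admin * .drug_dose_per_kg[drug] * weight_kg *
        exp(stats::rnorm(.N, 0, 0.25))]
  aidx <- rep(seq_len(nrow(dg)), dg$n_admin)
  admins <- dg[aidx, .(pidx, epoch, drug, n_admin, total_mg)]
  admins[, timestamp_h := (epoch - 1) * eh + stats::runif(.N, 0, eh)]
  admins[, dose_mg := total_mg / n_admin]

  # per-(patient, epoch) risk covariates
  fentC <- matrix(0, n, max(K))
  fe <- dg[drug == "fentanyl", .(d = sum(total_mg)), by = .(pidx, epoch)]
  if (nrow(fe)) fentC[cbind(fe$pidx, fe$epoch)] <- fe$d
  fentC <- t(apply(fentC, 1, cumsum)) / patients$weight_kg
  midD <- matrix(0, n, max(K))
  me <- dg[drug == "midazolam", .(any = 1), by = .(pidx, epoch)]
  if (nrow(me)) midD[cbind(me$pidx, me$epoch)] <- 1
  midD <- t(apply(midD, 1, cumsum)) * eh

  # recency-weighted heart-rate delta available when predicting epoch e
  # (uses epochs e-1 .. e-6)
  Kmax <- max(K)
  hrW <- matrix(0, n, Kmax)
  for (lag in 1:6) {
    src <- seq_len(Kmax) - lag
    ok <- src >= 1
    hrW[, ok] <- hrW[, ok, drop = FALSE] +
      cfg$recency_weights[lag] * hrD[, src[ok], drop = FALSE]
  }

  list(patients = patients, meas = meas, admins = admins,
       hrD = hrD, hrW = hrW, fentC = fentC, midD = midD, K = K)
}

# Sequential label simulation with withdrawal-history feedback. `noise` and
# `u` may be supplied (pre-drawn) so that intercept tuning is monotone.
.sim_labels <- function(cov, cfg, beta0, noise = NULL, u = NULL) {
  n <- nrow(cov$patients); Kmax <- max(cov$K)
  if (is.null(noise)) noise <- matrix(stats::rnorm(n * Kmax, 0, cfg$noise_sd), n, Kmax)
  if (is.null(u)) u <- matrix(stats::runif(n * Kmax), n, Kmax)
  st <- cfg$standardize; b <- cfg$beta
  prior_pos <- as.numeric(cov$patients$prior_withdrawal_history)
  lab <- matrix(NA_integer_, n, Kmax)
  ptrue <- matrix(NA_real_, n, Kmax)
  hist_at <- matrix(NA_real_, n, Kmax)
  for (e in seq_len(Kmax)) {
    act <- cov$K >= e
    prev_col <- if (e > 1) e - 1 else NULL
    fent <- if (is.null(prev_col)) rep(0, n) else cov$fentC[, prev_col]
    mid <- if (is.null(prev_col)) rep(0, n) else cov$midD[, prev_col]
    lg <- beta0 +
      b["history"] * (prior_pos - st$history[1]) / st$history[2] +
      b["fentanyl_dose"] * (fent - st$fentanyl[1]) / st$fentanyl[2] +
      b["hr_delta"] * (cov$hrW[, e] - st$hr[1]) / st$hr[2] +
      b["midazolam_duration"] * (mid - st$midazolam[1]) / st$midazolam[2] +
      b["previous_epochs"] * (e - st$previous[1]) / st$previous[2] +
      noise[, e]
    p <- stats::plogis(lg)
    y <- as.integer(u[, e] < p)
    lab[act, e] <- y[act]
    ptrue[act, e] <- p[act]
    hist_at[act, e] <- prior_pos[act]
    prior_pos <- prior_pos + ifelse(act, y, 0)
  }
  list(labels = lab, p_true = ptrue, hist_at = hist_at)
}

#' Generate a synthetic post-extubation cohort
#'
#' Simulates raw patient timelines (vitals, medication administrations,
#' WAT-1 assessments, demographics) with the planted risk mechanism of
#' [cohort_config()], plus the ground truth needed for recovery tests.
#' Positive epochs receive a WAT-1 score >= 3 and negative epochs a score
#' < 3, one assessment per epoch, so labels round-trip exactly through the
#' feature pipeline.
#'
#' @param config An [cohort_config()] object.
#' @return A list of class `iws_cohort` with elements `patients`, `vitals`,
#'   `meds`, `wat1` (data.tables in the ingest layout) and `ground_truth`
#'   (per-epoch true probabilities and labels, the planted coefficient
#'   vector, and `driver_features` in decreasing planted importance).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 5, seed = 1))
#' names(coh)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "iws_cohort_config"))
  with_seed(config$seed, {
    cov <- .sim_covariates(config)
    sim <- .sim_labels(cov, config, config$beta0)
    n <- nrow(cov$patients); eh <- config$epoch_hours

    # WAT-1: one assessment per epoch, consistent with the label
    pe <- data.table::data.table(pidx = rep(seq_len(n), cov$K),
                                 epoch = sequence(cov$K))
    pe[, label := sim$labels[cbind(pidx, epoch)]]
    pe[, timestamp_h := (epoch - 1) * eh + stats::runif(.N, 0.1 * eh, 0.9 * eh)]
    pe[, score := ifelse(label == 1L, sample(3:9, .N, replace = TRUE),
                         sample(0:2, .N, replace = TRUE))]

    ids <- cov$patients$patient_id
    vitals <- cov$meas[miss == FALSE,
                       .(patient_id = ids[pidx], timestamp_h = round(timestamp_h, 3),
                         variable = vital, value)]
    meds <- cov$admins[, .(patient_id = ids[pidx],
                           timestamp_h = round(timestamp_h, 3),
                           drug, dose_mg = signif(dose_mg, 6))]
    wat1 <- pe[, .(patient_id = ids[pidx], timestamp_h = round(timestamp_h, 3),
                   score)]
    data.table::setorder(vitals, patient_id, timestamp_h)
    data.table::setorder(meds, patient_id, timestamp_h)
    data.table::setorder(wat1, patient_id, timestamp_h)

    gt_lab <- pe[, .(patient_id = ids[pidx], epoch,
                     p_true = sim$p_true[cbind(pidx, epoch)], label)]
    # the raw covariates entering each epoch's risk logit (for recovery tests)
    prevcol <- function(M) {
      cbind(0, M)[cbind(pe$pidx, pe$epoch)]
    }
    gt_cov <- pe[, .(patient_id = ids[pidx], epoch,
                     prior_positive_epochs = sim$hist_at[cbind(pidx, epoch)],
                     fentanyl_cum_per_kg = prevcol(cov$fentC),
                     hr_recency_delta = cov$hrW[cbind(pidx, epoch)],
                     midazolam_duration_h = prevcol(cov$midD),
                     previous_epochs = epoch)]
    out <- list(
      patients = cov$patients[, .(patient_id, weight_kg, age_months,
                                  mech_vent_duration_h,
                                  prior_withdrawal_history)],
      vitals = vitals, meds = meds, wat1 = wat1,
      ground_truth = list(
        labels = gt_lab,
        covariates = gt_cov,
        beta0 = config$beta0, beta = config$beta,
        driver_features = c("prior_withdrawal_epochs",
                            "fentanyl_cumulative_dose_per_kg",
                            "heart_rate_max_delta",
                            "midazolam_cumulative_duration_h",
                            "previous_epochs"),
        n_epochs = cov$K),
      config = config)
    class(out) <- "iws_cohort"
    out
  })
}

#' @export
print.iws_cohort <- function(x, ...) {
  prev <- mean(x$ground_truth$labels$label)
  cat(sprintf(paste0("Synthetic IWS cohort: %d patients, %d epochs, ",
                     "epoch prevalence %.3f\n"),
              nrow(x$patients), nrow(x$ground_truth$labels), prev))
  invisible(x)
}

#' Tune the risk-model intercept to a target prevalence
#'
#' Bisects on the intercept `beta0` until the simulated epoch-level IWS
#' prevalence is within `tol` of `target`, holding all other coefficients
#' and the covariate draw fixed (common random numbers make the realized
#' prevalence monotone in the intercept, so bisection is exact).
#'
#' @param config A [cohort_config()]; its `n_patients` controls the
#'   simulation size used during tuning.
#' @param target Target prevalence; defaults to `config$prevalence`.
#' @param tol Absolute tolerance on realized prevalence.
#' @param interval Bracketing interval for the intercept.
#' @param max_iter Maximum bisection steps.
#' @return The tuned intercept (numeric scalar) with attribute
#'   `realized_prevalence`.
#' @export
tune_intercept <- function(config = cohort_config(), target = config$prevalence,
                           tol = 0.01, interval = c(-10, 5), max_iter = 60) {
  with_seed(config$seed, {
    cov <- .sim_covariates(config)
    n <- nrow(cov$patients); Kmax <- max(cov$K)
    noise <- matrix(stats::rnorm(n * Kmax, 0, config$noise_sd), n, Kmax)
    u <- matrix(stats::runif(n * Kmax), n, Kmax)
    prev_at <- function(b0) {
      lab <- .sim_labels(cov, config, b0, noise = noise, u = u)$labels
      mean(lab, na.rm = TRUE)
    }
    lo <- interval[1]; hi <- interval[2]
    if (prev_at(lo) > target || prev_at(hi) < target) {
      stop("intercept interval does not bracket the target prevalence")
    }
    for (i in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      p <- prev_at(mid)
      if (abs(p - target) <= tol) {
        return(structure(mid, realized_prevalence = p))
      }
      if (p < target) lo <- mid else hi <- mid
    }
    stop("bisection failed to reach target prevalence within ", max_iter,
         " iterations")
  })
}

#' Export a synthetic cohort to the four ingest CSV files
#'
#' Writes `vitals.csv`, `meds.csv`, `wat1.csv`, `patients.csv` in the layout
#' consumed by [prepare_windows()]; the round trip through the ingest layer
#' is lossless.
#'
#' @param cohort An `iws_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "iws_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(cohort$vitals, file.path(dir, "vitals.csv"))
  data.table::fwrite(cohort$meds, file.path(dir, "meds.csv"))
  data.table::fwrite(cohort$wat1, file.path(dir, "wat1.csv"))
  data.table::fwrite(cohort$patients, file.path(dir, "patients.csv"))
  invisible(dir)
}
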