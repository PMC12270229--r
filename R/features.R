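#' Aggregate one vital sign over one 4-hour epoch
#'
#' Computes the per-epoch summary statistics used as model features: the
#' minimum and maximum observed values, the max delta change (max - min),
#' the mean, and the number of measurements. An empty epoch yields `NA`
#' value fields (the missing sentinel) with `count = 0`; downstream
#' imputation removes all sentinels.
#'
#' @param measurements A data.frame with columns `timestamp_h`, `value`, or
#'   a numeric vector of values, all falling within one epoch.
#' @return Named list: `vmin`, `vmax`, `max_delta`, `mean`, `count`.
#' @export
#' @examples
#' aggregate_vital_epoch(data.frame(timestamp_h = c(1, 2.5, 3.9),
#'                                  value = c(120, 140, 130)))
aggregate_vital_epoch <- function(measurements) {
  v <- if (is.data.frame(measurements)) measurements$value else as.numeric(measurements)
  if (length(v) == 0) {
    return(list(vmin = NA_real_, vmax = NA_real_, max_delta = NA_real_,
                mean = NA_real_, count = 0L))
  }
  list(vmin = min(v), vmax = max(v), max_delta = max(v) - min(v),
       mean = mean(v), count = length(v))
}

#' Aggregate one medication's administrations through one epoch
#'
#' Derives the four dose features for one drug at one epoch:
#' the current average dose per kg over the epoch (total epoch dose /
#' weight / epoch length, an mg/kg/h rate), the cumulative dose per kg
#' since extubation through the epoch end, the total dose per kg in the
#' previous epoch, and the cumulative duration of exposure (number of
#' epochs up to this one containing at least one administration, times the
#' epoch length). Epochs with no documented dose contribute zero.
#'
#' @param admins data.frame with `timestamp_h`, `dose_mg`: all
#'   administrations of one drug up to the end of the epoch, time-ordered.
#' @param weight_kg Patient weight (> 0).
#' @param epoch_index 1-based epoch index since extubation.
#' @param epoch_hours Epoch length in hours.
#' @return Named list: `current_avg_dose_per_kg`, `cumulative_dose_per_kg`,
#'   `previous_epoch_dose_per_kg`, `cumulative_duration_h`.
#' @export
aggregate_medication_epoch <- function(admins, weight_kg, epoch_index,
                                       epoch_hours = 4) {
  stopifnot(weight_kg > 0, epoch_index >= 1)
  if (is.null(admins) || nrow(admins) == 0) {
    admins <- data.frame(timestamp_h = numeric(), dose_mg = numeric())
  }
  if (any(admins$dose_mg < 0)) stop("negative dose in medication record")
  ep <- floor(admins$timestamp_h / epoch_hours) + 1
  keep <- ep <= epoch_index
  ep <- ep[keep]; dose <- admins$dose_mg[keep]
  in_cur <- sum(dose[ep == epoch_index])
  in_prev <- if (epoch_index > 1) sum(dose[ep == epoch_index - 1]) else 0
  dosed_epochs <- length(unique(ep[dose > 0]))
  list(current_avg_dose_per_kg = in_cur / (weight_kg * epoch_hours),
       cumulative_dose_per_kg = sum(dose) / weight_kg,
       previous_epoch_dose_per_kg = in_prev / weight_kg,
       cumulative_duration_h = dosed_epochs * epoch_hours)
}

#' Impute missing per-epoch vital summaries
#'
#' Patient-centric imputation: a missing epoch is filled with the
#' immediately preceding epoch's observed mean (the most recent valid value
#' within the previous four hours); failing that, with the patient's mean
#' over all available measurements of that variable; failing that (a
#' patient with zero measurements of the variable anywhere), with a
#' cohort-level fallback mean, with a warning. Filled epochs get
#' `vmin = vmax = mean = fill`, `max_delta = 0`; `count` remains 0.
#'
#' @param summaries data.table/data.frame with columns `patient_id`,
#'   `variable`, `epoch`, `vmin`, `vmax`, `max_delta`, `mean`, `count`, in
#'   chronological order within patient and variable.
#' @param fallback_means Optional named vector of cohort-level means per
#'   variable (fitted on the training split) used as the last resort.
#' @return The completed table; no `NA` value fields remain.
#' @export
impute_vitals <- function(summaries, fallback_means = NULL) {
  dt <- data.table::as.data.table(summaries)
  data.table::setorder(dt, patient_id, variable, epoch)
  # patient mean across all available measurements (count-weighted)
  dt[, pat_mean := {
    ok <- count > 0
    if (any(ok)) sum(mean[ok] * count[ok]) / sum(count[ok]) else NA_real_
  }, by = .(patient_id, variable)]
  # carry-forward horizon of exactly one epoch: previous epoch's observed mean
  dt[, prev_mean := data.table::shift(ifelse(count > 0, mean, NA_real_)),
     by = .(patient_id, variable)]
  dt[, fill := data.table::fifelse(count > 0, mean,
        data.table::fifelse(!is.na(prev_mean), prev_mean, pat_mean))]
  if (anyNA(dt$fill)) {
    miss_var <- unique(dt[is.na(fill), variable])
    if (is.null(fallback_means) || !all(miss_var %in% names(fallback_means))) {
      # last resort within the data at hand
      dt[, coh_mean := {
        ok <- count > 0
        if (any(ok)) sum(mean[ok] * count[ok]) / sum(count[ok]) else NA_real_
      }, by = variable]
      warning("patient(s) with no measurements of: ",
              paste(miss_var, collapse = ", "),
              "; falling back to the cohort mean of the supplied data")
      dt[is.na(fill), fill := coh_mean]
      dt[, coh_mean := NULL]
    } else {
      warning("patient(s) with no measurements of: ",
              paste(miss_var, collapse = ", "),
              "; using supplied cohort fallback means")
      dt[is.na(fill), fill := fallback_means[variable]]
    }
  }
  dt[count == 0, `:=`(vmin = fill, vmax = fill, max_delta = 0, mean = fill)]
  dt[, c("pat_mean", "prev_mean", "fill") := NULL]
  dt[]
}

#' Assemble one 66-feature epoch vector
#'
#' Concatenates per-vital summaries, per-drug dose summaries and the four
#' per-epoch scalars in the canonical [feature_schema()] order.
#'
#' @param vital_summaries Named list (one per schema vital) of
#'   [aggregate_vital_epoch()] results.
#' @param med_summaries Named list (one per schema drug) of
#'   [aggregate_medication_epoch()] results.
#' @param statics Named list/vector with `age_months`,
#'   `mech_vent_duration_h`.
#' @param epoch_index 1-based epoch index (the `previous_epochs` feature).
#' @param prior_withdrawal_epochs Recorded prior withdrawal history plus
#'   the count of earlier in-stay IWS-positive epochs.
#' @return Named numeric vector of length 66.
#' @export
assemble_feature_vector <- function(vital_summaries, med_summaries, statics,
                                    epoch_index, prior_withdrawal_epochs) {
  schema <- feature_schema()
  miss_v <- setdiff(schema_vitals(), names(vital_summaries))
  miss_d <- setdiff(schema_drugs(), names(med_summaries))
  if (length(miss_v) || length(miss_d)) {
    stop("feature schema mismatch; missing: ",
         paste(c(miss_v, miss_d), collapse = ", "))
  }
  stat_map <- c(min = "vmin", max = "vmax", max_delta = "max_delta",
                mean = "mean", count = "count")
  out <- numeric(length(schema))
  names(out) <- schema
  for (v in schema_vitals()) {
    for (s in names(stat_map)) {
      out[paste(v, s, sep = "_")] <-
        as.numeric(vital_summaries[[v]][[stat_map[s]]])
    }
  }
  for (d in schema_drugs()) {
    for (s in attr(feature_schema(), "dose_stats")) {
      out[paste(d, s, sep = "_")] <- as.numeric(med_summaries[[d]][[s]])
    }
  }
  out["age_months"] <- as.numeric(statics[["age_months"]])
  out["prior_withdrawal_epochs"] <- prior_withdrawal_epochs
  out["previous_epochs"] <- epoch_index
  out["mech_vent_duration_h"] <- as.numeric(statics[["mech_vent_duration_h"]])
  out
}

#' Build sliding observation windows for one patient
#'
#' A patient with `K` consecutive epochs yields `max(0, K - lookback)`
#' windows: window `j` covers feature epochs `j .. j+lookback-1` and takes
#' its binary label from epoch `j+lookback` (the 4-hour prediction epoch),
#' with a stride of one epoch. Patients without the requisite preceding
#' history yield no windows.
#'
#' @param features Numeric matrix `K x 66` of epoch feature vectors
#'   (row `e` = epoch `e`).
#' @param labels Integer vector of length `K` of per-epoch IWS labels.
#' @param lookback Number of epochs per observation window (default 6).
#' @return List with `x` (array `n_windows x lookback x 66`), `label`,
#'   `window_start` (the epoch index `j` of each window's first epoch).
#' @export
build_windows <- function(features, labels, lookback = 6) {
  K <- nrow(features)
  stopifnot(length(labels) == K)
  n <- max(0L, K - lookback)
  x <- array(NA_real_, c(n, lookback, ncol(features)),
             dimnames = list(NULL, NULL, colnames(features)))
  if (n > 0) {
    for (t in seq_len(lookback)) {
      x[, t, ] <- features[seq_len(n) + t - 1, , drop = FALSE]
    }
  }
  list(x = x, label = if (n > 0) labels[seq_len(n) + lookback] else integer(0),
       window_start = seq_len(n))
}

# ---- ingest -----------------------------------------------------------------

.read_cohort_input <- function(data) {
  if (inherits(data, "iws_cohort")) {
    return(list(vitals = data$vitals, meds = data$meds, wat1 = data$wat1,
                patients = data$patients))
  }
  if (is.character(data) && length(data) == 1 && dir.exists(data)) {
    return(list(
      vitals = data.table::fread(file.path(data, "vitals.csv")),
      meds = data.table::fread(file.path(data, "meds.csv")),
      wat1 = data.table::fread(file.path(data, "wat1.csv")),
      patients = data.table::fread(file.path(data, "patients.csv"))))
  }
  stopifnot(is.list(data),
            all(c("vitals", "meds", "wat1", "patients") %in% names(data)))
  lapply(data[c("vitals", "meds", "wat1", "patients")],
         data.table::as.data.table)
}

# Validate and clean the four ingest tables; returns tables + a report of
# rejected records (nothing is silently dropped).
.validate_cohort <- function(d) {
  rep <- list()
  pts <- data.table::as.data.table(d$patients)
  bad_wt <- pts[!(weight_kg > 0)]
  if (nrow(bad_wt)) pts <- pts[weight_kg > 0]
  rep$patients_rejected_nonpositive_weight <- nrow(bad_wt)

  vit <- data.table::as.data.table(d$vitals)
  dup_v <- duplicated(vit, by = c("patient_id", "variable", "timestamp_h"))
  rep$vitals_rejected_duplicate_timestamp <- sum(dup_v)
  vit <- vit[!dup_v][is.finite(value) & timestamp_h >= 0]

  med <- data.table::as.data.table(d$meds)
  bad_dose <- med$dose_mg < 0
  rep$meds_rejected_negative_dose <- sum(bad_dose)
  med <- med[!bad_dose & timestamp_h >= 0]

  wat <- data.table::as.data.table(d$wat1)
  bad_score <- !(wat$score >= 0 & wat$score <= 12)
  rep$wat1_rejected_out_of_range <- sum(bad_score)
  wat <- wat[!bad_score & timestamp_h >= 0]

  keep <- pts$patient_id
  list(vitals = vit[patient_id %in% keep], meds = med[patient_id %in% keep],
       wat1 = wat[patient_id %in% keep], patients = pts, report = rep)
}

# ---- full pipeline ----------------------------------------------------------

#' Transform raw patient timelines into observation windows
#'
#' Runs the full feature pipeline: ingest validation, 4-hour epoch
#' aggregation of vitals and medications, patient-centric imputation,
#' epoch-vector assembly in [feature_schema()] order, per-epoch IWS
#' labeling (label 1 iff any WAT-1 score >= 3 falls in the epoch's
#' half-open interval), and sliding-window construction. Timestamps are
#' hours since extubation; epoch `e` covers `[(e-1)*epoch_hours,
#' e*epoch_hours)`. The output windows are *unscaled*; see [fit_minmax()].
#'
#' @param data An `iws_cohort`, a directory containing `vitals.csv`,
#'   `meds.csv`, `wat1.csv`, `patients.csv`, or a named list of the four
#'   data.frames.
#' @param epoch_hours Epoch length in hours.
#' @param lookback Number of epochs per observation window.
#' @param label_missing `"negative"` labels prediction epochs with no WAT-1
#'   assessment 0; `"exclude"` drops those windows.
#' @param fallback_means Optional named per-variable cohort means for the
#'   imputation last resort (fit these on the training split).
#' @return An object of class `iws_windows`: list with `x` (array
#'   `N x lookback x 66`), `label`, `patient_id`, `window_start`,
#'   `feature_names`, `epoch_hours`, `lookback`, `scaled` (FALSE),
#'   `validation` (ingest report).
#' @export
prepare_windows <- function(data, epoch_hours = 4, lookback = 6,
                            label_missing = c("negative", "exclude"),
                            fallback_means = NULL) {
  label_missing <- match.arg(label_missing)
  d <- .validate_cohort(.read_cohort_input(data))
  schema <- feature_schema()
  vitals_all <- schema_vitals(); drugs_all <- schema_drugs()
  pts <- d$patients

  # per-patient epoch horizon from the latest record in any stream
  maxt <- rbind(d$vitals[, .(t = timestamp_h), by = patient_id][, .(t = max(t)), by = patient_id],
                d$meds[, .(t = max(timestamp_h)), by = patient_id],
                d$wat1[, .(t = max(timestamp_h)), by = patient_id])
  maxt <- maxt[, .(t = max(t)), by = patient_id]
  horiz <- merge(pts[, .(patient_id)], maxt, by = "patient_id", all.x = TRUE)
  horiz[is.na(t), t := 0]
  horiz[, K := as.integer(floor(t / epoch_hours) + 1)]

  # ---- vitals ----
  vit <- d$vitals[patient_id %in% horiz$patient_id]
  vit[, epoch := as.integer(floor(timestamp_h / epoch_hours) + 1)]
  vstat <- vit[, .(vmin = min(value), vmax = max(value), mean = mean(value),
                   count = .N), by = .(patient_id, variable, epoch)]
  vstat[, max_delta := vmax - vmin]
  grid <- horiz[, .(epoch = seq_len(K)), by = patient_id]
  vgrid <- grid[rep(seq_len(nrow(grid)), each = length(vitals_all))]
  vgrid[, variable := rep(vitals_all, nrow(grid))]
  vfull <- merge(vgrid, vstat, by = c("patient_id", "variable", "epoch"),
                 all.x = TRUE)
  vfull[is.na(count), count := 0L]
  vfull <- impute_vitals(vfull, fallback_means = fallback_means)

  vw <- data.table::dcast(vfull, patient_id + epoch ~ variable,
                          value.var = c("vmin", "vmax", "max_delta", "mean", "count"))
  # canonical names <vital>_<stat>
  stat_map <- c(vmin = "min", vmax = "max", max_delta = "max_delta",
                mean = "mean", count = "count")
  for (s in names(stat_map)) {
    for (v in vitals_all) {
      data.table::setnames(vw, paste(s, v, sep = "_"),
                           paste(v, stat_map[s], sep = "_"))
    }
  }

  # ---- medications ----
  med <- d$meds[patient_id %in% horiz$patient_id & drug %in% drugs_all]
  med[, epoch := as.integer(floor(timestamp_h / epoch_hours) + 1)]
  mstat <- med[, .(dose = sum(dose_mg)), by = .(patient_id, drug, epoch)]
  mgrid <- grid[rep(seq_len(nrow(grid)), each = length(drugs_all))]
  mgrid[, drug := rep(drugs_all, nrow(grid))]
  mfull <- merge(mgrid, mstat, by = c("patient_id", "drug", "epoch"), all.x = TRUE)
  mfull[is.na(dose), dose := 0]
  data.table::setorder(mfull, patient_id, drug, epoch)
  mfull <- merge(mfull, pts[, .(patient_id, weight_kg)], by = "patient_id",
                 sort = FALSE)
  mfull[, `:=`(
    current_avg_dose_per_kg = dose / (weight_kg * epoch_hours),
    cumulative_dose_per_kg = cumsum(dose) / weight_kg,
    previous_epoch_dose_per_kg = data.table::shift(dose, fill = 0) / weight_kg,
    cumulative_duration_h = cumsum(dose > 0) * epoch_hours
  ), by = .(patient_id, drug)]
  mw <- data.table::dcast(mfull, patient_id + epoch ~ drug,
                          value.var = attr(schema, "dose_stats"))
  for (s in attr(schema, "dose_stats")) {
    for (dg in drugs_all) {
      data.table::setnames(mw, paste(s, dg, sep = "_"), paste(dg, s, sep = "_"))
    }
  }

  # ---- labels ----
  wat <- d$wat1[patient_id %in% horiz$patient_id]
  wat[, epoch := as.integer(floor(timestamp_h / epoch_hours) + 1)]
  lab <- wat[, .(label = as.integer(any(score >= 3)), has_wat1 = TRUE),
             by = .(patient_id, epoch)]
  lgrid <- merge(grid, lab, by = c("patient_id", "epoch"), all.x = TRUE)
  lgrid[is.na(label), `:=`(label = 0L, has_wat1 = FALSE)]
  data.table::setorder(lgrid, patient_id, epoch)

  # ---- statics + assembly ----
  feat <- merge(vw, mw, by = c("patient_id", "epoch"))
  feat <- merge(feat, lgrid, by = c("patient_id", "epoch"))
  feat <- merge(feat,
                pts[, .(patient_id, age_months, mech_vent_duration_h,
                        prior_withdrawal_history)],
                by = "patient_id", sort = FALSE)
  data.table::setorder(feat, patient_id, epoch)
  feat[, previous_epochs := epoch]
  feat[, prior_withdrawal_epochs :=
         prior_withdrawal_history + cumsum(data.table::shift(label, fill = 0L)),
       by = patient_id]

  miss_cols <- setdiff(schema, names(feat))
  if (length(miss_cols)) {
    stop("internal schema mismatch; missing features: ",
         paste(miss_cols, collapse = ", "))
  }

  F <- as.matrix(feat[, schema, with = FALSE])
  stopifnot(!anyNA(F))
  pid <- feat$patient_id
  labv <- feat$label
  hasw <- feat$has_wat1

  # sliding windows over the per-patient stacked feature matrix
  Kp <- feat[, .N, by = patient_id]
  offs <- c(0L, cumsum(Kp$N))
  widx <- integer(0); wpid <- character(0); wstart <- integer(0)
  for (i in seq_len(nrow(Kp))) {
    nK <- Kp$N[i]
    nw <- max(0L, nK - lookback)
    if (nw > 0) {
      widx <- c(widx, offs[i] + seq_len(nw))
      wpid <- c(wpid, rep(Kp$patient_id[i], nw))
      wstart <- c(wstart, seq_len(nw))
    }
  }
  N <- length(widx)
  x <- array(NA_real_, c(N, lookback, length(schema)),
             dimnames = list(NULL, NULL, schema))
  for (t in seq_len(lookback)) {
    x[, t, ] <- F[widx + t - 1L, , drop = FALSE]
  }
  wlab <- labv[widx + lookback]
  wwat <- hasw[widx + lookback]
  if (label_missing == "exclude" && any(!wwat)) {
    keep <- wwat
    x <- x[keep, , , drop = FALSE]; wlab <- wlab[keep]
    wpid <- wpid[keep]; wstart <- wstart[keep]
  }

  out <- list(x = x, label = as.integer(wlab), patient_id = wpid,
              window_start = wstart, feature_names = as.character(schema),
              epoch_hours = epoch_hours, lookback = lookback,
              scaled = FALSE, scaling = NULL, validation = d$report)
  class(out) <- "iws_windows"
  out
}

#' @export
print.iws_windows <- function(x, ...) {
  cat(sprintf("%d observation windows (%d x %d features, %s), prevalence %.3f\n",
              length(x$label), x$lookback, length(x$feature_names),
              if (x$scaled) "scaled" else "unscaled",
              if (length(x$label)) mean(x$label) else NA_real_))
  invisible(x)
}

#' Subset an `iws_windows` object by window index
#' @param w An `iws_windows` object.
#' @param idx Integer or logical window index.
#' @return The subsetted `iws_windows` object.
#' @export
windows_subset <- function(w, idx) {
  stopifnot(inherits(w, "iws_windows"))
  w$x <- w$x[idx, , , drop = FALSE]
  w$label <- w$label[idx]
  w$patient_id <- w$patient_id[idx]
  w$window_start <- w$window_start[idx]
  w
}
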