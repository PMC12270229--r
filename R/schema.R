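#' Feature schema registry
#'
#' The model consumes one 66-dimensional feature vector per 4-hour epoch.
#' The roster is a named, versioned registry so it can be swapped wholesale
#' if an alternative roster becomes available:
#'
#' * 6 vital signs x 5 per-epoch statistics (`min`, `max`, `max_delta`,
#'   `mean`, `count`) = 30 features;
#' * 8 sedative/opioid medications x 4 dose features
#'   (`current_avg_dose_per_kg` in mg/kg/h, `cumulative_dose_per_kg` in
#'   mg/kg since extubation, `previous_epoch_dose_per_kg` in mg/kg,
#'   `cumulative_duration_h` in hours of exposure) = 32 features;
#' * 4 per-epoch scalars: `age_months`, `prior_withdrawal_epochs` (recorded
#'   prior withdrawal history plus the number of earlier in-stay epochs
#'   already labeled IWS-positive), `previous_epochs` (the 1-based index of
#'   the epoch since extubation), `mech_vent_duration_h`.
#'
#' @param version Schema version string; only `"v1"` is defined.
#' @return Character vector of 66 feature names in canonical order, with
#'   attributes `version`, `vitals`, `drugs`, `vital_stats`, `dose_stats`.
#' @export
#' @examples
#' length(feature_schema())  # 66
feature_schema <- function(version = "v1") {
  if (!identical(version, "v1")) {
    stop("unknown feature schema version: ", version)
  }
  vitals <- c("temperature", "heart_rate", "sbp", "dbp", "respiratory_rate", "map")
  vital_stats <- c("min", "max", "max_delta", "mean", "count")
  drugs <- c("fentanyl", "morphine", "hydromorphone", "methadone",
             "midazolam", "dexmedetomidine", "lorazepam", "propofol")
  dose_stats <- c("current_avg_dose_per_kg", "cumulative_dose_per_kg",
                  "previous_epoch_dose_per_kg", "cumulative_duration_h")
  statics <- c("age_months", "prior_withdrawal_epochs", "previous_epochs",
               "mech_vent_duration_h")
  nm <- c(
    as.vector(t(outer(vitals, vital_stats, paste, sep = "_"))),
    as.vector(t(outer(drugs, dose_stats, paste, sep = "_"))),
    statics
  )
  structure(nm, version = version, vitals = vitals, drugs = drugs,
            vital_stats = vital_stats, dose_stats = dose_stats,
            statics = statics)
}

#' @keywords internal
schema_vitals <- function() attr(feature_schema(), "vitals")

#' @keywords internal
schema_drugs <- function() attr(feature_schema(), "drugs")

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# sign with the convention sign(0) := +1, used by every epsilon rule.
sign0 <- function(x) ifelse(x >= 0, 1, -1)

`%||%` <- function(a, b) if (is.null(a)) b else a
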