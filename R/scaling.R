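#' Fit per-feature min-max scaling statistics
#'
#' Computes per-feature `(train_min, train_max)` over every epoch of the
#' supplied (training-split) windows. Fit on training data only; applying
#' the fitted statistics clips out-of-range values into `[0, 1]`.
#'
#' @param w An `iws_windows` object, or a numeric matrix with one column
#'   per feature.
#' @return Object of class `iws_scaling`: list with `min`, `max`,
#'   `feature_names`.
#' @export
fit_minmax <- function(w) {
  m <- if (inherits(w, "iws_windows")) {
    matrix(w$x, ncol = dim(w$x)[3],
           dimnames = list(NULL, w$feature_names))
  } else {
    as.matrix(w)
  }
  out <- list(min = apply(m, 2, min), max = apply(m, 2, max),
              feature_names = colnames(m))
  class(out) <- "iws_scaling"
  out
}

#' Apply (or invert) min-max scaling
#'
#' Scales each feature as `(v - min) / (max - min)`, clipped to `[0, 1]`;
#' a feature constant in training maps to 0.
#'
#' @param w An `iws_windows` object or numeric feature matrix.
#' @param scaling A fitted [fit_minmax()] object.
#' @return The scaled object of the same type (windows are flagged
#'   `scaled = TRUE` and carry the scaling).
#' @export
apply_minmax <- function(w, scaling) {
  if (!inherits(scaling, "iws_scaling")) {
    stop("`scaling` must be a fitted iws_scaling object (see fit_minmax)")
  }
  rng <- scaling$max - scaling$min
  scale_mat <- function(m) {
    sm <- sweep(m, 2, scaling$min, "-")
    sm <- sweep(sm, 2, ifelse(rng > 0, rng, 1), "/")
    sm[, rng == 0] <- 0
    pmin(pmax(sm, 0), 1)
  }
  if (inherits(w, "iws_windows")) {
    d <- dim(w$x)
    m <- matrix(w$x, ncol = d[3])
    w$x <- array(scale_mat(m), d, dimnames = dimnames(w$x))
    w$scaled <- TRUE
    w$scaling <- scaling
    return(w)
  }
  scale_mat(as.matrix(w))
}

#' @rdname apply_minmax
#' @export
invert_minmax <- function(w, scaling) {
  rng <- scaling$max - scaling$min
  m <- if (inherits(w, "iws_windows")) matrix(w$x, ncol = dim(w$x)[3]) else as.matrix(w)
  out <- sweep(sweep(m, 2, rng, "*"), 2, scaling$min, "+")
  out[, rng == 0] <- scaling$min[rng == 0]
  out
}

#' Split a cohort into scaled train/validation/test window sets
#'
#' Splits *by patient* (no patient contributes windows to more than one
#' split): `1 - test_frac` of patients for training, of which `val_frac`
#' are reserved for early stopping and Platt calibration. The imputation
#' fallback means and the min-max scaling are fitted on the training
#' patients only and applied to all splits.
#'
#' @param data Input accepted by [prepare_windows()].
#' @param test_frac Fraction of patients held out for testing.
#' @param val_frac Fraction of training patients reserved for validation.
#' @param seed Integer seed for the patient-level split.
#' @param ... Passed to [prepare_windows()].
#' @return List with `iws_windows` elements `train`, `val`, `test`, plus
#'   `scaling` and `split` (the patient id assignment).
#' @export
build_dataset <- function(data, test_frac = 0.2, val_frac = 0.2, seed = 0, ...) {
  d <- .read_cohort_input(data)
  ids <- sort(unique(as.character(d$patients$patient_id)))
  with_seed(seed, {
    n <- length(ids)
    test_ids <- sample(ids, round(test_frac * n))
    tr_all <- setdiff(ids, test_ids)
    val_ids <- sample(tr_all, round(val_frac * length(tr_all)))
    train_ids <- setdiff(tr_all, val_ids)

    # training-cohort fallback means for imputation
    vit <- data.table::as.data.table(d$vitals)
    fb <- vit[patient_id %in% train_ids, .(m = mean(value)), by = variable]
    fallback <- stats::setNames(fb$m, fb$variable)

    w <- prepare_windows(d, fallback_means = fallback, ...)
    wtr <- windows_subset(w, w$patient_id %in% train_ids)
    wva <- windows_subset(w, w$patient_id %in% val_ids)
    wte <- windows_subset(w, w$patient_id %in% test_ids)
    sc <- fit_minmax(wtr)
    list(train = apply_minmax(wtr, sc), val = apply_minmax(wva, sc),
         test = apply_minmax(wte, sc), scaling = sc,
         split = list(train = train_ids, val = val_ids, test = test_ids))
  })
}
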