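#' Fit a Platt calibrator on validation scores
#'
#' Logistic recalibration of raw classifier scores: a logistic regression
#' of the true labels on the logit of the raw probability is fitted on the
#' validation split, giving calibrated `p = sigma(A * logit(p_raw) + B)`.
#' Raw probabilities are clipped to `[1e-7, 1 - 1e-7]` before the logit.
#' With slope `A > 0` the map is strictly monotone, so rank-based metrics
#' (AUROC, AUPRC) are unchanged by calibration.
#'
#' @param p_raw Raw predicted probabilities on the validation split.
#' @param labels Binary labels (0/1) of the validation split.
#' @return Object of class `iws_platt` with `A` (slope), `B` (intercept).
#' @export
fit_platt <- function(p_raw, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("Platt calibration needs both classes in the validation labels")
  }
  l <- stats::qlogis(pmin(pmax(p_raw, 1e-7), 1 - 1e-7))
  fit <- stats::glm(labels ~ l, family = stats::binomial())
  out <- list(A = unname(stats::coef(fit)[2]), B = unname(stats::coef(fit)[1]))
  class(out) <- "iws_platt"
  out
}

#' @rdname fit_platt
#' @param calibrator A fitted `iws_platt` object.
#' @param p_raw Raw probabilities to recalibrate.
#' @return `apply_platt`: calibrated probabilities.
#' @export
apply_platt <- function(calibrator, p_raw) {
  if (!inherits(calibrator, "iws_platt")) {
    stop("`calibrator` must be a fitted iws_platt object")
  }
  l <- stats::qlogis(pmin(pmax(p_raw, 1e-7), 1 - 1e-7))
  stats::plogis(calibrator$A * l + calibrator$B)
}

#' Reliability curve and expected calibration error
#'
#' Bins predictions into `n_bins` equal-width bins on `[0, 1]` and compares
#' the mean predicted probability with the observed event frequency per
#' bin. `ECE = sum_b (count_b / N) * |mean_pred_b - obs_freq_b|`; empty
#' bins are skipped.
#'
#' @param probabilities Predicted probabilities.
#' @param labels Binary labels.
#' @param n_bins Number of equal-width bins (>= 2).
#' @return List with `bins` (data.frame: `mean_pred`, `obs_freq`, `count`)
#'   and `ece`.
#' @export
calibration_curve <- function(probabilities, labels, n_bins = 10) {
  stopifnot(n_bins >= 2)
  labels <- as.numeric(labels)
  b <- pmin(floor(probabilities * n_bins) + 1, n_bins)
  bins <- data.frame(
    bin = seq_len(n_bins),
    mean_pred = tapply(probabilities, factor(b, levels = seq_len(n_bins)), mean),
    obs_freq = tapply(labels, factor(b, levels = seq_len(n_bins)), mean),
    count = as.integer(table(factor(b, levels = seq_len(n_bins)))))
  keep <- bins$count > 0
  bins <- bins[keep, ]
  ece <- sum(bins$count / sum(bins$count) * abs(bins$mean_pred - bins$obs_freq))
  list(bins = bins, ece = ece)
}
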