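#' Globally permute one feature across windows
#'
#' Shuffles the feature's whole 6-epoch trajectory *between* windows (the
#' window-level block permutation): the feature-label association is
#' broken while each window keeps a temporally coherent trajectory and the
#' multiset of trajectories is preserved. All other features are
#' untouched. An alternative mode shuffles each epoch independently.
#'
#' @param windows `iws_windows` object or `N x T x D` array.
#' @param feature Feature name (must exist in the schema) or index.
#' @param seed Integer seed; identical seeds give identical permutations.
#' @param mode `"trajectory"` (default, across-window block shuffle) or
#'   `"independent"` (each epoch shuffled separately).
#' @return Object of the same type with the feature permuted.
#' @export
global_permutation <- function(windows, feature, seed = 0,
                               mode = c("trajectory", "independent")) {
  mode <- match.arg(mode)
  is_w <- inherits(windows, "iws_windows")
  x <- if (is_w) windows$x else windows
  fi <- .feature_index(x, windows, feature)
  N <- dim(x)[1]
  with_seed(seed, {
    if (mode == "trajectory") {
      perm <- sample.int(N)
      x[, , fi] <- x[perm, , fi, drop = FALSE]
    } else {
      for (t in seq_len(dim(x)[2])) {
        x[, t, fi] <- x[sample.int(N), t, fi]
      }
    }
  })
  if (is_w) { windows$x <- x; windows } else x
}

#' Permute one feature at one time epoch only
#'
#' Shuffles the `(feature, epoch_index)` entries across windows; every
#' other entry is bit-identical to the input.
#'
#' @param windows `iws_windows` object or `N x T x D` array.
#' @param feature Feature name or index.
#' @param epoch_index Epoch position within the window (1..lookback).
#' @param seed Integer seed.
#' @return Object of the same type with the single slice permuted.
#' @export
epoch_permutation <- function(windows, feature, epoch_index, seed = 0) {
  is_w <- inherits(windows, "iws_windows")
  x <- if (is_w) windows$x else windows
  stopifnot(epoch_index >= 1, epoch_index <= dim(x)[2])
  fi <- .feature_index(x, windows, feature)
  with_seed(seed, {
    x[, epoch_index, fi] <- x[sample.int(dim(x)[1]), epoch_index, fi]
  })
  if (is_w) { windows$x <- x; windows } else x
}

.feature_index <- function(x, windows, feature) {
  if (is.numeric(feature)) {
    stopifnot(feature >= 1, feature <= dim(x)[3])
    return(as.integer(feature))
  }
  fn <- if (inherits(windows, "iws_windows")) windows$feature_names else dimnames(x)[[3]]
  fi <- match(feature, fn)
  if (is.na(fi)) stop("unknown feature: ", feature)
  fi
}

#' Permutation-importance report
#'
#' Evaluates the model's raw, uncalibrated outputs at the default
#' threshold 0.5 on the unpermuted windows (baseline) and after each
#' requested permutation, reporting the full metric block (AUROC, AUPRC,
#' sensitivity, precision, accuracy, specificity, NPV, F1) and the deltas
#' from baseline. Labels are never permuted.
#'
#' @param model Trained `iws_lstm`.
#' @param windows Scaled `iws_windows` (or array) to evaluate on.
#' @param specs List of permutation specifications; each a list with
#'   `feature`, `scope` (`"global"` or `"epoch"`), `epoch_index` (required
#'   iff `scope = "epoch"`), and optional `seed` (default 0).
#' @param labels Binary labels (taken from `windows` if an `iws_windows`).
#' @param threshold Classification threshold on the raw output.
#' @return data.frame: first row the baseline, one row per spec, with
#'   metric columns and `d_*` delta columns.
#' @export
permutation_report <- function(model, windows, specs, labels = NULL,
                               threshold = 0.5) {
  if (inherits(windows, "iws_windows")) {
    labels <- labels %||% windows$label
  }
  stopifnot(!is.null(labels))
  block <- function(scores) {
    rp <- roc_pr(scores, labels)
    cm <- .confusion_metrics(scores, labels, threshold)
    data.frame(auroc = rp$auroc, auprc = rp$auprc,
               sensitivity = cm$sensitivity, precision = cm$precision,
               accuracy = cm$accuracy, specificity = cm$specificity,
               npv = cm$npv, f1 = cm$f1)
  }
  base <- block(predict_proba(model, windows))
  rows <- cbind(data.frame(feature = "none", scope = "baseline",
                           epoch_index = NA_integer_, seed = NA_integer_),
                base)
  met <- names(base)
  for (sp in specs) {
    seed <- sp$seed %||% 0
    wp <- if (identical(sp$scope, "global")) {
      global_permutation(windows, sp$feature, seed = seed)
    } else if (identical(sp$scope, "epoch")) {
      epoch_permutation(windows, sp$feature, sp$epoch_index, seed = seed)
    } else stop("scope must be 'global' or 'epoch'")
    b <- block(predict_proba(model, wp))
    rows <- rbind(rows, cbind(
      data.frame(feature = sp$feature, scope = sp$scope,
                 epoch_index = sp$epoch_index %||% NA_integer_, seed = seed),
      b))
  }
  for (m in met) rows[[paste0("d_", m)]] <- rows[[m]] - base[[m]]
  rows
}
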