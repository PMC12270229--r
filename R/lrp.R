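#' Epsilon-rule relevance redistribution through a linear map
#'
#' Standard LRP rule for a linear (fully connected) transformation
#' `z_k = sum_j a_j W[j,k] + bias_k`: each input receives
#' `R_j = sum_k a_j W[j,k] / (z_k + eps * sign(z_k)) * R_out[k]`,
#' with `sign(0) := +1`. The denominator uses the bias-inclusive
#' pre-activation; bias terms absorb no relevance, so with `eps = 0`
#' relevance is conserved exactly when the bias is zero.
#'
#' @param R_out Relevance of the output unit(s): scalar or vector.
#' @param a Input activations (length `n_in`).
#' @param w Weights: vector (single output) or `n_in x n_out` matrix.
#' @param z Output pre-activation(s), consistent with the forward trace.
#' @param eps Stabilizer, `>= 0` (0 allowed for conservation checks).
#' @return Relevance over the inputs (length `n_in`).
#' @export
#' @examples
#' lrp_epsilon_linear(1, a = c(1, 1), w = c(3, 1), z = 4, eps = 0)
lrp_epsilon_linear <- function(R_out, a, w, z, eps) {
  stopifnot(eps >= 0)
  denom <- z + eps * sign0(z)
  if (any(denom == 0)) {
    stop("zero denominator in epsilon rule (z + eps * sign(z) = 0)")
  }
  if (is.null(dim(w))) {
    stopifnot(length(R_out) == 1, length(z) == 1)
    a * w / denom * R_out
  } else {
    stopifnot(length(z) == ncol(w), length(R_out) == ncol(w),
              length(a) == nrow(w))
    drop((a * w) %*% (R_out / denom))
  }
}

#' Relevance flow from hidden state to cell state
#'
#' Distributes the hidden-state relevance onto the cell state through the
#' output gate: `R_c = R_h * o_t * (1 - tanh(c_t)^2)`, the derivative
#' factor of `h_t = o_t * tanh(c_t)`. Implemented exactly as printed; note
#' it rescales (rather than conserves) relevance — see the
#' `conservation` flag of [lrp_explain()].
#'
#' @param R_h Hidden-state relevance (vector).
#' @param o_t Output gate activation.
#' @param c_t Cell state.
#' @return Cell-state relevance contribution.
#' @export
lrp_hidden_to_cell <- function(R_h, o_t, c_t) {
  stopifnot(length(R_h) == length(o_t), length(o_t) == length(c_t))
  R_h * o_t * (1 - tanh(c_t)^2)
}

#' Split cell-state relevance between the forget and input branches
#'
#' The cell update `c_t = f*c_prev + i*g` has two additive branches; the
#' relevance is partitioned by their relative magnitudes:
#' `R_forget = f*c_prev / (c_t + eps*sign(c_t)) * R_c` and
#' `R_input = i*g / (c_t + eps*sign(c_t)) * R_c`. With `eps = 0` the two
#' outputs sum to `R_c` exactly.
#'
#' @param R_c Cell-state relevance.
#' @param f_t,c_prev,i_t,g_t Gate/state values from the forward trace.
#' @param eps Stabilizer.
#' @return List with `forget` and `input` branch relevances.
#' @export
lrp_cell_split <- function(R_c, f_t, c_prev, i_t, g_t, eps) {
  fb <- f_t * c_prev
  ib <- i_t * g_t
  d0 <- fb + ib
  denom <- d0 + eps * sign0(d0)
  if (any(denom == 0)) stop("zero denominator in cell-split rule")
  list(forget = fb / denom * R_c, input = ib / denom * R_c)
}

#' Relevance onto the candidate gate
#'
#' The input-branch relevance is passed to the candidate proportionally to
#' the input gate: `R_g = R_input_branch * i_t`.
#'
#' @param R_input_branch Input-branch relevance from [lrp_cell_split()].
#' @param i_t Input gate activation.
#' @return Candidate relevance.
#' @export
lrp_candidate <- function(R_input_branch, i_t) {
  R_input_branch * i_t
}

# Fold eval-mode batch norm into the FC head: logit = w_eff . h6 + b_eff.
.fold_bn_head <- function(params) {
  bn <- params$bn
  s <- sqrt(bn$var + bn$eps)
  w_eff <- params$head$w * bn$gamma / s
  b_eff <- params$head$b + sum(params$head$w * (bn$beta - bn$mean * bn$gamma / s))
  list(w = w_eff, b = b_eff)
}

# Relevance recursion for one window given its (already extracted) trace
# of per-layer matrices [T x H].
.explain_one <- function(params, tr, h6, logit, epsilon, conservation) {
  H <- params$hidden_dim; L <- params$num_layers
  Tn <- nrow(tr[[1]]$h); D <- ncol(tr[[1]]$x)
  head_eff <- .fold_bn_head(params)
  R_y <- logit
  R_h <- lapply(seq_len(L), function(l) matrix(0, Tn, H))
  R_c <- lapply(seq_len(L), function(l) matrix(0, Tn, H))
  map <- matrix(0, Tn, D)
  R_h[[L]][Tn, ] <- lrp_epsilon_linear(R_y, a = h6, w = head_eff$w,
                                       z = logit, eps = epsilon)
  for (t in rev(seq_len(Tn))) {
    for (l in rev(seq_len(L))) {
      lay <- params$layers[[l]]
      trl <- tr[[l]]
      i <- trl$i[t, ]; f <- trl$f[t, ]; g <- trl$g[t, ]; o <- trl$o[t, ]
      cc <- trl$c[t, ]; zg <- trl$zg[t, ]
      c_prev <- if (t > 1) trl$c[t - 1, ] else rep(0, H)
      h_prev <- if (t > 1) trl$h[t - 1, ] else rep(0, H)
      x_t <- trl$x[t, ]
      Rh <- R_h[[l]][t, ]
      Rc_from_h <- if (conservation == "as_printed") {
        lrp_hidden_to_cell(Rh, o, cc)
      } else {
        Rh  # strict-conservation variant: pass-through
      }
      Rc <- R_c[[l]][t, ] + Rc_from_h
      sp <- lrp_cell_split(Rc, f, c_prev, i, g, epsilon)
      if (t > 1) R_c[[l]][t - 1, ] <- R_c[[l]][t - 1, ] + sp$forget
      Rg <- lrp_candidate(sp$input, i)
      # Eq over the concatenated candidate input [h_{t-1}, x_t]
      Wg <- rbind(lay$Wh[, 2 * H + 1:H, drop = FALSE],
                  lay$Wx[, 2 * H + 1:H, drop = FALSE])
      Ra <- lrp_epsilon_linear(Rg, a = c(h_prev, x_t), w = Wg, z = zg,
                               eps = epsilon)
      Rhp <- Ra[seq_len(H)]
      Rx <- Ra[H + seq_len(length(x_t))]
      if (t > 1) R_h[[l]][t - 1, ] <- R_h[[l]][t - 1, ] + Rhp
      if (l > 1) {
        R_h[[l - 1]][t, ] <- R_h[[l - 1]][t, ] + Rx
      } else {
        map[t, ] <- map[t, ] + Rx
      }
    }
  }
  map
}

#' Explain one prediction by layer-wise relevance propagation
#'
#' Starts from the raw (pre-calibration) logit as the output relevance,
#' propagates it through the batch-norm-folded fully connected head onto
#' the final hidden state with the epsilon rule, then recurses backward
#' through time and down the layer stack: hidden-state relevance flows to
#' the cell state through the output gate, is split between the forget
#' branch (forwarded to the previous time step's cell state) and the input
#' branch, passes the input gate onto the candidate, and is redistributed
#' over the concatenated `[h_{t-1}, x_t]` through the candidate gate's
#' weights. Relevance reaching a layer's input joins the hidden-state
#' relevance of the layer below at the same time step; layer-1 input
#' relevance forms the per-feature, per-epoch relevance map. Input, forget
#' and output gate pre-activations receive no relevance (candidate-gate-only
#' attribution); zero initial states receive none by construction.
#'
#' @param model Trained `iws_lstm` (or `iws_lstm_params`).
#' @param window One scaled window: `T x D` matrix.
#' @param epsilon Stabilizer of the epsilon rules (default 1e-3).
#' @param conservation `"as_printed"` applies the output-gate derivative
#'   factor when moving hidden relevance to the cell (the published rule,
#'   which rescales relevance); `"pass_through"` is a strict-conservation
#'   variant (`R_c = R_h`) for comparison.
#' @return Object of class `iws_relevance`: list with `map` (`T x D`,
#'   signed), `aggregate` (per-feature sum over epochs), `logit`,
#'   `leakage` (logit minus total assigned relevance), `epsilon`.
#' @export
lrp_explain <- function(model, window, epsilon = 1e-3,
                        conservation = c("as_printed", "pass_through")) {
  conservation <- match.arg(conservation)
  params <- if (inherits(model, "iws_lstm")) model$params else model
  stopifnot(is.matrix(window), ncol(window) == params$input_dim)
  fw <- .forward(params, window, mode = "eval", keep_trace = TRUE)
  tr <- lapply(fw$trace, function(trl) {
    lapply(trl, function(a) {
      m <- a[1, , , drop = FALSE]; dim(m) <- dim(a)[2:3]; m
    })
  })
  h6 <- tr[[params$num_layers]]$h[nrow(window), ]
  map <- .explain_one(params, tr, h6, fw$logit, epsilon, conservation)
  dimnames(map) <- list(NULL, colnames(window))
  out <- list(map = map, aggregate = colSums(map), logit = fw$logit,
              leakage = fw$logit - sum(map), epsilon = epsilon,
              conservation = conservation)
  class(out) <- "iws_relevance"
  out
}

#' Relevance maps for a whole window set
#'
#' Runs [lrp_explain()] over every window (with one shared batched forward
#' pass for the traces).
#'
#' @param model Trained `iws_lstm`.
#' @param windows `iws_windows` object or `N x T x D` array.
#' @param epsilon,conservation As in [lrp_explain()].
#' @return List of class `iws_relevance_set`: `maps` (array `N x T x D`),
#'   `logits`, `feature_names`.
#' @export
explain_windows <- function(model, windows, epsilon = 1e-3,
                            conservation = c("as_printed", "pass_through")) {
  conservation <- match.arg(conservation)
  params <- if (inherits(model, "iws_lstm")) model$params else model
  x <- if (inherits(windows, "iws_windows")) windows$x else windows
  fn <- if (inherits(windows, "iws_windows")) windows$feature_names else dimnames(x)[[3]]
  N <- dim(x)[1]; Tn <- dim(x)[2]; D <- dim(x)[3]
  fw <- .forward(params, x, mode = "eval", keep_trace = TRUE)
  maps <- array(0, c(N, Tn, D), dimnames = list(NULL, NULL, fn))
  for (n in seq_len(N)) {
    tr <- lapply(fw$trace, function(trl) {
      lapply(trl, function(a) {
        m <- a[n, , , drop = FALSE]; dim(m) <- dim(a)[2:3]; m
      })
    })
    h6 <- tr[[params$num_layers]]$h[Tn, ]
    maps[n, , ] <- .explain_one(params, tr, h6, fw$logit[n], epsilon,
                                conservation)
  }
  out <- list(maps = maps, logits = fw$logit, feature_names = fn,
              epsilon = epsilon, conservation = conservation)
  class(out) <- "iws_relevance_set"
  out
}

#' Aggregate relevance maps into importance rankings
#'
#' Per-(feature, epoch) score = mean over windows of the relevance;
#' per-feature score = sum over epochs of those means. Both signed and
#' absolute-value versions are emitted (whether a heatmap should show
#' signed or absolute mean relevance is a presentation choice, so both are
#' available).
#'
#' @param rel An `iws_relevance_set`, a list of `iws_relevance` objects, or
#'   an `N x T x D` array of relevance maps.
#' @return List with `mean_map` (`T x D`), `feature_total` (named, signed),
#'   `abs_mean_map`, `abs_feature_total`, and `ranking` (data.frame sorted
#'   by decreasing absolute importance).
#' @export
aggregate_importance <- function(rel) {
  maps <- if (inherits(rel, "iws_relevance_set")) {
    rel$maps
  } else if (is.array(rel) && length(dim(rel)) == 3) {
    rel
  } else if (is.list(rel)) {
    arr <- array(0, c(length(rel), dim(rel[[1]]$map)))
    for (i in seq_along(rel)) arr[i, , ] <- rel[[i]]$map
    dimnames(arr) <- list(NULL, NULL, colnames(rel[[1]]$map))
    arr
  } else stop("unsupported input to aggregate_importance")
  if (dim(maps)[1] < 1) stop("need at least one relevance map")
  fn <- dimnames(maps)[[3]]
  mean_map <- apply(maps, c(2, 3), mean)
  abs_mean_map <- apply(abs(maps), c(2, 3), mean)
  feature_total <- colSums(mean_map)
  abs_feature_total <- colSums(abs_mean_map)
  names(feature_total) <- fn
  names(abs_feature_total) <- fn
  rk <- data.frame(feature = fn, signed = feature_total,
                   absolute = abs_feature_total, row.names = NULL)
  rk <- rk[order(-rk$absolute), ]
  list(mean_map = mean_map, feature_total = feature_total,
       abs_mean_map = abs_mean_map, abs_feature_total = abs_feature_total,
       ranking = rk)
}
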