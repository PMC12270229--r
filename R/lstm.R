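#' Initialize LSTM parameters
#'
#' All weights and biases are drawn i.i.d. uniform on
#' `[-1/sqrt(H), +1/sqrt(H)]` where `H` is the hidden dimension — a
#' controlled initialization that keeps the starting point in a well-scaled
#' region of parameter space. Gate blocks are stored stacked in the order
#' input, forget, candidate, output: `Wx` is `D_l x 4H` (layer input
#' dimension `D_l` = `input_dim` at layer 1, `H` above), `Wh` is `H x 4H`,
#' `b` is length `4H`. The head holds the fully connected weights (length
#' `H`) and bias; batch-norm affine parameters start at identity with zero
#' running mean and unit running variance.
#'
#' @param input_dim Number of input features per time step (66).
#' @param hidden_dim Hidden state dimension `H`.
#' @param num_layers Number of stacked LSTM layers.
#' @param seed Integer seed; parameters are a deterministic function of it.
#' @return Object of class `iws_lstm_params`.
#' @export
init_params <- function(input_dim, hidden_dim, num_layers = 2, seed = 0) {
  if (input_dim < 1 || hidden_dim < 1 || num_layers < 1) {
    stop("dimensions must be positive")
  }
  H <- as.integer(hidden_dim)
  k <- 1 / sqrt(H)
  with_seed(seed, {
    layers <- vector("list", num_layers)
    for (l in seq_len(num_layers)) {
      D_l <- if (l == 1) input_dim else H
      layers[[l]] <- list(
        Wx = matrix(stats::runif(D_l * 4 * H, -k, k), D_l, 4 * H),
        Wh = matrix(stats::runif(H * 4 * H, -k, k), H, 4 * H),
        b = stats::runif(4 * H, -k, k))
    }
    p <- list(layers = layers,
              head = list(w = stats::runif(H, -k, k),
                          b = stats::runif(1, -k, k)),
              bn = list(gamma = rep(1, H), beta = rep(0, H),
                        mean = rep(0, H), var = rep(1, H), eps = 1e-5),
              input_dim = as.integer(input_dim), hidden_dim = H,
              num_layers = as.integer(num_layers))
    class(p) <- "iws_lstm_params"
    p
  })
}

# Core cell update shared by the step API and the batched forward pass.
# X: N x D_l, Hp/Cp: N x H. Gate order in the stacked blocks: i, f, g, o.
.cell_core <- function(X, Hp, Cp, layer) {
  H <- ncol(Hp)
  A <- X %*% layer$Wx + Hp %*% layer$Wh +
    matrix(layer$b, nrow(X), 4 * H, byrow = TRUE)
  i <- stats::plogis(A[, 1:H, drop = FALSE])
  f <- stats::plogis(A[, H + 1:H, drop = FALSE])
  zg <- A[, 2 * H + 1:H, drop = FALSE]
  g <- tanh(zg)
  o <- stats::plogis(A[, 3 * H + 1:H, drop = FALSE])
  c_new <- f * Cp + i * g
  h_new <- o * tanh(c_new)
  list(h = h_new, c = c_new, i = i, f = f, g = g, o = o, zg = zg)
}

#' One LSTM cell update
#'
#' Applies the gate equations for a single time step: input gate
#' `i = sigma(Wx_i x + Wh_i h + b_i)`, forget gate `f`, candidate
#' `g = tanh(Wx_g x + Wh_g h + b_g)`, output gate `o`, cell state
#' `c = f * c_prev + i * g`, hidden state `h = o * tanh(c)`, returning the
#' full gate trace needed for relevance propagation.
#'
#' @param x_t Input vector (length `D_l`) or matrix `N x D_l`.
#' @param h_prev,c_prev Previous hidden/cell state, same leading shape.
#' @param layer Layer parameter list with `Wx`, `Wh`, `b`.
#' @return List with `h`, `c` and gates `i`, `f`, `g`, `o` and candidate
#'   pre-activation `zg`, as vectors if the input was a vector.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, layer) {
  vec <- is.null(dim(x_t))
  X <- if (vec) matrix(x_t, 1) else as.matrix(x_t)
  Hp <- if (is.null(dim(h_prev))) matrix(h_prev, 1) else as.matrix(h_prev)
  Cp <- if (is.null(dim(c_prev))) matrix(c_prev, 1) else as.matrix(c_prev)
  if (!all(is.finite(X), is.finite(Hp), is.finite(Cp))) {
    stop("non-finite inputs to lstm_cell_step")
  }
  out <- .cell_core(X, Hp, Cp, layer)
  if (vec) out <- lapply(out, drop)
  out
}

# Batched multilayer forward pass.
# x: array N x T x D (or matrix T x D for one window).
# mode "train" uses batch statistics for batch norm and (if dropout_rate > 0
# and a mask is drawn) dropout; "eval" uses running statistics and no
# dropout. Internal helper; returns caches as requested.
.forward <- function(params, x, mode = "eval", keep_trace = FALSE,
                     dropout_rate = 0, dropout_mask = NULL,
                     keep_cache = FALSE) {
  if (is.matrix(x)) x <- array(x, c(1, nrow(x), ncol(x)))
  stopifnot(length(dim(x)) == 3, dim(x)[3] == params$input_dim)
  N <- dim(x)[1]; Tn <- dim(x)[2]; H <- params$hidden_dim
  L <- params$num_layers
  trace <- if (keep_trace || keep_cache) vector("list", L) else NULL
  Xl <- x
  for (l in seq_len(L)) {
    lay <- params$layers[[l]]
    h <- matrix(0, N, H); c <- matrix(0, N, H)
    Hs <- array(0, c(N, Tn, H)); Cs <- Hs
    Is <- Hs; Fs <- Hs; Gs <- Hs; Os <- Hs; Zg <- Hs
    for (t in seq_len(Tn)) {
      Xt <- Xl[, t, , drop = FALSE]
      dim(Xt) <- c(N, dim(Xl)[3])
      st <- .cell_core(Xt, h, c, lay)
      h <- st$h; c <- st$c
      Hs[, t, ] <- h; Cs[, t, ] <- c
      Is[, t, ] <- st$i; Fs[, t, ] <- st$f; Gs[, t, ] <- st$g
      Os[, t, ] <- st$o; Zg[, t, ] <- st$zg
    }
    if (!is.null(trace)) {
      trace[[l]] <- list(x = Xl, h = Hs, c = Cs, i = Is, f = Fs, g = Gs,
                         o = Os, zg = Zg)
    }
    Xl <- Hs
  }
  h6 <- Xl[, Tn, , drop = TRUE]
  if (is.null(dim(h6))) h6 <- matrix(h6, N)
  bn <- params$bn
  if (mode == "train") {
    mu <- colMeans(h6)
    v <- colMeans(sweep(h6, 2, mu)^2)
  } else {
    mu <- bn$mean; v <- bn$var
  }
  std <- sqrt(v + bn$eps)
  xhat <- sweep(sweep(h6, 2, mu), 2, std, "/")
  hbn <- sweep(sweep(xhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  if (mode == "train" && dropout_rate > 0) {
    if (is.null(dropout_mask)) {
      dropout_mask <- matrix(stats::runif(N * H) >= dropout_rate, N, H)
    }
    hdrop <- hbn * dropout_mask / (1 - dropout_rate)
  } else {
    dropout_mask <- NULL
    hdrop <- hbn
  }
  logit <- drop(hdrop %*% params$head$w) + params$head$b
  out <- list(logit = logit, prob = stats::plogis(logit))
  if (keep_trace) out$trace <- trace
  if (keep_cache) {
    out$cache <- list(trace = trace, h6 = h6, mu = mu, v = v, std = std,
                      xhat = xhat, hbn = hbn, hdrop = hdrop,
                      dropout_mask = dropout_mask,
                      dropout_rate = dropout_rate, Tn = Tn)
  }
  out
}

#' Forward pass over observation windows
#'
#' Stacks the LSTM layers (each layer consumes the hidden sequence of the
#' layer below), takes the final hidden state of the top layer, applies
#' batch normalization, dropout (train mode only), and the fully connected
#' head, and maps the logit through a sigmoid. In eval mode batch norm uses
#' running statistics (a fixed affine map) and the output is deterministic.
#'
#' @param model An `iws_lstm` model or `iws_lstm_params`.
#' @param x Array `N x T x D` of scaled windows, a `T x D` matrix for a
#'   single window, or an `iws_windows` object.
#' @param mode `"eval"` or `"train"`.
#' @param keep_trace Retain all gate activations, cell and hidden states
#'   per layer and time step (needed for relevance propagation).
#' @return List with `logit`, `prob`, and `trace` if requested.
#' @export
lstm_forward <- function(model, x, mode = c("eval", "train"),
                         keep_trace = FALSE) {
  mode <- match.arg(mode)
  params <- if (inherits(model, "iws_lstm")) model$params else model
  dr <- if (inherits(model, "iws_lstm")) model$config$dropout_rate %||% 0 else 0
  if (inherits(x, "iws_windows")) x <- x$x
  .forward(params, x, mode = mode, keep_trace = keep_trace,
           dropout_rate = if (mode == "train") dr else 0)
}

#' Raw (uncalibrated) predicted probabilities
#'
#' Eval-mode forward pass per window, returning the raw sigmoid output.
#' Warns if inputs look unscaled (values outside `[0, 1]`).
#'
#' @param model A trained `iws_lstm` model.
#' @param windows An `iws_windows` object or `N x T x D` array.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, windows) {
  x <- if (inherits(windows, "iws_windows")) windows$x else windows
  if (min(x) < -1e-8 || max(x) > 1 + 1e-8) {
    warning("input values outside [0, 1]; windows may be unscaled")
  }
  lstm_forward(model, x, mode = "eval")$prob
}
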