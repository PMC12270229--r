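#' Training configuration for the recurrent risk model
#'
#' @param hidden_dim Hidden dimension `H` (default 64).
#' @param num_layers Number of stacked LSTM layers (default 2).
#' @param dropout_rate Dropout probability on the batch-normalized final
#'   hidden state (train mode only).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum optimizer epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement).
#' @param pos_weight Multiplier on the positive-class term of the binary
#'   cross-entropy (1 = unweighted).
#' @param weight_decay Decoupled L2 penalty applied to weight matrices
#'   (not biases or batch-norm parameters) at each update. Shrinks weights
#'   on features that act only as constants, whose job the (unpenalized)
#'   biases then take over — which also keeps relevance attributions from
#'   crediting non-informative near-constant inputs.
#' @param seed Integer seed driving initialization, shuffling and dropout.
#' @param bn_momentum Running-statistic momentum of the batch-norm layer.
#' @param verbose Print per-epoch losses.
#' @return List of class `iws_train_config`.
#' @export
train_config <- function(hidden_dim = 64, num_layers = 2, dropout_rate = 0.3,
                         lr = 1e-3, batch_size = 64, max_epochs = 500,
                         patience = 25, pos_weight = 1, weight_decay = 0.3,
                         seed = 0, bn_momentum = 0.1, verbose = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "iws_train_config"
  cfg
}

# Weighted binary cross-entropy on the logit, clamped to [-30, 30] in the
# loss only. Returns loss and d(loss)/d(logit).
.bce <- function(logit, y, pos_weight = 1) {
  z <- pmin(pmax(logit, -30), 30)
  p <- stats::plogis(z)
  eps <- 1e-12
  li <- -(pos_weight * y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dlogit <- ((1 - y) * p - pos_weight * y * (1 - p)) / length(y)
  list(loss = mean(li), dlogit = dlogit)
}

# Forward + backward over one batch; returns loss and gradients in the
# same structure as the parameters.
.loss_and_grads <- function(params, x, y, dropout_rate = 0, pos_weight = 1,
                            mode = "train") {
  fw <- .forward(params, x, mode = mode, dropout_rate = dropout_rate,
                 keep_cache = TRUE)
  ca <- fw$cache
  N <- dim(x)[1]; Tn <- ca$Tn; H <- params$hidden_dim; L <- params$num_layers
  lb <- .bce(fw$logit, y, pos_weight)
  dlogit <- lb$dlogit

  g <- list(layers = vector("list", L),
            head = list(w = numeric(H), b = 0),
            bn = list(gamma = numeric(H), beta = numeric(H)))
  # head
  g$head$w <- drop(crossprod(ca$hdrop, dlogit))
  g$head$b <- sum(dlogit)
  dhdrop <- outer(dlogit, params$head$w)
  # dropout
  dhbn <- if (!is.null(ca$dropout_mask)) {
    dhdrop * ca$dropout_mask / (1 - ca$dropout_rate)
  } else dhdrop
  # batch norm
  g$bn$gamma <- colSums(dhbn * ca$xhat)
  g$bn$beta <- colSums(dhbn)
  dxhat <- sweep(dhbn, 2, params$bn$gamma, "*")
  if (mode == "train") {
    mcol <- function(m) colMeans(m)
    dh6 <- sweep(dxhat, 2, mcol(dxhat), "-") -
      sweep(ca$xhat, 2, mcol(dxhat * ca$xhat), "*")
    dh6 <- sweep(dh6, 2, ca$std, "/")
  } else {
    dh6 <- sweep(dxhat, 2, ca$std, "/")
  }

  # backprop through time, top layer down
  dH_ext <- array(0, c(N, Tn, H))
  dH_ext[, Tn, ] <- dh6
  for (l in rev(seq_len(L))) {
    tr <- ca$trace[[l]]
    lay <- params$layers[[l]]
    D_l <- dim(tr$x)[3]
    gWx <- matrix(0, D_l, 4 * H); gWh <- matrix(0, H, 4 * H)
    gb <- numeric(4 * H)
    dX <- array(0, c(N, Tn, D_l))
    dh_rec <- matrix(0, N, H); dc_rec <- matrix(0, N, H)
    for (t in rev(seq_len(Tn))) {
      sl <- function(a) { m <- a[, t, , drop = FALSE]; dim(m) <- c(N, dim(a)[3]); m }
      dh <- sl(dH_ext) + dh_rec
      i <- sl(tr$i); f <- sl(tr$f); gg <- sl(tr$g); o <- sl(tr$o)
      cc <- sl(tr$c)
      tc <- tanh(cc)
      do_ <- dh * tc
      dc <- dh * o * (1 - tc^2) + dc_rec
      c_prev <- if (t > 1) { m <- tr$c[, t - 1, , drop = FALSE]; dim(m) <- c(N, H); m } else matrix(0, N, H)
      h_prev <- if (t > 1) { m <- tr$h[, t - 1, , drop = FALSE]; dim(m) <- c(N, H); m } else matrix(0, N, H)
      di <- dc * gg; dg <- dc * i; df <- dc * c_prev
      dc_rec <- dc * f
      dA <- cbind(di * i * (1 - i), df * f * (1 - f),
                  dg * (1 - gg^2), do_ * o * (1 - o))
      xt <- sl(tr$x)
      gWx <- gWx + crossprod(xt, dA)
      gWh <- gWh + crossprod(h_prev, dA)
      gb <- gb + colSums(dA)
      dX[, t, ] <- dA %*% t(lay$Wx)
      dh_rec <- dA %*% t(lay$Wh)
    }
    g$layers[[l]] <- list(Wx = gWx, Wh = gWh, b = gb)
    if (l > 1) dH_ext <- dX
  }
  list(loss = lb$loss, grads = g, logit = fw$logit,
       bn_batch = list(mean = ca$mu, var = ca$v))
}

# Flat iteration over the trainable parameter slots.
.param_slots <- function(L) {
  slots <- list()
  for (l in seq_len(L)) {
    for (nm in c("Wx", "Wh", "b")) slots[[length(slots) + 1]] <- c("layers", l, nm)
  }
  slots[[length(slots) + 1]] <- c("head", NA, "w")
  slots[[length(slots) + 1]] <- c("head", NA, "b")
  slots[[length(slots) + 1]] <- c("bn", NA, "gamma")
  slots[[length(slots) + 1]] <- c("bn", NA, "beta")
  slots
}

.get_slot <- function(p, s) {
  if (s[1] == "layers") p$layers[[as.integer(s[2])]][[s[3]]] else p[[s[1]]][[s[3]]]
}
.set_slot <- function(p, s, v) {
  if (s[1] == "layers") p$layers[[as.integer(s[2])]][[s[3]]] <- v else p[[s[1]]][[s[3]]] <- v
  p
}

#' Train the recurrent IWS risk model
#'
#' Minimizes binary cross-entropy with Adam over minibatches, with batch
#' normalization and dropout applied after the LSTM layers, early stopping
#' on validation loss, and a fully deterministic trajectory given
#' `config$seed`. Gradients are computed by manual backpropagation through
#' the unrolled recurrence.
#'
#' @param train Training split: an `iws_windows` object, or a list with
#'   `x` (array `N x T x D`) and `label`.
#' @param val Validation split in the same form (used for early stopping
#'   and, downstream, Platt calibration).
#' @param config An [train_config()].
#' @return Object of class `iws_lstm`: list with `params` (the
#'   best-validation parameters, batch-norm running statistics included),
#'   `config`, `history` (per-epoch train/val loss), `best_epoch`.
#' @export
lstm_train <- function(train, val, config = train_config()) {
  xtr <- if (inherits(train, "iws_windows")) train$x else train$x
  ytr <- if (inherits(train, "iws_windows")) train$label else train$label
  xva <- if (inherits(val, "iws_windows")) val$x else val$x
  yva <- if (inherits(val, "iws_windows")) val$label else val$label
  if (length(ytr) == 0 || length(yva) == 0) stop("empty training or validation split")
  if (length(unique(ytr)) < 2) stop("training labels contain a single class")
  N <- dim(xtr)[1]; D <- dim(xtr)[3]
  cfg <- config

  with_seed(cfg$seed, {
    params <- init_params(D, cfg$hidden_dim, cfg$num_layers,
                          seed = sample.int(.Machine$integer.max, 1))
    slots <- .param_slots(cfg$num_layers)
    mset <- lapply(slots, function(s) .get_slot(params, s) * 0)
    vset <- mset
    step <- 0
    b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
    best <- list(loss = Inf, params = params, epoch = 0)
    hist <- data.frame(epoch = integer(), train_loss = numeric(),
                       val_loss = numeric())
    wait <- 0

    for (ep in seq_len(cfg$max_epochs)) {
      ord <- sample.int(N)
      nb <- ceiling(N / cfg$batch_size)
      tl <- 0
      for (bi in seq_len(nb)) {
        idx <- ord[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, N)]
        if (length(idx) < 2) next  # batch statistics need >= 2 samples
        xb <- xtr[idx, , , drop = FALSE]
        lg <- .loss_and_grads(params, xb, ytr[idx],
                              dropout_rate = cfg$dropout_rate,
                              pos_weight = cfg$pos_weight)
        tl <- tl + lg$loss * length(idx)
        # batch-norm running statistics (unbiased variance for the update)
        nbatch <- length(idx)
        ub <- lg$bn_batch$var * nbatch / max(1, nbatch - 1)
        params$bn$mean <- (1 - cfg$bn_momentum) * params$bn$mean +
          cfg$bn_momentum * lg$bn_batch$mean
        params$bn$var <- (1 - cfg$bn_momentum) * params$bn$var +
          cfg$bn_momentum * ub
        step <- step + 1
        for (si in seq_along(slots)) {
          gv <- .get_slot(lg$grads, slots[[si]])
          mset[[si]] <- b1 * mset[[si]] + (1 - b1) * gv
          vset[[si]] <- b2 * vset[[si]] + (1 - b2) * gv^2
          mhat <- mset[[si]] / (1 - b1^step)
          vhat <- vset[[si]] / (1 - b2^step)
          pv <- .get_slot(params, slots[[si]])
          s3 <- slots[[si]][3]
          if (s3 %in% c("Wx", "Wh", "w")) {
            pv <- pv * (1 - cfg$lr * (cfg$weight_decay %||% 0))
          }
          pv <- pv - cfg$lr * mhat / (sqrt(vhat) + aeps)
          params <- .set_slot(params, slots[[si]], pv)
        }
      }
      tl <- tl / N
      vfw <- .forward(params, xva, mode = "eval")
      vl <- .bce(vfw$logit, yva, cfg$pos_weight)$loss
      hist <- rbind(hist, data.frame(epoch = ep, train_loss = tl, val_loss = vl))
      if (cfg$verbose) {
        message(sprintf("epoch %3d  train %.4f  val %.4f", ep, tl, vl))
      }
      if (vl < best$loss - 1e-6) {
        best <- list(loss = vl, params = params, epoch = ep)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= cfg$patience) break
      }
    }
    model <- list(params = best$params, config = cfg, history = hist,
                  best_epoch = best$epoch)
    class(model) <- "iws_lstm"
    model
  })
}

#' @export
print.iws_lstm <- function(x, ...) {
  cat(sprintf(paste0("iws_lstm: %d-layer LSTM, H=%d, D=%d; trained %d epochs",
                     " (best val loss %.4f at epoch %d)\n"),
              x$params$num_layers, x$params$hidden_dim, x$params$input_dim,
              nrow(x$history), min(x$history$val_loss), x$best_epoch))
  invisible(x)
}
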