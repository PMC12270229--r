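# Independent reference implementations used as oracles. Deliberately
# written in a different style (scalar/per-unit loops, no shared code with
# the package) directly from the gate equations.

# Reference forward pass for one window (T x D matrix) -> logit.
ref_lstm_logit <- function(params, win) {
  H <- params$hidden_dim
  inp <- win
  for (l in seq_len(params$num_layers)) {
    Wx <- params$layers[[l]]$Wx
    Wh <- params$layers[[l]]$Wh
    b <- params$layers[[l]]$b
    h <- rep(0, H)
    cc <- rep(0, H)
    hs <- matrix(0, nrow(inp), H)
    for (t in seq_len(nrow(inp))) {
      x <- inp[t, ]
      for (j in seq_len(H)) {
        ai <- sum(x * Wx[, j]) + sum(h * Wh[, j]) + b[j]
        af <- sum(x * Wx[, H + j]) + sum(h * Wh[, H + j]) + b[H + j]
        ag <- sum(x * Wx[, 2 * H + j]) + sum(h * Wh[, 2 * H + j]) + b[2 * H + j]
        ao <- sum(x * Wx[, 3 * H + j]) + sum(h * Wh[, 3 * H + j]) + b[3 * H + j]
        i_g <- 1 / (1 + exp(-ai))
        f_g <- 1 / (1 + exp(-af))
        g_g <- tanh(ag)
        o_g <- 1 / (1 + exp(-ao))
        hs[t, j] <- NA  # filled after cc update below
        cc_j <- f_g * cc[j] + i_g * g_g
        hs[t, j] <- o_g * tanh(cc_j)
        cc[j] <- cc_j
      }
      h <- hs[t, ]
    }
    inp <- hs
  }
  hT <- inp[nrow(inp), ]
  bn <- params$bn
  hbn <- (hT - bn$mean) / sqrt(bn$var + bn$eps) * bn$gamma + bn$beta
  sum(hbn * params$head$w) + params$head$b
}

# Brute-force AUROC via the Mann-Whitney pair statistic.
mw_auroc <- function(scores, labels) {
  sp <- scores[labels == 1]
  sn <- scores[labels == 0]
  tot <- 0
  for (a in sp) for (b in sn) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(sp) * length(sn))
}

# Brute-force per-epoch labeler: scan every WAT-1 record.
brute_epoch_label <- function(wat1, epoch, epoch_hours = 4) {
  lo <- (epoch - 1) * epoch_hours
  hi <- epoch * epoch_hours
  any(wat1$score >= 3 & wat1$timestamp_h >= lo & wat1$timestamp_h < hi)
}

# Random scaled windows for forward tests.
rand_windows <- function(N, Tn, D, seed) {
  set.seed(seed)
  array(runif(N * Tn * D), c(N, Tn, D))
}
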