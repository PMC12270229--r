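test_that("initialization is deterministic and bounded by 1/sqrt(H)", {
  p1 <- init_params(66, 64, 2, seed = 3)
  p2 <- init_params(66, 64, 2, seed = 3)
  expect_identical(p1, p2)
  allw <- c(unlist(lapply(p1$layers, function(l) c(l$Wx, l$Wh, l$b))),
            p1$head$w, p1$head$b)
  expect_lte(max(abs(allw)), 1 / sqrt(64))
  pH1 <- init_params(3, 1, 1, seed = 1)
  expect_lte(max(abs(c(pH1$layers[[1]]$Wx, pH1$layers[[1]]$Wh))), 1)
  expect_error(init_params(0, 4), "positive")
})

test_that("cell step reproduces hand-evaluated gate equations", {
  H <- 2
  zero <- list(Wx = matrix(0, 3, 4 * H), Wh = matrix(0, H, 4 * H),
               b = rep(0, 4 * H))
  s <- lstm_cell_step(c(1, 2, 3), rep(0, H), rep(0, H), zero)
  expect_equal(s$i, rep(0.5, H))
  expect_equal(s$f, rep(0.5, H))
  expect_equal(s$o, rep(0.5, H))
  expect_equal(s$g, rep(0, H))
  expect_equal(s$c, rep(0, H))
  expect_equal(s$h, rep(0, H))

  # memory preservation: f ~ 1, i ~ 0 keeps the cell state
  keep <- zero
  keep$b[H + 1:H] <- 20   # forget gate
  keep$b[1:H] <- -20      # input gate
  c_prev <- c(0.7, -0.4)
  s2 <- lstm_cell_step(c(0, 0, 0), rep(0, H), c_prev, keep)
  expect_equal(s2$c, c_prev, tolerance = 1e-8)

  # scalar case with all weights 0.5, x = 1: hand-evaluate the equations
  lay <- list(Wx = matrix(0.5, 1, 4), Wh = matrix(0.5, 1, 4), b = 0.5 * rep(1, 4))
  s3 <- lstm_cell_step(1, 0, 0, lay)
  a <- 0.5 * 1 + 0.5 * 0 + 0.5
  i <- 1 / (1 + exp(-a)); f <- i; o <- i; g <- tanh(a)
  cc <- f * 0 + i * g
  expect_equal(s3$i, i, tolerance = 1e-12)
  expect_equal(s3$c, cc, tolerance = 1e-12)
  expect_equal(s3$h, o * tanh(cc), tolerance = 1e-12)

  expect_error(lstm_cell_step(NaN, 0, 0, lay), "non-finite")
})

test_that("forward pass matches the independent reference implementation", {
  # modest size here; the full-size 20-seed sweep lives in the acceptance suite
  for (s in 1:5) {
    p <- init_params(7, 5, 2, seed = s)
    x <- rand_windows(3, 6, 7, seed = 100 + s)
    fw <- lstm_forward(p, x)
    for (n in 1:3) {
      expect_equal(fw$logit[n], ref_lstm_logit(p, x[n, , ]), tolerance = 1e-10)
    }
  }
})

test_that("trace satisfies the hidden-state identity and gate ranges", {
  p <- init_params(10, 8, 2, seed = 11)
  x <- rand_windows(4, 6, 10, seed = 12)
  fw <- lstm_forward(p, x, keep_trace = TRUE)
  for (l in 1:2) {
    tr <- fw$trace[[l]]
    expect_lt(max(abs(tr$h - tr$o * tanh(tr$c))), 1e-10)
    expect_true(all(tr$i > 0 & tr$i < 1))
    expect_true(all(tr$f > 0 & tr$f < 1))
    expect_true(all(tr$o > 0 & tr$o < 1))
    expect_true(all(tr$g > -1 & tr$g < 1))
  }
  expect_true(all(fw$prob > 0 & fw$prob < 1))
})

test_that("eval-mode forward is deterministic and batching-consistent", {
  p <- init_params(6, 4, 2, seed = 2)
  x <- rand_windows(5, 6, 6, seed = 3)
  f1 <- lstm_forward(p, x)
  f2 <- lstm_forward(p, x)
  expect_identical(f1$logit, f2$logit)
  one <- lstm_forward(p, x[2, , ])
  expect_equal(one$logit, f1$logit[2], tolerance = 1e-6)
})

test_that("train and eval mode agree when dropout is off and batch norm frozen", {
  p <- init_params(5, 4, 1, seed = 8)
  x <- rand_windows(16, 6, 5, seed = 9)
  tr <- iwsrisk:::.forward(p, x, mode = "train", dropout_rate = 0,
                           keep_cache = TRUE)
  # freeze running statistics at the batch statistics
  p$bn$mean <- tr$cache$mu
  p$bn$var <- tr$cache$v
  ev <- iwsrisk:::.forward(p, x, mode = "eval")
  expect_equal(tr$logit, ev$logit, tolerance = 1e-6)
})

test_that("analytic gradients match central finite differences", {
  set.seed(42)
  p <- init_params(3, 2, 1, seed = 5)
  x <- array(runif(4 * 6 * 3), c(4, 6, 3))
  y <- c(1, 0, 1, 0)
  lg <- iwsrisk:::.loss_and_grads(p, x, y, dropout_rate = 0, mode = "train")
  h <- 1e-6
  for (s in iwsrisk:::.param_slots(1)) {
    g <- iwsrisk:::.get_slot(lg$grads, s)
    for (idx in seq_len(min(3, length(g)))) {
      v <- iwsrisk:::.get_slot(p, s)
      v1 <- v; v1[idx] <- v1[idx] + h
      v2 <- v; v2[idx] <- v2[idx] - h
      f1 <- iwsrisk:::.loss_and_grads(iwsrisk:::.set_slot(p, s, v1), x, y,
                                      0, mode = "train")$loss
      f2 <- iwsrisk:::.loss_and_grads(iwsrisk:::.set_slot(p, s, v2), x, y,
                                      0, mode = "train")$loss
      num <- (f1 - f2) / (2 * h)
      expect_equal(g[idx], num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces loss on a separable problem, deterministically", {
  set.seed(77)
  N <- 160
  x <- array(runif(N * 6 * 5), c(N, 6, 5))
  y <- rbinom(N, 1, 0.5)
  x[, , 1] <- x[, , 1] * 0.2 + 0.8 * matrix(y, N, 6)  # separable feature
  tr <- list(x = x[1:120, , , drop = FALSE], label = y[1:120])
  va <- list(x = x[121:160, , , drop = FALSE], label = y[121:160])
  cfg <- train_config(hidden_dim = 8, max_epochs = 12, patience = 12,
                      dropout_rate = 0.1, seed = 4)
  m1 <- lstm_train(tr, va, cfg)
  expect_lt(tail(m1$history$train_loss, 1), m1$history$train_loss[1])
  m2 <- lstm_train(tr, va, cfg)
  expect_identical(m1$history, m2$history)   # reproducible trajectory
  expect_identical(m1$params$head$w, m2$params$head$w)

  expect_error(lstm_train(list(x = tr$x, label = rep(1, 120)), va, cfg),
               "single class")
  expect_error(lstm_train(list(x = tr$x[0, , , drop = FALSE],
                               label = integer(0)), va, cfg),
               "empty")
})

test_that("predict_proba is deterministic, in range, and warns on unscaled input", {
  p <- init_params(5, 4, 1, seed = 1)
  m <- list(params = p, config = train_config(hidden_dim = 4, num_layers = 1))
  class(m) <- "iws_lstm"
  x <- rand_windows(6, 6, 5, seed = 2)
  pr <- predict_proba(m, x)
  expect_identical(pr, predict_proba(m, x))
  expect_true(all(pr > 0 & pr < 1))
  xb <- x; xb[1, 1, 1] <- 3
  expect_warning(predict_proba(m, xb), "unscaled")
})

test_that("model bundles round-trip through JSON serialization", {
  set.seed(5)
  N <- 60
  x <- array(runif(N * 6 * 4), c(N, 6, 4))
  y <- rbinom(N, 1, 0.4)
  m <- lstm_train(list(x = x[1:40, , ], label = y[1:40]),
                  list(x = x[41:60, , ], label = y[41:60]),
                  train_config(hidden_dim = 6, num_layers = 2, max_epochs = 3,
                               seed = 2))
  f <- tempfile(fileext = ".json")
  sc <- fit_minmax(matrix(runif(40), 10, 4))
  save_model(m, f, scaling = sc)
  m2 <- load_model(f)
  expect_equal(predict_proba(m2, x), predict_proba(m, x), tolerance = 1e-12)
  expect_equal(attr(m2, "scaling")$min, sc$min, tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(f)
})
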