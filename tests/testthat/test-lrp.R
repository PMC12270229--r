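test_that("epsilon rule redistributes proportionally and conserves at eps 0", {
  expect_equal(lrp_epsilon_linear(1, a = 1, w = 2, z = 2, eps = 0), 1)
  expect_equal(lrp_epsilon_linear(1, a = c(1, 1), w = c(3, 1), z = 4, eps = 0),
               c(0.75, 0.25))
  expect_equal(lrp_epsilon_linear(1, a = c(1, 1), w = c(3, 1), z = 4, eps = 0.4),
               c(3 / 4.4, 1 / 4.4))
  expect_error(lrp_epsilon_linear(1, a = 1, w = 1, z = 0, eps = 0), "zero")
  # matrix form sums over output units
  W <- cbind(c(1, 2), c(3, 0))
  a <- c(1, 1)
  z <- colSums(a * W)
  R <- lrp_epsilon_linear(c(0.5, 0.5), a, W, z, eps = 0)
  expect_equal(sum(R), 1)
})

test_that("hidden-to-cell rule applies the output-gate tanh derivative factor", {
  expect_equal(lrp_hidden_to_cell(0.8, 1, 0), 0.8)
  expect_equal(lrp_hidden_to_cell(5, 0, 2), 0)
  expect_equal(lrp_hidden_to_cell(1, 1, 5), 1 - tanh(5)^2)
})

test_that("cell-split rule partitions by branch magnitude", {
  # f*c_prev = 0.3, i*g = 0.7
  s <- lrp_cell_split(1, f_t = 0.6, c_prev = 0.5, i_t = 1, g_t = 0.7, eps = 0)
  expect_equal(s$forget, 0.3)
  expect_equal(s$input, 0.7)
  s2 <- lrp_cell_split(0.9, 0.5, 0.8, 0.5, 0.8, eps = 0)  # equal branches
  expect_equal(s2$forget, s2$input)
  expect_equal(s2$forget + s2$input, 0.9)
  s3 <- lrp_cell_split(0.4, 0.5, 0.6, 1, 0, eps = 0)      # input branch zero
  expect_equal(s3$forget, 0.4)
  expect_equal(s3$input, 0)
})

test_that("candidate rule is the elementwise input-gate product", {
  expect_equal(lrp_candidate(0.4, 1), 0.4)
  expect_equal(lrp_candidate(0.4, 0), 0)
  expect_equal(lrp_candidate(0.4, 0.5), 0.2)
})

test_that("a model with zero input weights yields an all-zero relevance map", {
  p <- init_params(6, 4, 2, seed = 2)
  for (l in 1:2) p$layers[[l]]$Wx[] <- 0
  w <- matrix(runif(36), 6, 6, dimnames = list(NULL, NULL))
  colnames(w) <- paste0("f", 1:6)
  r <- lrp_explain(p, w)
  expect_true(all(r$map == 0))
  expect_equal(unname(r$aggregate), rep(0, 6))
})

test_that("relevance maps have window shape and additive aggregates", {
  p <- init_params(8, 6, 2, seed = 13)
  w <- matrix(runif(48), 6, 8)
  colnames(w) <- paste0("f", 1:8)
  r <- lrp_explain(p, w)
  expect_equal(dim(r$map), c(6, 8))
  expect_equal(r$aggregate, colSums(r$map), tolerance = 1e-10)
})

test_that("relevance maps converge as epsilon decreases", {
  for (s in 1:3) {
    p <- init_params(6, 5, 2, seed = s)
    set.seed(100 + s)
    w <- matrix(runif(36), 6, 6)
    colnames(w) <- paste0("f", 1:6)
    ref <- lrp_explain(p, w, epsilon = 1e-6)$map
    d <- sapply(c(1e-1, 1e-2, 1e-3, 1e-4), function(e) {
      max(abs(lrp_explain(p, w, epsilon = e)$map - ref))
    })
    expect_true(all(diff(d) < 0))
  }
})

test_that("gate-pinned linear-regime relevance matches the analytic contributions", {
  set.seed(6)
  H <- 6; D <- 10; Tn <- 6
  p <- init_params(D, H, 1, seed = 4)
  p$layers[[1]]$Wh[] <- 0
  p$layers[[1]]$Wx[] <- 0
  Wg <- matrix(rnorm(D * H, 0, 0.01), D, H)
  p$layers[[1]]$Wx[, 2 * H + 1:H] <- Wg
  p$layers[[1]]$b[] <- c(rep(20, H), rep(-20, H), rep(0, H), rep(20, H))
  p$head$w <- rnorm(H, 0, 0.5); p$head$b <- 0
  p$bn <- list(gamma = rep(1, H), beta = rep(0, H), mean = rep(0, H),
               var = rep(1, H), eps = 0)
  w <- matrix(runif(Tn * D), Tn, D)
  colnames(w) <- paste0("f", 1:D)
  r <- lrp_explain(p, w, epsilon = 1e-6)
  analytic <- w[Tn, ] * as.vector(Wg %*% p$head$w)
  expect_gte(cor(r$map[Tn, ], analytic), 0.99)
})

test_that("strict-conservation variant conserves the logit with open input gates", {
  # With the hidden-to-cell pass-through, zero biases elsewhere and input
  # gates pinned open (so the candidate rule's i_t factor is ~1), every
  # remaining rule is exactly proportional and the map total recovers the
  # logit.
  H <- 4; D <- 5
  p <- init_params(D, H, 1, seed = 9)
  p$layers[[1]]$b[] <- 0
  p$layers[[1]]$b[1:H] <- 20       # input gate ~ 1
  p$head$b <- 0
  p$bn <- list(gamma = rep(1, H), beta = rep(0, H), mean = rep(0, H),
               var = rep(1, H), eps = 0)
  w <- matrix(runif(30), 6, D)
  colnames(w) <- paste0("f", 1:D)
  r <- lrp_explain(p, w, epsilon = 0, conservation = "pass_through")
  expect_equal(sum(r$map), r$logit, tolerance = 1e-6)
  # the as-printed variant deliberately rescales; its leakage is reported
  r2 <- lrp_explain(p, w, epsilon = 0)
  expect_equal(r2$leakage, r2$logit - sum(r2$map), tolerance = 1e-12)
})

test_that("aggregated importance ranks and identities behave as defined", {
  m1 <- matrix(0, 6, 3, dimnames = list(NULL, c("a", "b", "c")))
  m1[2, 2] <- 1.5
  r1 <- structure(list(map = m1), class = "iws_relevance")
  agg <- aggregate_importance(list(r1))
  expect_equal(agg$ranking$feature[1], "b")
  expect_equal(agg$feature_total, colSums(agg$mean_map), tolerance = 1e-10,
               ignore_attr = TRUE)
  # two windows with opposite-sign relevance cancel in the signed mean
  m2 <- m1; m2[2, 2] <- -1.5
  r2 <- structure(list(map = m2), class = "iws_relevance")
  agg2 <- aggregate_importance(list(r1, r2))
  expect_equal(unname(agg2$feature_total["b"]), 0)
  expect_gt(unname(agg2$abs_feature_total["b"]), 0)
})

test_that("relevance agrees with occlusion impact on the planted cohort", {
  fxm <- fx_main(101)
  rel <- fxm$rel
  imp <- window_abs_importance(rel)
  model <- fxm$model
  x <- fxm$ds$test$x
  n_use <- min(250, dim(x)[1])
  xs <- x[seq_len(n_use), , , drop = FALSE]
  base <- lstm_forward(model, xs)$logit
  occ <- vapply(seq_len(dim(xs)[3]), function(f) {
    xo <- xs
    xo[, , f] <- 0
    mean(abs(lstm_forward(model, xo)$logit - base))
  }, numeric(1))
  expect_gte(cor(imp, occ, method = "spearman"), 0.7)
})

test_that("recency-planted signal concentrates relevance on the last epoch", {
  fxr <- fx_recency()
  rel <- explain_windows(fxr$model, fxr$ds$test)
  fi <- match("heart_rate_max_delta", rel$feature_names)
  mass <- colMeans(abs(rel$maps[, , fi]))
  expect_gt(mass[6], mass[1])
})
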