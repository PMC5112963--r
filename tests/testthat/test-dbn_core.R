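test_that("logistic is symmetric, saturating and stable", {
  expect_equal(logistic(0), 0.5)
  expect_equal(logistic(700), 1)
  expect_equal(logistic(-700), 0)
  x <- c(-3.2, -0.5, 0.1, 2.7)
  expect_equal(logistic(x) + logistic(-x), rep(1, 4))
})

test_that("up and down passes evaluate the stated formulas", {
  l0 <- zero_layer(5, 3)
  expect_equal(up_pass(l0, rep(0.7, 5)), rep(0.5, 3))
  expect_equal(down_pass(l0, rep(0.2, 3)), rep(0.5, 5))

  # 2-visible / 1-hidden toy, hand evaluation
  l <- zero_layer(2, 1)
  l$W <- matrix(c(1, -1), nrow = 2)
  l$b <- 0.5
  expect_equal(up_pass(l, c(1, 1)), logistic(0.5), tolerance = 1e-12)
  # down pass shares the same symmetric weights
  h <- 0.8
  expect_equal(down_pass(l, h), logistic(c(1, -1) * 0.8), tolerance = 1e-12)
  # round trip matches explicit composition
  v <- c(1, 0)
  expect_equal(down_pass(l, up_pass(l, v)),
               logistic(c(1, -1) * logistic(1 + 0.5)))
})

test_that("matrix and vector forms of the passes agree", {
  set.seed(31)
  l <- rbm_layer(6, 4)
  V <- matrix(runif(18), nrow = 3)
  H <- up_pass(l, V)
  for (i in 1:3) expect_equal(H[i, ], up_pass(l, V[i, ]))
  D <- down_pass(l, H, scale = 0.5)
  for (i in 1:3) expect_equal(D[i, ], down_pass(l, H[i, ], scale = 0.5))
})

test_that("dropout mask silences hidden units completely", {
  set.seed(32)
  l <- rbm_layer(5, 4)
  h <- up_pass(l, runif(5), dropout_mask = c(1, 0, 1, 0))
  expect_equal(h[c(2, 4)], c(0, 0))
  expect_true(all(h[c(1, 3)] > 0))
  expect_equal(up_pass(l, runif(5), dropout_mask = rep(0, 4)), rep(0, 4))
})

test_that("pass dimension mismatches raise errors", {
  l <- rbm_layer(5, 3)
  expect_error(up_pass(l, rep(0.5, 4)), "length 4")
  expect_error(down_pass(l, rep(0.5, 5)), "length 5")
})

test_that("cd1_step matches the hand-computed outer-product update", {
  # deterministic variant: probabilities throughout
  l <- zero_layer(2, 1)
  l$W <- matrix(c(0.3, -0.2), nrow = 2); l$b <- 0.1; l$c <- c(0.05, -0.05)
  v <- c(1, 0); eps <- 0.01
  h_pos <- logistic(0.3 * 1 + (-0.2) * 0 + 0.1)
  v_neg <- logistic(c(0.3, -0.2) * h_pos + l$c)
  h_neg <- logistic(sum(c(0.3, -0.2) * v_neg) + 0.1)
  l2 <- cd1_step(l, v, eps, sampling = "all_probabilities")
  expect_equal(l2$W, l$W + eps * (outer(v, h_pos) - outer(v_neg, h_neg)))
  expect_equal(l2$b, l$b + eps * (h_pos - h_neg))
  expect_equal(l2$c, l$c + eps * (v - v_neg))
})

test_that("cd1_step is a fixed point when the negative phase reproduces the data", {
  # all parameters zero and v = 0.5: h+ = 0.5, v- = 0.5 = v+, h- = h+
  l <- zero_layer(3, 2)
  l2 <- cd1_step(l, rep(0.5, 3), eps = 0.1, sampling = "all_probabilities")
  expect_equal(l2$W, l$W)
  expect_equal(l2$b, l$b)
  expect_equal(l2$c, l$c)
})

test_that("compiled trainer reproduces the pure-R reference", {
  set.seed(33)
  data <- matrix(rbinom(60, 1, 0.4), nrow = 6, ncol = 10)
  cfg <- training_config(epochs = 4, learning_rate = 0.05, dropout_p = 0,
                         sampling = "all_probabilities", shuffle = FALSE)
  set.seed(34); l0 <- rbm_layer(10, 4)
  fast <- train_layer(l0, data, cfg)
  ref <- attnet:::train_layer_r(l0, data, cfg)
  expect_equal(fast$W, ref$W, tolerance = 1e-12)
  expect_equal(fast$b, ref$b, tolerance = 1e-12)
  expect_equal(fast$c, ref$c, tolerance = 1e-12)
  expect_equal(attr(fast, "error_log"), attr(ref, "error_log"),
               tolerance = 1e-12)

  # with per-epoch dropout both sides draw the mask from the same stream
  cfg_d <- training_config(epochs = 3, learning_rate = 0.05, dropout_p = 0.5,
                           sampling = "all_probabilities", shuffle = FALSE)
  set.seed(35); fast_d <- train_layer(l0, data, cfg_d)
  set.seed(35); ref_d <- attnet:::train_layer_r(l0, data, cfg_d)
  expect_equal(fast_d$W, ref_d$W, tolerance = 1e-12)
  expect_equal(fast_d$b, ref_d$b, tolerance = 1e-12)
})

test_that("training with zero epochs or zero rate leaves parameters unchanged", {
  set.seed(36)
  l <- rbm_layer(8, 3)
  data <- matrix(rbinom(40, 1, 0.5), nrow = 5)
  t0 <- train_layer(l, data, training_config(epochs = 0))
  expect_equal(t0$W, l$W)
  expect_equal(t0$b, l$b)
  same <- cd1_step(l, data[1, ], eps = 0, sampling = "all_probabilities")
  expect_equal(same$W, l$W)
})

test_that("CD-1 reduces reconstruction error on a small pattern set", {
  set.seed(37)
  data <- diag(4)[rep(1:4, 5), ] # orthogonal one-hot patterns
  l <- rbm_layer(4, 6)
  fit <- train_layer(l, data, training_config(epochs = 200,
                                              learning_rate = 0.05,
                                              dropout_p = 0))
  log <- attr(fit, "error_log")
  expect_lt(log[200], log[1])
  expect_lt(log[200], 0.2)
})

test_that("trainer is deterministic under a fixed seed", {
  data <- matrix(rbinom(60, 1, 0.3), nrow = 6)
  cfg <- training_config(epochs = 5, learning_rate = 0.02, dropout_p = 0.5)
  set.seed(38); a <- train_layer(rbm_layer(10, 4), data, cfg)
  set.seed(38); b <- train_layer(rbm_layer(10, 4), data, cfg)
  expect_identical(a$W, b$W)
  expect_identical(a$b, b$b)
  expect_identical(attr(a, "error_log"), attr(b, "error_log"))
})

test_that("greedy training respects a modular connectivity mask", {
  set.seed(39)
  mask <- attnet:::block_mask(c(6L, 4L), c(3L, 2L))
  l <- rbm_layer(10, 5, mask = mask)
  expect_true(all(l$W[mask == 0] == 0))
  data <- matrix(rbinom(80, 1, 0.4), nrow = 8)
  fit <- train_layer(l, data, training_config(epochs = 20,
                                              learning_rate = 0.05))
  expect_true(all(fit$W[mask == 0] == 0))
  expect_gt(sum(abs(fit$W[mask == 1])), 0)
})

test_that("each layer of the stack reduces its own reconstruction error", {
  set.seed(40)
  data <- matrix(rbinom(200, 1, 0.3), nrow = 20, ncol = 10)
  net <- deep_net(c(8L, 6L, 4L), n_visible = 10L)
  net <- train_network(net, data, training_config(epochs = 100,
                                                  learning_rate = 0.05,
                                                  dropout_p = 0))
  for (log in attr(net, "error_logs")) expect_lt(log[100], log[1])
})

test_that("reconstruction of an all-zero-parameter net is exactly 0.5", {
  net <- zero_net()
  v <- rbinom(10, 1, 0.5)
  for (d in 1:3) expect_equal(reconstruct(net, v, depth = d), rep(0.5, 10))
})

test_that("reconstruct equals the explicit composition of passes", {
  set.seed(41)
  net <- deep_net(c(6L, 4L, 3L), n_visible = 10L)
  net$trained_with <- training_config(epochs = 1) # dropout 0.5 -> scale 0.5
  v <- runif(10)
  h1 <- up_pass(net$layers[[1]], v)
  h2 <- up_pass(net$layers[[2]], h1)
  h3 <- up_pass(net$layers[[3]], h2)
  d2 <- down_pass(net$layers[[3]], h3, scale = 0.5)
  d1 <- down_pass(net$layers[[2]], d2, scale = 0.5)
  d0 <- down_pass(net$layers[[1]], d1, scale = 0.5)
  expect_equal(reconstruct(net, v, depth = 3), d0, tolerance = 1e-12)
  # depth 1 stops after the first layer
  expect_equal(reconstruct(net, v, depth = 1),
               down_pass(net$layers[[1]], h1, scale = 0.5), tolerance = 1e-12)
  # without retention scaling
  net$trained_with$test_scale <- "none"
  expect_equal(reconstruct(net, v, depth = 1),
               down_pass(net$layers[[1]], h1, scale = 1), tolerance = 1e-12)
})

test_that("a filter excluding every hidden neuron leaves only visible biases", {
  set.seed(42)
  net <- deep_net(c(5L, 4L, 3L), n_visible = 8L)
  net$layers[[1]]$c <- rnorm(8)
  filt <- list(rep(0, 5), rep(0, 4), rep(0, 3))
  v <- runif(8)
  expect_equal(reconstruct(net, v, class_filter = filt),
               logistic(net$layers[[1]]$c))
})

test_that("iterative generation chains full-depth reconstructions", {
  set.seed(43)
  net <- deep_net(c(6L, 4L, 3L), n_visible = 10L)
  net$trained_with <- training_config()
  v0 <- runif(10)
  seqs <- iterate_generation(net, v0, steps = 3)
  expect_length(seqs, 3)
  expect_equal(seqs[[1]], reconstruct(net, v0))
  expect_equal(seqs[[2]], reconstruct(net, seqs[[1]]))
  # a fixed point yields a constant sequence
  net0 <- zero_net()
  const <- iterate_generation(net0, rep(0.5, 10), steps = 4)
  for (s in const) expect_equal(s, rep(0.5, 10))
})

test_that("CD training raises the model probability of the training patterns", {
  # 3-visible / 2-hidden RBM; oracle = brute-force enumeration of all
  # 2^5 joint states via the energy function
  set.seed(44)
  train_pats <- rbind(c(1, 1, 0), c(0, 0, 1))
  data <- train_pats[rep(1:2, 10), ]
  l <- rbm_layer(3, 2)
  fit <- train_layer(l, data, training_config(epochs = 500,
                                              learning_rate = 0.05,
                                              dropout_p = 0))
  all_v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  probs <- apply(all_v, 1, function(v) rbm_unnorm_prob(fit, v))
  is_train <- apply(all_v, 1, function(v)
    any(apply(train_pats, 1, function(tp) all(tp == v))))
  expect_gt(min(probs[is_train]), max(probs[!is_train]))
})

test_that("activations and weights stay finite and in range after training", {
  set.seed(45)
  data <- matrix(rbinom(120, 1, 0.4), nrow = 12)
  l <- train_layer(rbm_layer(10, 5), data,
                   training_config(epochs = 50, learning_rate = 0.1))
  expect_true(all(is.finite(l$W)))
  h <- up_pass(l, data[1, ])
  expect_true(all(h > 0 & h < 1))
  v <- down_pass(l, h)
  expect_true(all(v > 0 & v < 1))
})
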