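# Restricted Boltzmann Machine stack --------------------------------------
#
# Each layer pair is an RBM with one symmetric weight matrix W (visible x
# hidden), hidden biases b and visible biases c. Recognition (up) and
# generation (down) share W. Training is one-step contrastive divergence
# (CD-1) with per-epoch dropout of hidden units; the inner loop lives in
# compiled code (src/cd1.cpp), with a pure-R reference kept for testing.

#' Numerically stable logistic function
#'
#' @param x Numeric vector or matrix.
#' @return `1 / (1 + exp(-x))`, elementwise, in (0, 1).
#' @export
logistic <- function(x) {
  # plogis is the stable base-R implementation of the same function
  stats::plogis(x)
}

#' Create one RBM layer
#'
#' Weights are initialised from Normal(0, sd = 0.1); all biases start at 0.
#' An optional binary connectivity mask (for the modular-architecture
#' control) zeroes the masked weights at initialisation and keeps them at
#' zero through training.
#'
#' @param n_visible,n_hidden Layer dimensions.
#' @param mask Optional `n_visible x n_hidden` 0/1 matrix.
#' @return An object of class `rbm_layer` with fields `W` (`n_visible x
#'   n_hidden`), `b` (hidden biases), `c` (visible biases), `mask`.
#' @export
rbm_layer <- function(n_visible, n_hidden, mask = NULL) {
  W <- matrix(stats::rnorm(n_visible * n_hidden, mean = 0, sd = 0.1),
              nrow = n_visible, ncol = n_hidden)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(W)))
    W <- W * mask
  }
  structure(
    list(W = W, b = numeric(n_hidden), c = numeric(n_visible), mask = mask,
         n_visible = as.integer(n_visible), n_hidden = as.integer(n_hidden)),
    class = "rbm_layer"
  )
}

#' @export
print.rbm_layer <- function(x, ...) {
  cat(sprintf("rbm_layer: %d visible x %d hidden%s\n", x$n_visible,
              x$n_hidden, if (is.null(x$mask)) "" else " (masked)"))
  invisible(x)
}

#' Training configuration
#'
#' @param epochs Training epochs per layer (default 500).
#' @param learning_rate CD-1 learning rate applied per input pattern
#'   (default 0.002; use 0.0002 when dropout is disabled).
#' @param dropout_p Probability that a hidden unit is dropped for an entire
#'   epoch (default 0.5; 0 disables dropout).
#' @param minibatch_size Patterns per parameter update (default 1 = online).
#' @param sampling `"bernoulli_hidden"` (default): the positive-phase hidden
#'   states driving the reconstruction are sampled from Bernoulli(h);
#'   `"all_probabilities"`: probabilities used throughout (deterministic CD).
#' @param test_scale `"retention"` (default): at test time the top-down
#'   contributions are scaled by the retention probability `1 - dropout_p`,
#'   compensating for all hidden units being active; `"none"` disables.
#' @param shuffle Shuffle the pattern order each epoch (default `TRUE`).
#' @return A list of class `training_config`.
#' @export
training_config <- function(epochs = 500L, learning_rate = 0.002,
                            dropout_p = 0.5, minibatch_size = 1L,
                            sampling = c("bernoulli_hidden", "all_probabilities"),
                            test_scale = c("retention", "none"),
                            shuffle = TRUE) {
  sampling <- match.arg(sampling)
  test_scale <- match.arg(test_scale)
  stopifnot(learning_rate > 0, dropout_p >= 0, dropout_p < 1,
            epochs >= 0, minibatch_size >= 1)
  structure(
    list(epochs = as.integer(epochs), learning_rate = learning_rate,
         dropout_p = dropout_p, minibatch_size = as.integer(minibatch_size),
         sampling = sampling, test_scale = test_scale,
         shuffle = isTRUE(shuffle)),
    class = "training_config"
  )
}

#' Create an untrained network (stack of RBM layers)
#'
#' Default architecture: 1925 visible units and hidden layers of 300, 200
#' and 100 neurons. `connectivity = "modular"` restricts the first two
#' layers to channel-wise blocks (stimuli / context / action project to
#' 150/50/100 units, then to 100/25/75 units; the third layer is fully
#' connected) and requires the default visible layout.
#'
#' @param layer_sizes Hidden-layer sizes, bottom-up.
#' @param n_visible Number of visible units.
#' @param connectivity `"full"` or `"modular"`.
#' @param modular_sizes For `"modular"`: list of two length-3 integer vectors
#'   giving the per-block hidden sizes of layers 1 and 2.
#' @return An object of class `deep_net`.
#' @export
deep_net <- function(layer_sizes = c(300L, 200L, 100L),
                     n_visible = n_visible_units,
                     connectivity = c("full", "modular"),
                     modular_sizes = list(c(150L, 50L, 100L),
                                          c(100L, 25L, 75L))) {
  connectivity <- match.arg(connectivity)
  dims <- c(as.integer(n_visible), as.integer(layer_sizes))
  masks <- vector("list", length(layer_sizes))
  if (connectivity == "modular") {
    if (n_visible != n_visible_units)
      stop("modular connectivity requires the standard 1925-unit layout")
    # visible blocks: stimuli (red+green, 1250), context (50), action (625)
    vis_blocks <- c(1250L, 50L, 625L)
    stopifnot(length(layer_sizes) == 3L,
              sum(modular_sizes[[1]]) == layer_sizes[1],
              sum(modular_sizes[[2]]) == layer_sizes[2])
    masks[[1]] <- block_mask(vis_blocks, modular_sizes[[1]])
    masks[[2]] <- block_mask(modular_sizes[[1]], modular_sizes[[2]])
  }
  layers <- vector("list", length(layer_sizes))
  for (k in seq_along(layer_sizes)) {
    layers[[k]] <- rbm_layer(dims[k], dims[k + 1L], mask = masks[[k]])
  }
  structure(
    list(layers = layers, dims = dims, connectivity = connectivity,
         trained_with = NULL),
    class = "deep_net"
  )
}

block_mask <- function(visible_blocks, hidden_blocks) {
  stopifnot(length(visible_blocks) == length(hidden_blocks))
  M <- matrix(0, nrow = sum(visible_blocks), ncol = sum(hidden_blocks))
  voff <- c(0L, cumsum(visible_blocks))
  hoff <- c(0L, cumsum(hidden_blocks))
  for (i in seq_along(visible_blocks)) {
    M[(voff[i] + 1L):voff[i + 1L], (hoff[i] + 1L):hoff[i + 1L]] <- 1
  }
  M
}

#' @export
print.deep_net <- function(x, ...) {
  cat(sprintf("deep_net: %s (%s connectivity)%s\n",
              paste(x$dims, collapse = " -> "), x$connectivity,
              if (is.null(x$trained_with)) ", untrained" else ", trained"))
  invisible(x)
}

as_activation_matrix <- function(v, n_units) {
  if (is.matrix(v)) {
    if (ncol(v) != n_units)
      stop("activation has ", ncol(v), " columns; expected ", n_units)
    v
  } else {
    if (length(v) != n_units)
      stop("activation has length ", length(v), "; expected ", n_units)
    matrix(v, nrow = 1L)
  }
}

#' Bottom-up (recognition) pass through one RBM layer
#'
#' `h_j = logistic(sum_i w_ij v_i + b_j)`. Accepts a single activation
#' vector or a matrix with one pattern per row. Dropped hidden units
#' (0 entries of `dropout_mask`) output exactly 0.
#'
#' @param layer An [rbm_layer()].
#' @param v Visible activations in \[0, 1\] (vector, or matrix rows).
#' @param dropout_mask Optional 0/1 vector over hidden units.
#' @return Hidden probabilities, same shape convention as `v`.
#' @export
up_pass <- function(layer, v, dropout_mask = NULL) {
  vec_in <- !is.matrix(v)
  V <- as_activation_matrix(v, layer$n_visible)
  H <- logistic(sweep(V %*% layer$W, 2L, layer$b, "+"))
  if (!is.null(dropout_mask)) {
    stopifnot(length(dropout_mask) == layer$n_hidden)
    H <- sweep(H, 2L, as.numeric(dropout_mask != 0), "*")
  }
  if (vec_in) drop(H) else H
}

#' Top-down (generative) pass through one RBM layer
#'
#' `v_i = logistic(scale * sum_j w_ij h_j + c_i)` using the same symmetric
#' weights as [up_pass()]. `scale` implements test-time dropout
#' compensation (retention probability).
#'
#' @param layer An [rbm_layer()].
#' @param h Hidden activations (vector, or matrix rows).
#' @param scale Multiplier on the weighted top-down input (default 1).
#' @return Visible probabilities.
#' @export
down_pass <- function(layer, h, scale = 1) {
  vec_in <- !is.matrix(h)
  H <- as_activation_matrix(h, layer$n_hidden)
  V <- logistic(sweep(scale * tcrossprod(H, layer$W), 2L, layer$c, "+"))
  if (vec_in) drop(V) else V
}

#' One CD-1 update for a single pattern (reference implementation)
#'
#' Positive phase: hidden probabilities `h+` from the data `v+`; hidden
#' states driving the reconstruction are Bernoulli samples of `h+` (or the
#' probabilities themselves under `sampling = "all_probabilities"`).
#' Negative phase: `v- = down_pass(states)`, `h- = up_pass(v-)`, both as
#' probabilities. Updates: `dW = eps (v+ h+' - v- h-')`, hidden biases
#' `eps (h+ - h-)`, visible biases `eps (v+ - v-)`; masked connections are
#' never updated. This scalar-loop-free R version is the oracle against
#' which the compiled trainer is checked; [train_layer()] is the fast path.
#'
#' @param layer An [rbm_layer()].
#' @param v Visible pattern in \[0, 1\]^n_visible.
#' @param eps Learning rate.
#' @param dropout_mask Optional 0/1 vector; dropped units neither activate
#'   nor learn.
#' @param sampling See [training_config()].
#' @return The updated `rbm_layer`.
#' @export
cd1_step <- function(layer, v, eps, dropout_mask = NULL,
                     sampling = c("bernoulli_hidden", "all_probabilities")) {
  sampling <- match.arg(sampling)
  stopifnot(length(v) == layer$n_visible)
  h_pos <- up_pass(layer, v, dropout_mask)
  h_state <- if (sampling == "bernoulli_hidden") {
    s <- as.numeric(stats::runif(layer$n_hidden) < h_pos)
    if (!is.null(dropout_mask)) s * (dropout_mask != 0) else s
  } else h_pos
  v_neg <- down_pass(layer, h_state)
  h_neg <- up_pass(layer, v_neg, dropout_mask)
  dW <- eps * (outer(v, h_pos) - outer(v_neg, h_neg))
  if (!is.null(layer$mask)) dW <- dW * layer$mask
  layer$W <- layer$W + dW
  db <- eps * (h_pos - h_neg)
  if (!is.null(dropout_mask)) db <- db * (dropout_mask != 0)
  layer$b <- layer$b + db
  layer$c <- layer$c + eps * (v - v_neg)
  layer
}

#' Train one RBM layer with CD-1
#'
#' For each epoch: draw one dropout mask (each hidden unit dropped for the
#' whole epoch with probability `dropout_p`), shuffle the pattern order, and
#' apply a CD-1 update per pattern (or per minibatch). Runs in compiled
#' code; random draws come from R's global stream.
#'
#' @param layer An [rbm_layer()].
#' @param data Matrix of training activations, one pattern per row.
#' @param config A [training_config()].
#' @return The trained layer, with the per-epoch mean absolute
#'   reconstruction error attached as attribute `"error_log"`.
#' @export
train_layer <- function(layer, data, config = training_config()) {
  data <- as_activation_matrix(data, layer$n_visible)
  if (nrow(data) == 0L) stop("empty training data")
  fit <- cd1_train(
    layer$W, layer$b, layer$c, data,
    epochs = config$epochs, eps = config$learning_rate,
    dropout_p = config$dropout_p, minibatch = config$minibatch_size,
    sample_hidden = config$sampling == "bernoulli_hidden",
    shuffle = config$shuffle,
    mask = if (is.null(layer$mask)) NULL else layer$mask
  )
  layer$W <- fit$W
  layer$b <- drop(fit$b)
  layer$c <- drop(fit$c)
  attr(layer, "error_log") <- drop(fit$error_log)
  layer
}

# Pure-R epoch loop built on cd1_step, used in tests as the independent
# oracle for the compiled trainer. Deterministic settings only
# (all_probabilities, no shuffle), so no RNG-stream alignment is needed.
train_layer_r <- function(layer, data, config = training_config()) {
  stopifnot(config$sampling == "all_probabilities", !config$shuffle)
  data <- as_activation_matrix(data, layer$n_visible)
  n <- nrow(data)
  err <- numeric(config$epochs)
  for (e in seq_len(config$epochs)) {
    mask <- if (config$dropout_p > 0)
      as.numeric(stats::runif(layer$n_hidden) >= config$dropout_p)
    else NULL
    tot <- 0
    for (i in seq_len(n)) {
      v <- data[i, ]
      v_neg <- down_pass(layer, up_pass(layer, v, mask)) # pre-update error
      tot <- tot + mean(abs(v - v_neg))
      layer <- cd1_step(layer, v, config$learning_rate, mask, config$sampling)
    }
    err[e] <- tot / n
  }
  attr(layer, "error_log") <- err
  layer
}

#' Greedy layer-wise training of the full stack
#'
#' Trains layer 1 on the data, propagates the data through the trained
#' layer 1 as deterministic probabilities (no dropout, no sampling), trains
#' layer 2 on those activations, and likewise layer 3. Every layer receives
#' the full epoch budget.
#'
#' @param net A [deep_net()].
#' @param data An `attnet_dataset` or a matrix of visible patterns (rows).
#' @param config A [training_config()].
#' @return The trained `deep_net`; per-layer error logs in
#'   `attr(, "error_logs")`, and the config stored in `$trained_with`.
#' @export
train_network <- function(net, data, config = training_config()) {
  V <- if (inherits(data, "attnet_dataset")) data$V else data
  logs <- vector("list", length(net$layers))
  for (k in seq_along(net$layers)) {
    net$layers[[k]] <- train_layer(net$layers[[k]], V, config)
    logs[[k]] <- attr(net$layers[[k]], "error_log")
    if (k < length(net$layers)) V <- up_pass(net$layers[[k]], V)
  }
  net$trained_with <- config
  attr(net, "error_logs") <- logs
  net
}

down_scale <- function(net) {
  cfg <- net$trained_with
  if (is.null(cfg) || cfg$test_scale == "none") 1 else 1 - cfg$dropout_p
}

apply_filter <- function(H, keep) {
  if (is.null(keep)) return(H)
  if (is.matrix(H)) sweep(H, 2L, as.numeric(keep != 0), "*")
  else H * as.numeric(keep != 0)
}

#' Deterministic mean-field reconstruction
#'
#' Passes the input up through layers `1..depth` and back down, using
#' probabilities throughout (no sampling, no dropout). When the network was
#' trained with dropout and `test_scale = "retention"`, each top-down
#' contribution is scaled by the retention probability to compensate for
#' all hidden units being active. `class_filter` (a list of 0/1 keep
#' vectors, one per hidden layer, as produced by [class_filter()]) zeroes
#' the activations of excluded hidden neurons on both the up and the down
#' pass.
#'
#' @param net A `deep_net` (an untrained net is allowed and reconstructs
#'   near-uniform 0.5).
#' @param v Visible vector, or matrix with one pattern per row.
#' @param depth How many hidden layers participate (1 to
#'   `length(net$layers)`).
#' @param class_filter Optional per-layer keep vectors.
#' @return Reconstructed visible probabilities, same shape as `v`.
#' @export
reconstruct <- function(net, v, depth = length(net$layers),
                        class_filter = NULL) {
  stopifnot(depth >= 1L, depth <= length(net$layers))
  vec_in <- !is.matrix(v)
  A <- as_activation_matrix(v, net$dims[1])
  s <- down_scale(net)
  for (k in seq_len(depth)) {
    A <- up_pass(net$layers[[k]], A)
    if (!is.null(class_filter)) A <- apply_filter(A, class_filter[[k]])
  }
  for (k in rev(seq_len(depth))) {
    A <- down_pass(net$layers[[k]], A, scale = s)
    if (k > 1L && !is.null(class_filter))
      A <- apply_filter(A, class_filter[[k - 1L]])
  }
  if (vec_in) drop(A) else A
}

#' Iterative generation from self-produced input
#'
#' Feeds the network its own full reconstruction: `x_1 = reconstruct(v0)`,
#' `x_{t+1} = reconstruct(x_t)`, always at full depth.
#'
#' @param net A trained `deep_net`.
#' @param v0 Initial visible input (vector or matrix rows).
#' @param steps Number of time steps (>= 1).
#' @return List of length `steps` with the reconstruction at each step.
#' @export
iterate_generation <- function(net, v0, steps = 5L) {
  stopifnot(steps >= 1L)
  out <- vector("list", steps)
  x <- v0
  for (t in seq_len(steps)) {
    x <- reconstruct(net, x)
    out[[t]] <- x
  }
  out
}
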