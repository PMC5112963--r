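# Small deterministic fixtures used across test files.

# An RBM layer with every parameter zero: up/down passes output exactly 0.5.
zero_layer <- function(nv, nh) {
  l <- rbm_layer(nv, nh)
  l$W[] <- 0; l$b[] <- 0; l$c[] <- 0
  l
}

zero_net <- function(sizes = c(6L, 4L, 3L), nv = 10L) {
  net <- deep_net(sizes, n_visible = nv)
  for (k in seq_along(net$layers)) net$layers[[k]] <- zero_layer(
    net$layers[[k]]$n_visible, net$layers[[k]]$n_hidden)
  net
}

# Small random net over the full 1925-unit layout (untrained, for
# structural tests that need real specs).
tiny_full_net <- function(seed = 42) {
  set.seed(seed)
  deep_net(c(12L, 8L, 5L))
}

# Unnormalised probability of a visible state under an RBM, by explicit
# enumeration of all hidden states: p*(v) = sum_h exp(v'Wh + b'h + c'v).
rbm_unnorm_prob <- function(layer, v) {
  nh <- layer$n_hidden
  states <- as.matrix(expand.grid(rep(list(0:1), nh)))
  tot <- 0
  for (r in seq_len(nrow(states))) {
    h <- as.numeric(states[r, ])
    tot <- tot + exp(drop(v %*% layer$W %*% h) + sum(layer$b * h) +
                       sum(layer$c * v))
  }
  tot
}
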