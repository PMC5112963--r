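# Receptive fields and context-dependence classification ------------------

#' Split a visible-length weight vector into the five channels
#'
#' @param w Numeric vector of length 1925.
#' @return Object of class `receptive_field`: named list with `red`,
#'   `green`, `context_a`, `context_b`, `action` components.
#' @export
rf_channels <- function(w) {
  stopifnot(length(w) == n_visible_units)
  out <- lapply(names(channel_offsets), function(ch)
    w[channel_offsets[[ch]] + seq_len(channel_sizes[[ch]])])
  names(out) <- names(channel_offsets)
  structure(out, class = "receptive_field")
}

#' Receptive field of a first-layer neuron
#'
#' The neuron's incoming weight column, split into the five visible
#' channels.
#'
#' @param net A [deep_net()].
#' @param j Hidden-neuron index in layer 1.
#' @return A `receptive_field`.
#' @export
layer1_rf <- function(net, j) {
  W <- net$layers[[1L]]$W
  if (j < 1L || j > ncol(W)) stop("neuron index ", j, " out of range")
  rf_channels(W[, j])
}

threshold_weights <- function(W, theta) {
  W * (abs(W) >= theta)
}

#' Effective receptive field of a deeper neuron
#'
#' Projects a layer-2 or layer-3 neuron to the visible layer through a
#' linear combination of the lower weight matrices, keeping only the
#' stronger connections: each weight matrix is thresholded entrywise
#' (entries with absolute value below `theta` set to 0) and the thresholded
#' matrices are multiplied (`threshold_first`, the default). The
#' alternative `combine_first` multiplies the raw matrices and thresholds
#' the product.
#'
#' @param net A `deep_net`.
#' @param layer 2 or 3 (use [layer1_rf()] for layer 1).
#' @param j Hidden-neuron index in that layer.
#' @param theta Absolute-weight threshold (default 0.5).
#' @param order `"threshold_first"` or `"combine_first"`.
#' @return A `receptive_field`.
#' @export
effective_rf <- function(net, layer, j, theta = 0.5,
                         order = c("threshold_first", "combine_first")) {
  order <- match.arg(order)
  if (layer == 1L) stop("use layer1_rf() for first-layer neurons")
  stopifnot(layer >= 2L, layer <= length(net$layers))
  Ws <- lapply(net$layers[seq_len(layer)], `[[`, "W")
  P <- if (order == "threshold_first") {
    Reduce(`%*%`, lapply(Ws, threshold_weights, theta = theta))
  } else {
    threshold_weights(Reduce(`%*%`, Ws), theta)
  }
  if (j < 1L || j > ncol(P)) stop("neuron index ", j, " out of range")
  rf_channels(P[, j])
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(structure(0, degenerate = TRUE))
  stats::cor(x, y)
}

#' Classify one neuron as context-dependent or -independent
#'
#' The context score is the difference between the mean context-A and mean
#' context-B incoming weights; a neuron whose absolute score is below
#' `theta_ctx` is context-independent (`"none"`), otherwise it prefers the
#' stronger context (`"cA_gt_cB"` / `"cB_gt_cA"`). Also reports the Pearson
#' correlations between the action map and each colour map (0, flagged
#' `degenerate`, if either map has zero variance).
#'
#' @param rf A `receptive_field`.
#' @param theta_ctx Context-sensitivity threshold (default 0.3).
#' @return List with `context_class`, `context_score`, `r_action_red`,
#'   `r_action_green`.
#' @export
classify_neuron <- function(rf, theta_ctx = 0.3) {
  s <- mean(rf$context_a) - mean(rf$context_b)
  cls <- if (abs(s) < theta_ctx) "none" else if (s > 0) "cA_gt_cB" else "cB_gt_cA"
  list(context_class = cls, context_score = s,
       r_action_red = safe_cor(rf$action, rf$red),
       r_action_green = safe_cor(rf$action, rf$green))
}

#' Classify every hidden neuron of the network
#'
#' @param net A trained `deep_net`.
#' @param theta Weight threshold for effective receptive fields of layers
#'   2-3 (default 0.5).
#' @param theta_ctx Context-sensitivity threshold (default 0.3).
#' @return A data frame with one row per hidden neuron: `layer`, `index`,
#'   `context_class`, `context_score`, `r_action_red`, `r_action_green`.
#' @export
classify_population <- function(net, theta = 0.5, theta_ctx = 0.3) {
  rows <- list()
  for (k in seq_along(net$layers)) {
    nh <- net$layers[[k]]$n_hidden
    for (j in seq_len(nh)) {
      rf <- if (k == 1L) layer1_rf(net, j)
            else effective_rf(net, k, j, theta = theta)
      cl <- classify_neuron(rf, theta_ctx = theta_ctx)
      rows[[length(rows) + 1L]] <- data.frame(
        layer = k, index = j, context_class = cl$context_class,
        context_score = cl$context_score,
        r_action_red = as.numeric(cl$r_action_red),
        r_action_green = as.numeric(cl$r_action_green),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Per-layer proportions of context-dependent and -independent neurons
#'
#' @param classification Result of [classify_population()].
#' @return Data frame with `layer`, `context_independent`,
#'   `context_dependent` (proportions summing to 1 per layer).
#' @export
class_proportions <- function(classification) {
  out <- do.call(rbind, lapply(split(classification, classification$layer),
    function(d) data.frame(
      layer = d$layer[1L],
      context_independent = mean(d$context_class == "none"),
      context_dependent = mean(d$context_class != "none"))))
  rownames(out) <- NULL
  out
}

#' Build a per-layer activation filter keeping one neuron class
#'
#' @param classification Result of [classify_population()].
#' @param keep `"context_independent"` or `"context_dependent"`.
#' @return List of 0/1 keep vectors, one per hidden layer, usable as the
#'   `class_filter` argument of [reconstruct()] and [evaluate_condition()].
#' @export
class_filter <- function(classification,
                         keep = c("context_independent", "context_dependent")) {
  keep <- match.arg(keep)
  lapply(split(classification, classification$layer), function(d) {
    indep <- d$context_class[order(d$index)] == "none"
    as.numeric(if (keep == "context_independent") indep else !indep)
  })
}

#' Evaluate the network with only one neuron class operating
#'
#' Zeroes the activations of the excluded class in all hidden layers on
#' both the recognition and the generation pass, then evaluates the test
#' set.
#'
#' @param net A trained `deep_net`.
#' @param keep Neuron class allowed to operate.
#' @param test_set An `attnet_dataset`.
#' @param classification Optional precomputed [classify_population()]
#'   result (recomputed if missing).
#' @param theta,theta_ctx Classification thresholds.
#' @return A `region_means` vector.
#' @export
class_ablation <- function(net, keep = c("context_independent",
                                         "context_dependent"),
                           test_set, classification = NULL,
                           theta = 0.5, theta_ctx = 0.3) {
  keep <- match.arg(keep)
  if (is.null(classification))
    classification <- classify_population(net, theta = theta,
                                          theta_ctx = theta_ctx)
  filt <- class_filter(classification, keep)
  evaluate_condition(net, test_set, class_filter = filt)
}
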