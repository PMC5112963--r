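# Region-wise reconstruction metrics and condition-level analyses ---------

region_names <- c("relevant_stim", "irrelevant_stim", "correct_action",
                  "incorrect_action", "correct_context", "incorrect_context",
                  "remaining")

#' Partition the visible layer into the seven evaluation regions
#'
#' For a double-stimulus trial: the 25 units of the context-relevant
#' stimulus in its colour channel, the 25 units of the irrelevant stimulus,
#' the 25 action units at the relevant position (correct action), the 25
#' action units at the irrelevant position (incorrect action), the two
#' 25-unit context blocks, and all remaining units. The seven sets
#' partition the 1925 indices.
#'
#' @param spec A double-stimulus [pattern_spec()].
#' @return Named list of seven disjoint (1-based) integer index vectors.
#' @export
region_masks <- function(spec) {
  if (!is_double_stimulus(spec))
    stop("region masks are defined for double-stimulus patterns only")
  red_relevant <- spec$context == "A"
  rel <- square_indices(if (red_relevant) spec$red_pos else spec$green_pos,
                        if (red_relevant) "red" else "green")
  irr <- square_indices(if (red_relevant) spec$green_pos else spec$red_pos,
                        if (red_relevant) "green" else "red")
  act_ok <- square_indices(spec$action_pos, "action")
  irr_pos <- if (red_relevant) spec$green_pos else spec$red_pos
  act_bad <- square_indices(irr_pos, "action")
  ctx_ok <- channel_offsets[[if (red_relevant) "context_a" else "context_b"]] + 1:25
  ctx_bad <- channel_offsets[[if (red_relevant) "context_b" else "context_a"]] + 1:25
  named <- list(relevant_stim = rel, irrelevant_stim = irr,
                correct_action = act_ok, incorrect_action = act_bad,
                correct_context = ctx_ok, incorrect_context = ctx_bad)
  named$remaining <- setdiff(seq_len(n_visible_units), unlist(named))
  named
}

#' Mean activation of a reconstruction over the seven regions
#'
#' @param recon Numeric vector of length 1925 (reconstruction
#'   probabilities).
#' @param spec The double-stimulus [pattern_spec()] that defines the
#'   regions.
#' @return Named numeric vector of seven means (class `region_means`).
#' @export
region_means <- function(recon, spec) {
  stopifnot(length(recon) == n_visible_units)
  masks <- region_masks(spec)
  out <- vapply(masks, function(idx) mean(recon[idx]), numeric(1))
  class(out) <- c("region_means", class(out))
  out
}

region_means_matrix <- function(R, specs) {
  stopifnot(nrow(R) == length(specs))
  out <- matrix(NA_real_, nrow = length(specs), ncol = length(region_names),
                dimnames = list(NULL, region_names))
  for (i in seq_along(specs)) {
    masks <- region_masks(specs[[i]])
    for (r in region_names) out[i, r] <- mean(R[i, masks[[r]]])
  }
  out
}

#' Evaluate a trained network on a test set
#'
#' Reconstructs every test pattern with a deterministic mean-field pass
#' ([reconstruct()]) and averages the seven region means over patterns.
#'
#' @param net A trained [deep_net()].
#' @param test_set An `attnet_dataset` (condition `"complete"` or
#'   `"no_action"`).
#' @param depth Number of hidden layers allowed to operate.
#' @param class_filter Optional per-layer keep vectors (see
#'   [class_filter()]).
#' @return A `region_means` vector averaged over the test patterns.
#' @export
evaluate_condition <- function(net, test_set, depth = length(net$layers),
                               class_filter = NULL) {
  R <- reconstruct(net, test_set$V, depth = depth, class_filter = class_filter)
  out <- colMeans(region_means_matrix(R, test_set$specs))
  class(out) <- c("region_means", class(out))
  out
}

#' Replication-level region means
#'
#' Evaluates each trained replication network on the same test set,
#' returning one row of region means per replication.
#'
#' @param nets List of trained `deep_net` objects.
#' @inheritParams evaluate_condition
#' @return Matrix (replications x regions).
#' @export
replication_means <- function(nets, test_set, depth = NULL,
                              class_filter = NULL) {
  rows <- lapply(nets, function(net)
    evaluate_condition(net, test_set,
                       depth = if (is.null(depth)) length(net$layers) else depth,
                       class_filter = class_filter))
  do.call(rbind, rows)
}

#' Compare a region between two sets of replications
#'
#' A t-test treating replications as individuals: paired when the two
#' samples come from the same trained networks (the usual case), Welch
#' two-sample otherwise.
#'
#' @param a,b Numeric vectors (one value per replication), or matrices of
#'   replication-level region means from [replication_means()].
#' @param field Region name, required when `a`/`b` are matrices.
#' @param paired Use a paired test (default `TRUE`).
#' @return List with `t`, `df`, `p` (two-tailed), and the two means.
#' @export
compare_conditions <- function(a, b, field = NULL, paired = TRUE) {
  if (is.matrix(a)) { stopifnot(!is.null(field)); a <- a[, field] }
  if (is.matrix(b)) { stopifnot(!is.null(field)); b <- b[, field] }
  if (length(a) < 2L || length(b) < 2L)
    stop("need at least two replications per sample")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal replication counts")
  if (paired && all(a == b))
    return(list(t = 0, df = length(a) - 1L, p = 1,
                mean_a = mean(a), mean_b = mean(b)))
  ht <- stats::t.test(a, b, paired = paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}

#' Layer-ablation analysis
#'
#' Evaluates the network with only the first, the first two, and all three
#' hidden layers allowed to operate.
#'
#' @param net A trained `deep_net`.
#' @param test_set Typically the no-action test set.
#' @return Matrix (depth x regions) with rownames `"depth1"`, ...
#' @export
run_layer_ablation <- function(net, test_set) {
  depths <- seq_along(net$layers)
  out <- do.call(rbind, lapply(depths, function(d)
    evaluate_condition(net, test_set, depth = d)))
  rownames(out) <- paste0("depth", depths)
  out
}

#' Iterative-generation analysis
#'
#' Lets the network run on its own full-depth reconstruction for `steps`
#' time steps and averages the region means per step over the test set.
#'
#' @param net A trained `deep_net`.
#' @param test_set Typically the no-action test set.
#' @param steps Number of self-generation steps (default 5).
#' @return Matrix (steps x regions) with rownames `"step1"`, ...
#' @export
run_iterative_generation <- function(net, test_set, steps = 5L) {
  seqs <- iterate_generation(net, test_set$V, steps = steps)
  out <- do.call(rbind, lapply(seqs, function(R)
    colMeans(region_means_matrix(R, test_set$specs))))
  rownames(out) <- paste0("step", seq_len(steps))
  out
}
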