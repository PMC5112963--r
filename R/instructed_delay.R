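# Instructed-delay protocol ----------------------------------------------
#
# Eight processing time steps: the first item is presented externally at
# steps 1-2, a blank at steps 3-4, the second item at steps 5-6 and a final
# blank at steps 7-8. "Item" is either the two stimulus maps or the context
# block, depending on the presentation order. The action channel is never
# provided externally. From step 2 onward the network input mixes the
# external pattern (9/10) with the network's previous reconstruction
# (1/10).

#' Build the 8-step external-input schedule for one trial
#'
#' @param spec A double-stimulus [pattern_spec()].
#' @param order `"stimuli_first"`: stimuli at steps 1-2, context at steps
#'   5-6; `"context_first"`: the reverse.
#' @return Object of class `delay_schedule`: an 8 x 1925 matrix of external
#'   inputs (`$ext`) plus the spec and order. Channels not presented at a
#'   step are externally zero.
#' @export
build_schedule <- function(spec, order = c("stimuli_first", "context_first")) {
  order <- match.arg(order)
  if (!is_double_stimulus(spec))
    stop("the instructed-delay protocol requires a double-stimulus pattern")
  stim <- numeric(n_visible_units)
  stim[square_indices(spec$red_pos, "red")] <- 1
  stim[square_indices(spec$green_pos, "green")] <- 1
  ctx <- numeric(n_visible_units)
  ctx_name <- if (spec$context == "A") "context_a" else "context_b"
  ctx[channel_offsets[[ctx_name]] + 1:25] <- 1
  first <- if (order == "stimuli_first") stim else ctx
  second <- if (order == "stimuli_first") ctx else stim
  blank <- numeric(n_visible_units)
  ext <- rbind(first, first, blank, blank, second, second, blank, blank)
  rownames(ext) <- paste0("step", 1:8)
  structure(list(ext = ext, spec = spec, order = order),
            class = "delay_schedule")
}

#' Run one instructed-delay trial
#'
#' Step 1 input is fully external; for steps t >= 2 the input is
#' `0.9 * ext_t + 0.1 * recon_{t-1}` where `recon` is the full-depth
#' mean-field reconstruction. Returns the per-step region means.
#'
#' @param net A trained [deep_net()].
#' @param schedule A [build_schedule()] result.
#' @param keep_recons Also return the 8 raw reconstructions?
#' @return A `time_course`: an 8 x 7 matrix of region means (and
#'   `attr(,"recons")` if requested).
#' @export
run_trial <- function(net, schedule, keep_recons = FALSE) {
  ext <- schedule$ext
  recons <- matrix(NA_real_, nrow = 8L, ncol = n_visible_units)
  input <- ext[1L, ]
  for (t in 1:8) {
    if (t > 1L) input <- 0.9 * ext[t, ] + 0.1 * recons[t - 1L, ]
    recons[t, ] <- reconstruct(net, input)
  }
  tc <- t(apply(recons, 1L, region_means, spec = schedule$spec))
  colnames(tc) <- region_names
  rownames(tc) <- paste0("step", 1:8)
  class(tc) <- c("time_course", class(tc))
  if (keep_recons) attr(tc, "recons") <- recons
  tc
}

#' Run the instructed-delay experiment over many trials
#'
#' Vectorised over trials: all external schedules are stacked and the
#' 8-step mixing recursion is applied to the whole batch at once.
#'
#' @param net A trained `deep_net`.
#' @param specs List of double-stimulus [pattern_spec()]s (the trials).
#' @param order Presentation order, see [build_schedule()].
#' @return List with `mean` (8 x 7 matrix of region means averaged over
#'   trials) and `per_trial` (trials x 8 x 7 array).
#' @export
run_delay_experiment <- function(net, specs,
                                 order = c("stimuli_first", "context_first")) {
  order <- match.arg(order)
  n <- length(specs)
  schedules <- lapply(specs, build_schedule, order = order)
  per_trial <- array(NA_real_, dim = c(n, 8L, length(region_names)),
                     dimnames = list(NULL, paste0("step", 1:8), region_names))
  R_prev <- NULL
  for (t in 1:8) {
    EXT <- do.call(rbind, lapply(schedules, function(s) s$ext[t, ]))
    input <- if (t == 1L) EXT else 0.9 * EXT + 0.1 * R_prev
    R_prev <- reconstruct(net, input)
    per_trial[, t, ] <- region_means_matrix(R_prev, specs)
  }
  list(mean = apply(per_trial, c(2L, 3L), mean), per_trial = per_trial)
}
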