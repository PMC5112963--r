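# Study orchestration: baseline and control conditions --------------------

study_conditions <- c("baseline", "no_single_stim", "half_epochs",
                      "double_epochs", "no_dropout", "two_locations",
                      "modular", "half_neurons", "double_neurons")

#' Configuration for one experimental condition
#'
#' Returns the full recipe for a named condition: training-set options,
#' network architecture and training hyperparameters. The conditions are
#' the baseline plus eight controls: training on double-stimulus patterns
#' only; half (250) or double (1000) learning epochs; no dropout (with
#' learning rate 0.0002); stimuli restricted to two corner locations in
#' training and testing; a modular architecture whose first two layers
#' process stimuli/context/action in separate blocks (150/50/100 then
#' 100/25/75 units, third layer of 100 fully connected); and halved
#' (150, 100, 50) or doubled (600, 400, 200) hidden-layer sizes.
#'
#' `scale` shrinks epochs, training patterns and hidden-layer sizes
#' uniformly for reduced-scale runs (block sizes of the modular
#' architecture are scaled the same way).
#'
#' @param condition One of `"baseline"`, `"no_single_stim"`,
#'   `"half_epochs"`, `"double_epochs"`, `"no_dropout"`, `"two_locations"`,
#'   `"modular"`, `"half_neurons"`, `"double_neurons"`.
#' @param scale Positive multiplier on epochs, training-set size and layer
#'   sizes (default 1 = the full-scale study).
#' @param n_train Base training-set size before scaling (default 5000).
#' @param epochs,layer_sizes Optional explicit overrides applied after the
#'   condition defaults and before scaling, for non-uniform reduced
#'   protocols (e.g. 100 epochs, 1000 patterns, 150/100/50 units).
#' @param ... Further arguments for [training_config()] (e.g. `sampling`,
#'   `test_scale`).
#' @return A list of class `study_config`.
#' @export
study_config <- function(condition = study_conditions, scale = 1,
                         n_train = 5000L, epochs = NULL, layer_sizes = NULL,
                         ...) {
  condition <- match.arg(condition)
  stopifnot(scale > 0)
  epochs_override <- epochs
  sizes_override <- layer_sizes
  epochs <- 500L
  lr <- 0.002
  dropout <- 0.5
  sizes <- c(300L, 200L, 100L)
  connectivity <- "full"
  modular_sizes <- list(c(150L, 50L, 100L), c(100L, 25L, 75L))
  double_only <- FALSE
  two_locations <- FALSE
  switch(condition,
    no_single_stim = { double_only <- TRUE },
    half_epochs = { epochs <- 250L },
    double_epochs = { epochs <- 1000L },
    no_dropout = { dropout <- 0; lr <- 0.0002 },
    two_locations = { two_locations <- TRUE },
    modular = { connectivity <- "modular" },
    half_neurons = { sizes <- c(150L, 100L, 50L) },
    double_neurons = { sizes <- c(600L, 400L, 200L) },
    baseline = NULL
  )
  if (!is.null(epochs_override)) epochs <- as.integer(epochs_override)
  if (!is.null(sizes_override) && connectivity == "full")
    sizes <- as.integer(sizes_override)
  scale_int <- function(x, lo = 2L) pmax(lo, as.integer(round(x * scale)))
  if (scale != 1) {
    epochs <- scale_int(epochs, lo = 1L)
    n_train <- max(4L, 4L * as.integer(round(n_train * scale / 4)))
    sizes <- scale_int(sizes)
    modular_sizes <- lapply(modular_sizes, scale_int)
    if (connectivity == "modular") sizes <- vapply(modular_sizes, sum, 1L)
  }
  structure(
    list(condition = condition, scale = scale, n_train = n_train,
         layer_sizes = sizes, connectivity = connectivity,
         modular_sizes = modular_sizes,
         double_only = double_only, two_locations = two_locations,
         training = training_config(epochs = epochs, learning_rate = lr,
                                    dropout_p = dropout, ...)),
    class = "study_config"
  )
}

#' @export
print.study_config <- function(x, ...) {
  cat(sprintf(
    "study_config '%s': %d patterns, layers %s (%s), %d epochs, lr %g, dropout %g\n",
    x$condition, x$n_train, paste(x$layer_sizes, collapse = "/"),
    x$connectivity, x$training$epochs, x$training$learning_rate,
    x$training$dropout_p))
  invisible(x)
}

#' Train one replication of a condition
#'
#' Seeds the RNG, draws a fresh training set and a fresh weight
#' initialisation, and trains the stack greedily.
#'
#' @param cfg A [study_config()].
#' @param seed Integer seed for this replication.
#' @return A trained [deep_net()].
#' @export
train_replication <- function(cfg, seed) {
  set.seed(seed)
  train <- generate_training_set(cfg$n_train, two_locations = cfg$two_locations,
                                 double_only = cfg$double_only)
  net <- deep_net(cfg$layer_sizes, connectivity = cfg$connectivity,
                  modular_sizes = cfg$modular_sizes)
  train_network(net, train, cfg$training)
}

#' Run a full condition: replications, evaluation, summary
#'
#' Trains `n_reps` networks with different seeds, evaluates each on fresh
#' complete-input and no-action test sets, and (optionally) runs the
#' deeper analyses.
#'
#' @param cfg A [study_config()].
#' @param n_reps Number of replications (the full study uses 10).
#' @param seed Base seed; replication r uses `seed + 1000 * r`.
#' @param n_test Test patterns per condition (default 1000).
#' @param analyses Character subset of `"layers"`, `"generation"`,
#'   `"delay"`, `"receptive_fields"`, `"class_ablation"` to run in
#'   addition to the two reconstruction conditions.
#' @return A `study_result` list: `complete` and `no_action`
#'   replication-by-region matrices, per-analysis results, the config and
#'   seeds.
#' @export
run_study <- function(cfg, n_reps = 10L, seed = 1L, n_test = 1000L,
                      analyses = character()) {
  seeds <- seed + 1000L * seq_len(n_reps)
  nets <- lapply(seeds, function(s) train_replication(cfg, s))
  set.seed(seed + 500L)
  test_complete <- generate_test_set(n_test, "complete",
                                     two_locations = cfg$two_locations)
  test_noact <- generate_test_set(n_test, "no_action",
                                  two_locations = cfg$two_locations)
  res <- list(config = cfg, seeds = seeds,
              complete = replication_means(nets, test_complete),
              no_action = replication_means(nets, test_noact))
  if ("layers" %in% analyses)
    res$layers <- lapply(nets, run_layer_ablation, test_set = test_noact)
  if ("generation" %in% analyses)
    res$generation <- lapply(nets, run_iterative_generation,
                             test_set = test_noact)
  if ("delay" %in% analyses) {
    res$delay <- list(
      stimuli_first = lapply(nets, run_delay_experiment,
                             specs = test_noact$specs, order = "stimuli_first"),
      context_first = lapply(nets, run_delay_experiment,
                             specs = test_noact$specs, order = "context_first"))
  }
  if (any(c("receptive_fields", "class_ablation") %in% analyses)) {
    res$classification <- lapply(nets, classify_population)
    res$proportions <- lapply(res$classification, class_proportions)
  }
  if ("class_ablation" %in% analyses) {
    res$ablation <- list(
      independent_complete = mapply(function(n, cl)
        class_ablation(n, "context_independent", test_complete, cl),
        nets, res$classification, SIMPLIFY = FALSE),
      independent_no_action = mapply(function(n, cl)
        class_ablation(n, "context_independent", test_noact, cl),
        nets, res$classification, SIMPLIFY = FALSE),
      dependent_complete = mapply(function(n, cl)
        class_ablation(n, "context_dependent", test_complete, cl),
        nets, res$classification, SIMPLIFY = FALSE))
  }
  res$nets <- nets
  class(res) <- "study_result"
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("study_result '%s', %d replications\n", x$config$condition,
              length(x$seeds)))
  print(round(summary_row(x), 3))
  invisible(x)
}

#' One summary row (complete-input means and SDs) for a condition
#'
#' The four headline quantities of the control-condition table: mean
#' reconstruction of the relevant stimulus, the irrelevant stimulus, the
#' correct action and the incorrect action under complete input, with
#' between-replication standard deviations.
#'
#' @param res A `study_result`.
#' @return Named numeric vector.
#' @export
summary_row <- function(res) {
  m <- res$complete
  cols <- c("relevant_stim", "irrelevant_stim", "correct_action",
            "incorrect_action")
  out <- c(colMeans(m[, cols, drop = FALSE]),
           apply(m[, cols, drop = FALSE], 2L, stats::sd))
  names(out) <- c(cols, paste0(cols, "_sd"))
  out
}

#' Write the result tables of one or more conditions to CSV
#'
#' Emits a per-replication long table (`regions.csv`: condition,
#' replication, input condition, region, mean) and a condition-level
#' summary (`summary.csv`) in the style of the control-condition table.
#'
#' @param results A `study_result` or list of them.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the summary data frame.
#' @export
report <- function(results, dir) {
  if (inherits(results, "study_result")) results <- list(results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- list(); summ <- list()
  for (res in results) {
    cond <- res$config$condition
    for (input in c("complete", "no_action")) {
      m <- res[[input]]
      for (r in seq_len(nrow(m))) for (g in colnames(m)) {
        long[[length(long) + 1L]] <- data.frame(
          condition = cond, replication = r, input = input, region = g,
          mean = m[r, g], stringsAsFactors = FALSE)
      }
    }
    summ[[length(summ) + 1L]] <- data.frame(
      condition = cond, t(summary_row(res)), stringsAsFactors = FALSE)
  }
  long <- if (length(long)) do.call(rbind, long) else
    data.frame(condition = character(), replication = integer(),
               input = character(), region = character(), mean = numeric())
  summ <- if (length(summ)) do.call(rbind, summ) else
    data.frame(condition = character())
  utils::write.csv(long, file.path(dir, "regions.csv"), row.names = FALSE)
  utils::write.csv(summ, file.path(dir, "summary.csv"), row.names = FALSE)
  invisible(summ)
}
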