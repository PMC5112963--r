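# Reduced-scale study fixtures shared across the acceptance tests.
#
# The reduced protocol trains the baseline task at 100 epochs, 1000 training
# patterns and hidden layers of 150/100/50 units, with 2 replications --
# small enough for a test run, large enough for the qualitative effects.
# Networks are trained once per session and cached.

.reduced_cache <- new.env(parent = emptyenv())

reduced_config <- function(condition = "baseline") {
  study_config(condition, n_train = 1000, epochs = 100,
               layer_sizes = c(150, 100, 50))
}

reduced_nets <- function(condition = "baseline", n_reps = 2L) {
  key <- paste0(condition, n_reps)
  if (is.null(.reduced_cache[[key]])) {
    cfg <- reduced_config(condition)
    .reduced_cache[[key]] <- lapply(seq_len(n_reps), function(r)
      train_replication(cfg, seed = 20160 + r))
  }
  .reduced_cache[[key]]
}

# The package's reporting scale: about a third of the full study's weight
# updates, enough for the selective-attention effect to be measurable.
mid_nets <- function(n_reps = 2L) {
  if (is.null(.reduced_cache$mid)) {
    cfg <- study_config("baseline", n_train = 2500, epochs = 150,
                        layer_sizes = c(300, 200, 100))
    .reduced_cache$mid <- lapply(seq_len(n_reps), function(r)
      train_replication(cfg, seed = 55000 + r))
  }
  .reduced_cache$mid
}

reduced_test_set <- function(condition = "complete", two_locations = FALSE) {
  key <- paste0("ts_", condition, two_locations)
  if (is.null(.reduced_cache[[key]])) {
    set.seed(1115)
    .reduced_cache[[key]] <- generate_test_set(1000, condition,
                                               two_locations = two_locations)
  }
  .reduced_cache[[key]]
}
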