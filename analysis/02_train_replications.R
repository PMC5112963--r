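#!/usr/bin/env Rscript
# Step 2 -- train the replications.
#
# Trains baseline networks (greedy layer-wise CD-1 with per-epoch dropout)
# and stores them under scratch/models/ for the later analysis steps.
#
# By default this runs the package's reporting scale -- 150 epochs, 2500
# training patterns, hidden layers 300/200/100, 2 replications (about 3
# minutes each on one core) -- roughly a third of the full study's weight
# updates, enough for the selective-attention effect to be clearly
# measurable. For the full-scale study set FULL <- TRUE below (500 epochs,
# 5000 patterns, 10 replications; a multi-hour job).

library(attnet)

FULL <- FALSE
n_reps <- if (FULL) 10L else 2L
cfg <- if (FULL) study_config("baseline") else
  study_config("baseline", n_train = 2500, epochs = 150,
               layer_sizes = c(300, 200, 100))
print(cfg)

dir.create("scratch/models", recursive = TRUE, showWarnings = FALSE)
for (r in seq_len(n_reps)) {
  t0 <- Sys.time()
  net <- train_replication(cfg, seed = 20160 + r)
  took <- round(as.numeric(Sys.time() - t0, units = "mins"), 1)
  final_err <- vapply(attr(net, "error_logs"), function(e) e[length(e)],
                      numeric(1))
  cat(sprintf("replication %d: %.1f min, final layer errors %s\n",
              r, took, paste(round(final_err, 4), collapse = " / ")))
  saveRDS(net, sprintf("scratch/models/baseline_rep%02d.rds", r))
}
cat("Models written to scratch/models/\n")
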