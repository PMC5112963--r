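#!/usr/bin/env Rscript
# Step 5 -- instructed-delay time courses.
#
# Eight-step presentation schedules with 9:1 external/self-generated input
# mixing, in two orders. Stimuli first: both candidate actions activate
# equally until the context arrives (step 5), then the incorrect action is
# suppressed while the correct one does not increase. Context first: the
# actions only activate once the stimuli appear, with an immediate
# advantage for the correct one.

library(attnet)

models <- sort(Sys.glob("scratch/models/baseline_rep*.rds"))
stopifnot(length(models) >= 2)
nets <- lapply(models, readRDS)

set.seed(4)
specs <- generate_test_set(1000, "no_action")$specs[1:500]

rows <- list()
for (ord in c("stimuli_first", "context_first")) {
  per_net <- lapply(nets, function(net)
    run_delay_experiment(net, specs, ord)$mean)
  m <- Reduce(`+`, per_net) / length(per_net)
  cat("\nOrder:", ord, "\n")
  print(round(m[, c("relevant_stim", "irrelevant_stim", "correct_action",
                    "incorrect_action")], 3))
  rows[[ord]] <- data.frame(order = ord, step = 1:8, m)
}

dir.create("results", showWarnings = FALSE)
write.csv(do.call(rbind, rows), "results/instructed_delay.csv",
          row.names = FALSE)
cat("Wrote results/instructed_delay.csv\n")
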