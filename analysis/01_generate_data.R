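#!/usr/bin/env Rscript
# Step 1 -- the task data.
#
# Builds the context-dependent stimulus->action dataset: 1925-unit binary
# patterns (red map, green map, two context blocks, action map). The full
# study uses 5000 training patterns (half single-, half double-stimulus,
# contexts balanced) and 1000-pattern double-stimulus test sets per input
# condition. Writes a composition summary to results/.

library(attnet)

dir.create("results", showWarnings = FALSE)
set.seed(1)

train <- generate_training_set(5000)
test_complete <- generate_test_set(1000, "complete")
test_noact <- generate_test_set(1000, "no_action")

print(train)
print(test_complete)

two <- vapply(train$specs, attnet:::is_double_stimulus, logical(1))
ctx <- vapply(train$specs, function(s) s$context, character(1))
summary <- data.frame(
  set = c("train", "train", "test_complete", "test_no_action"),
  group = c("single_stimulus", "double_stimulus", "all", "all"),
  n = c(sum(!two), sum(two), test_complete$n, test_noact$n),
  n_context_A = c(sum(ctx[!two] == "A"), sum(ctx[two] == "A"),
                  sum(vapply(test_complete$specs, function(s) s$context,
                             character(1)) == "A"),
                  sum(vapply(test_noact$specs, function(s) s$context,
                             character(1)) == "A")),
  mean_active_units = c(mean(rowSums(train$V[!two, ])),
                        mean(rowSums(train$V[two, ])),
                        mean(rowSums(test_complete$V)),
                        mean(rowSums(test_noact$V)))
)
print(summary)
write.csv(summary, "results/data_summary.csv", row.names = FALSE)
cat("Wrote results/data_summary.csv\n")
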