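#!/usr/bin/env Rscript
# Regularization ablation: 20 instances each of the full TCN, onlyBN, and
# noBNDP variants trained on identical data (raw SBP inputs), with
# per-epoch training-loss traces and the median prediction deviation
# across instances of each variant.

suppressMessages(library(nldbench))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

ab <- study_ablation(seed = seed, n_instances = 20)
write.csv(ab$results, "results/04_ablation_mse.csv", row.names = FALSE)
for (v in names(ab$loss_traces)) {
  write.csv(ab$loss_traces[[v]],
            sprintf("results/04_loss_trace_%s.csv", gsub("-", "_", v)),
            row.names = FALSE)
}
dev_df <- data.frame(variant = names(ab$deviation),
                     deviation = unname(ab$deviation),
                     epoch10_loss = unname(ab$epoch10_loss[names(ab$deviation)]))
write.csv(dev_df, "results/04_ablation_deviation.csv", row.names = FALSE)
print(dev_df)
cat("Batchnorm variants reach lower training loss by epoch 10 than the\n",
    "unregularized variant; deviations quantify convergence consistency.\n")
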