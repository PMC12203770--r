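#!/usr/bin/env Rscript
# The central comparison: ridge regression vs the TCN and LSTM on five
# independent synthetic sessions with saturating (rectified) tuning.
# Reports pooled holdout MSE, high/low speed-regime mean speeds, and KL
# divergence of each decoder's velocity distribution from hand control.

suppressMessages(library(nldbench))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

res <- study_decoder_comparison(seed = seed)
write.csv(res, "results/03_decoder_comparison.csv", row.names = FALSE)
wins <- summarize_decoder_wins(res)
print(round(res, 4))
print(wins)
cat(sprintf(
  "TCN/LSTM pooled MSE %.1f%%/%.1f%% below RR; KL to hand control %.1f%%/%.1f%% lower.\n",
  100 * (1 - mean(res$tcn_mse) / mean(res$rr_mse)),
  100 * (1 - mean(res$lstm_mse) / mean(res$rr_mse)),
  100 * (1 - mean(res$tcn_kl) / mean(res$rr_kl)),
  100 * (1 - mean(res$lstm_kl) / mean(res$rr_kl))))
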