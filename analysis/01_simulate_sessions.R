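#!/usr/bin/env Rscript
# Simulates one study session with known encoding ground truth, saves it in
# the plain-text session container, and summarizes the behavioral shape the
# generator targets: a velocity distribution strongly peaked at zero (long
# holds) with heavy reach tails.

suppressMessages(library(nldbench))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 2 && args[1] == "--seed") as.integer(args[2]) else 1L
dir.create("results", showWarnings = FALSE)

em <- generate_encoding_model(96, "saturating", seed = derive_seed(seed, "enc"))
session <- generate_session(task_config(n_trials = 600,
                                        seed = derive_seed(seed, "task")),
                            em, c(normal = 600),
                            seed = derive_seed(seed, "session"))
write_session(session, "results/session_normal_600")

v <- as.vector(session$kinematics$velocity)
sp <- abs(v)
summary_df <- data.frame(
  n_trials = nrow(session$trials),
  n_bins = nrow(session$sbp),
  n_channels = ncol(session$sbp),
  mean_trial_s = nrow(session$sbp) * 0.05 / nrow(session$trials),
  excess_kurtosis = mean((v - mean(v))^4) / stats::var(v)^2 - 3,
  frac_below_10pct_peak = mean(sp < 0.1 * max(sp)))
write.csv(summary_df, "results/01_session_summary.csv", row.names = FALSE)
print(summary_df)
cat("Velocities are zero-peaked and heavy-tailed; holding dominates the session,\n",
    "matching the hand-control behavior the decoders must reproduce.\n")
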