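# The package's offline experiment recipes at CPU study scale. Each study
# fixes its problem sizes (sessions, fold usage, network widths, iteration
# budgets) as package choices — documented in the methods vignette — and
# takes a single experiment seed from which every session, fold shuffle and
# decoder instance seed is derived.

#' Decoder-comparison study: RR vs TCN vs LSTM on saturating encodings
#'
#' Generates `n_seeds` independent 96-channel, 600-trial sessions with the
#' saturating (rectified-tuning) encoder, prepares the standard
#' middle-600/holdout-100/five-fold protocol, trains one ridge, one TCN and
#' one LSTM instance on fold 1's 400 training trials, and evaluates all on
#' the 100-trial holdout: pooled MSE, high/low speed-regime mean speeds, and
#' the KL divergence of each decoder's velocity distribution from true hand
#' control.
#'
#' @param seed experiment seed.
#' @param n_seeds independent sessions (default 5).
#' @param n_trials trials per session (default 600).
#' @param n_channels channels (default 96).
#' @param lstm_opts,tcn_opts decoder option overrides.
#' @return data.frame: one row per session seed with per-decoder metrics.
#' @export
study_decoder_comparison <- function(seed = 1L, n_seeds = 5, n_trials = 600,
                                     n_channels = 96,
                                     tcn_opts = list(),
                                     lstm_opts = list(hidden_size = 48,
                                                      iterations = 700,
                                                      n_train_sequences = 6000)) {
  rows <- NULL
  for (i in seq_len(n_seeds)) {
    em <- generate_encoding_model(n_channels, "saturating",
                                  seed = derive_seed(seed, "encoding", i))
    s <- generate_session(
      task_config(n_trials = n_trials, seed = derive_seed(seed, "task", i)),
      em, stats::setNames(n_trials, "normal"),
      seed = derive_seed(seed, "session", i))
    folds <- prepare_session_folds(s, n_keep = min(n_trials, 600),
                                   seed = derive_seed(seed, "folds", i))
    ds <- make_decoder_dataset(s)
    tr <- folds$split$folds[[1]]$train

    pv_rr <- predict_velocity(
      train_velocity_decoder("rr", s, tr, dataset = ds), s, folds$holdout,
      dataset = ds)
    pv_tc <- predict_velocity(
      train_velocity_decoder("tcn", s, tr, dataset = ds,
                             seed = derive_seed(seed, "tcn", i),
                             opts = tcn_opts), s, folds$holdout, dataset = ds)
    pv_ls <- predict_velocity(
      train_velocity_decoder("lstm", s, tr, dataset = ds,
                             seed = derive_seed(seed, "lstm", i),
                             opts = lstm_opts), s, folds$holdout, dataset = ds)

    masks <- speed_regime_masks(pv_rr$true)
    edges <- pmf_edges(pv_rr$true)
    p_true <- velocity_pmf(pv_rr$true, edges)
    stat <- function(pv, tag) {
      rs <- regime_stats(pv$pred, pv$true, masks)
      out <- c(mse(pv$pred, pv$true), rs$high$mean_speed, rs$low$mean_speed,
               kl_divergence(p_true, velocity_pmf(pv$pred, edges)))
      names(out) <- paste0(tag, c("_mse", "_high_speed", "_low_speed", "_kl"))
      out
    }
    rows <- rbind(rows, c(seed_index = i, stat(pv_rr, "rr"),
                          stat(pv_tc, "tcn"), stat(pv_ls, "lstm")))
  }
  as.data.frame(rows)
}

#' Summarize decoder-comparison wins per seed
#'
#' @param res a [study_decoder_comparison()] result.
#' @return named integer vector: for each decoder and metric, in how many
#'   sessions the nonlinear decoder landed on the hand-control side of RR.
#' @export
summarize_decoder_wins <- function(res) {
  c(tcn_mse = sum(res$tcn_mse < res$rr_mse),
    lstm_mse = sum(res$lstm_mse < res$rr_mse),
    tcn_high_speed = sum(res$tcn_high_speed > res$rr_high_speed),
    lstm_high_speed = sum(res$lstm_high_speed > res$rr_high_speed),
    tcn_low_speed = sum(res$tcn_low_speed < res$rr_low_speed),
    lstm_low_speed = sum(res$lstm_low_speed < res$rr_low_speed),
    tcn_kl = sum(res$tcn_kl < res$rr_kl),
    lstm_kl = sum(res$lstm_kl < res$rr_kl))
}

#' Regularization-ablation study: TCN vs onlyBN vs noBNDP
#'
#' One compact session (48 channels, 120 trials), one 64-trial training
#' fold, `n_instances` seeded instances per variant trained on identical
#' data with raw (unnormalized) SBP inputs: the TCN and onlyBN variants at
#' their 10-epoch budget, noBNDP at its 80-epoch budget. Reports holdout
#' MSE per instance, per-epoch training-loss traces, epoch-10 losses, and
#' the median prediction deviation across instances of each variant.
#'
#' @param seed experiment seed.
#' @param n_instances instances per variant (default 20).
#' @param variants variant ids.
#' @return list with `results`, `loss_traces`, `deviation`,
#'   `epoch10_loss` (named mean training loss at epoch 10).
#' @export
study_ablation <- function(seed = 1L, n_instances = 20,
                           variants = c("tcn", "tcn-onlybn", "tcn-nobndp")) {
  em <- generate_encoding_model(48, "saturating",
                                seed = derive_seed(seed, "abl-enc"))
  s <- generate_session(
    task_config(n_trials = 120, seed = derive_seed(seed, "abl-task")),
    em, c(normal = 120), seed = derive_seed(seed, "abl-session"))
  folds <- prepare_session_folds(s, n_keep = 120, n_holdout = 40,
                                 seed = derive_seed(seed, "abl-folds"))
  ab <- run_stability_ablation(
    s, variants = variants, n_instances = n_instances, fold_id = 1,
    seed = derive_seed(seed, "abl"), folds = folds,
    opts = list(n_filters = 4, hidden = c(48, 48), batch_size = 64,
                normalize_inputs = FALSE))
  ab$epoch10_loss <- vapply(ab$loss_traces,
                            function(tr) mean(tr[, 10]), numeric(1))
  ab
}

#' Context-generalization study with ridge decoders
#'
#' A four-context session (600 trials per context) with the default context
#' shifts, the per-context fold protocol, and ridge decoders trained on
#' every single-context fold plus the mixed and full sets, tested on all
#' four holdouts; plus a null-control session whose context shifts have
#' zero magnitude.
#'
#' @param seed experiment seed.
#' @param fold_ids folds for the shifted session (default 1:5).
#' @param null_fold_ids folds for the null control (default 1:2).
#' @param n_trials trials per context (default 600).
#' @return list with `shifted`, `null` (mean MSE by group), `gap_closure`
#'   (mixed and full), `paired` (off vs on paired test), `null_gap_rel`.
#' @export
study_context_generalization <- function(seed = 1L, fold_ids = 1:5,
                                         null_fold_ids = 1:2,
                                         n_trials = 600) {
  ctx <- stats::setNames(rep(n_trials, 4),
                         c("normal", "spring", "wrist", "spring-wrist"))
  em <- generate_encoding_model(96, "saturating",
                                seed = derive_seed(seed, "ctx-enc"))
  s <- generate_session(
    task_config(n_trials = n_trials, seed = derive_seed(seed, "ctx-task")),
    em, ctx, seed = derive_seed(seed, "ctx-session"))
  cg <- run_context_generalization(s, roster = "rr", fold_ids = fold_ids,
                                   seed = derive_seed(seed, "ctx-run"),
                                   n_keep = n_trials)
  by_group <- tapply(cg$results$mse, cg$results$group, mean)

  # paired off-vs-on per (fold, test context)
  r <- cg$results[cg$results$group %in% c("on", "off"), ]
  on <- r[r$group == "on", ]
  on_v <- on$mse[order(on$fold, on$test_context)]
  off_m <- stats::aggregate(mse ~ fold + test_context,
                            r[r$group == "off", ], mean)
  off_v <- off_m$mse[order(off_m$fold, off_m$test_context)]
  paired <- paired_ttest(off_v, on_v, tail = "greater")

  gap <- by_group[["off"]] - by_group[["on"]]
  gap_closure <- c(
    mixed = (by_group[["off"]] - by_group[["mixed"]]) / gap,
    full = (by_group[["off"]] - by_group[["full"]]) / gap)

  em0 <- generate_encoding_model(96, "saturating",
                                 seed = derive_seed(seed, "ctx-enc"),
                                 context_shifts = scaled_context_shifts(0))
  s0 <- generate_session(
    task_config(n_trials = n_trials, seed = derive_seed(seed, "ctx-task")),
    em0, ctx, seed = derive_seed(seed, "ctx-session"))
  cg0 <- run_context_generalization(s0, roster = "rr",
                                    fold_ids = null_fold_ids,
                                    seed = derive_seed(seed, "ctx-run"),
                                    n_keep = n_trials)
  by_group0 <- tapply(cg0$results$mse, cg0$results$group, mean)

  list(shifted = by_group, null = by_group0, gap_closure = gap_closure,
       paired = paired,
       null_gap_rel = (by_group0[["off"]] - by_group0[["on"]]) /
         by_group0[["on"]])
}

#' Type-I error calibration of the statistical tests
#'
#' Runs each test on pure-noise replicates and reports the fraction of
#' rejections at alpha 0.01.
#'
#' @param seed experiment seed.
#' @param n_rep replicates per test (default 10000).
#' @param alpha nominal level.
#' @return named numeric vector of empirical type-I error rates.
#' @export
study_calibration <- function(seed = 1L, n_rep = 10000, alpha = 0.01) {
  with_seed(seed, {
    hits <- c(paired_t = 0, two_sample_t = 0, diff_props = 0, nested_anova = 0)
    day <- rep(1:3, each = 12)
    run <- rep(rep(1:3, each = 4), 3)
    for (i in seq_len(n_rep)) {
      hits["paired_t"] <- hits["paired_t"] +
        (paired_ttest(stats::rnorm(10), stats::rnorm(10))$p < alpha)
      hits["two_sample_t"] <- hits["two_sample_t"] +
        (two_sample_ttest(stats::rnorm(12), stats::rnorm(12))$p < alpha)
      hits["diff_props"] <- hits["diff_props"] +
        (diff_of_proportions(stats::rbinom(1, 200, 0.4), 200,
                             stats::rbinom(1, 200, 0.4), 200)$p < alpha)
      tab <- nested_anova(stats::rnorm(36), day, run)
      hits["nested_anova"] <- hits["nested_anova"] +
        (tab$p[tab$effect == "day"] < alpha)
    }
    hits / n_rep
  })
}

#' Long-run dual-state threshold behavior on a stationary stream
#'
#' Fits a dual-state decoder on a small synthetic session and streams
#' stationary feature windows through it, reporting the long-run fraction of
#' fast classifications (target ratio 1:1).
#'
#' @param seed experiment seed.
#' @param n_steps stream length (default 10000).
#' @return list with `fast_fraction` (after burn-in) and the threshold trace.
#' @export
study_ds_threshold <- function(seed = 1L, n_steps = 10000) {
  em <- generate_encoding_model(24, "saturating",
                                seed = derive_seed(seed, "ds-enc"))
  s <- generate_session(
    task_config(n_trials = 80, seed = derive_seed(seed, "ds-task")),
    em, c(normal = 80), seed = derive_seed(seed, "ds-session"))
  ds <- make_decoder_dataset(s)
  m <- fit_dual_state(ds$windows, ds$velocity)
  idx <- with_seed(derive_seed(seed, "ds-stream"),
                   sample(nrow(ds$windows), n_steps, replace = TRUE))
  out <- predict_dual_state(m, ds$windows[idx, ])
  burn <- floor(n_steps / 5)
  list(fast_fraction = mean(out$fast[(burn + 1):n_steps]),
       threshold = out$threshold)
}
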