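#' Prepare the standard single-context fold structure for a session
#'
#' Failure removal, middle-`n_keep` trim, final-`n_holdout` holdout, and the
#' shuffled `n_folds`-fold split of the remaining training pool.
#'
#' @param session a `binned_session`.
#' @param context restrict to one context (NULL = all trials).
#' @param n_keep,n_holdout,n_folds protocol sizes (600/100/5 default).
#' @param seed shuffle seed.
#' @return list with `holdout`, `split` (a `fold_split`), `kept`.
#' @export
prepare_session_folds <- function(session, context = NULL, n_keep = 600,
                                  n_holdout = 100, n_folds = 5, seed = 1L) {
  trials <- session$trials
  if (!is.null(context)) trials <- trials[trials$context == context, ]
  th <- trim_and_holdout(trials, n_keep, n_holdout)
  split <- make_folds(trials$trial[th$train_pool], seed = seed,
                      n_folds = n_folds)
  list(holdout = trials$trial[th$holdout], split = split,
       kept = trials$trial[th$kept])
}

#' Offline decoder comparison on one session
#'
#' For each fold, decoder family, and instance: train on the fold's training
#' trials, predict the holdout, and compute pooled MSE, speed-regime
#' statistics, and the KL divergence of the predicted-velocity distribution
#' from the true (hand-control) distribution. Instance seeds are derived per
#' (fold, decoder, instance) so partial reruns reproduce exactly.
#'
#' @param session a `binned_session`.
#' @param roster decoder kinds to run.
#' @param fold_ids folds to use.
#' @param n_instances instances per decoder per fold.
#' @param seed experiment seed.
#' @param folds optional [prepare_session_folds()] result.
#' @param decoder_opts named list: per-kind `opts` for
#'   [train_velocity_decoder()].
#' @param keep_predictions retain per-instance prediction matrices.
#' @return a `metrics_report`: list with `results` (data.frame), `edges`,
#'   `predictions` (optional), `holdout`.
#' @export
run_decoder_comparison <- function(session, roster = c("rr", "ds", "tcn",
                                                       "lstm"),
                                   fold_ids = 1, n_instances = 1, seed = 1L,
                                   folds = NULL, decoder_opts = list(),
                                   keep_predictions = FALSE) {
  stopifnot(length(roster) > 0, n_instances >= 1)
  if (is.null(folds)) {
    folds <- prepare_session_folds(session, seed = derive_seed(seed, "folds"))
  }
  dataset <- make_decoder_dataset(session)
  hold_rows <- dataset_rows(dataset, folds$holdout)
  true_hold <- dataset$velocity[hold_rows, , drop = FALSE]
  edges <- pmf_edges(true_hold)
  p_true <- velocity_pmf(true_hold, edges)
  masks <- speed_regime_masks(true_hold)

  rows <- list()
  preds <- list()
  for (f in fold_ids) {
    train_ids <- folds$split$folds[[f]]$train
    for (kind in roster) {
      for (inst in seq_len(n_instances)) {
        iseed <- derive_seed(seed, "fold", f, kind, "inst", inst)
        dec <- train_velocity_decoder(kind, session, train_ids,
                                      dataset = dataset, seed = iseed,
                                      opts = decoder_opts[[kind]] %||% list())
        pv <- predict_velocity(dec, session, folds$holdout, dataset = dataset)
        rs <- regime_stats(pv$pred, pv$true, masks)
        kl <- kl_divergence(velocity_pmf(pv$pred, edges), p_true)
        kl_from_true <- kl_divergence(p_true, velocity_pmf(pv$pred, edges))
        rows[[length(rows) + 1]] <- data.frame(
          decoder = kind, fold = f, instance = inst, seed = iseed,
          mse = mse(pv$pred, pv$true),
          high_mean_speed = rs$high$mean_speed, high_mse = rs$high$mse,
          low_mean_speed = rs$low$mean_speed, low_mse = rs$low$mse,
          kl_true_vs_pred = kl_from_true, kl_pred_vs_true = kl,
          stringsAsFactors = FALSE)
        if (keep_predictions) {
          preds[[paste(kind, f, inst, sep = "/")]] <- pv$pred
        }
      }
    }
  }
  structure(list(results = do.call(rbind, rows), edges = edges,
                 holdout = folds$holdout, true_regime = list(
                   high_mean_speed = regime_stats(true_hold, true_hold,
                                                  masks)$high$mean_speed,
                   low_mean_speed = regime_stats(true_hold, true_hold,
                                                 masks)$low$mean_speed),
                 predictions = if (keep_predictions) preds else NULL,
                 seed = as.integer(seed)),
            class = "metrics_report")
}

#' TCN regularization-ablation study on one session
#'
#' Trains `n_instances` of each requested TCN variant on one fold's training
#' set with identical data (instance seeds differ), records per-epoch
#' training-loss traces, holdout MSE per instance, and the median prediction
#' deviation across instances of each variant.
#'
#' @param session a `binned_session`.
#' @param variants TCN variant kinds.
#' @param n_instances instances per variant.
#' @param fold_id training fold.
#' @param seed experiment seed.
#' @param folds optional fold structure.
#' @param opts shared decoder opts (e.g. reduced widths, epochs).
#' @return list with `results` (per-instance data.frame), `loss_traces`
#'   (variant -> instances x epochs matrix), `deviation` (named vector).
#' @export
run_stability_ablation <- function(session,
                                   variants = c("tcn", "tcn-onlybn",
                                                "tcn-onlydp", "tcn-nobndp"),
                                   n_instances = 20, fold_id = 1, seed = 1L,
                                   folds = NULL, opts = list()) {
  if (is.null(folds)) {
    folds <- prepare_session_folds(session, seed = derive_seed(seed, "folds"))
  }
  dataset <- make_decoder_dataset(session)
  train_ids <- folds$split$folds[[fold_id]]$train
  rows <- list()
  loss_traces <- list()
  deviation <- numeric(0)
  for (kind in variants) {
    preds <- vector("list", n_instances)
    traces <- NULL
    for (inst in seq_len(n_instances)) {
      iseed <- derive_seed(seed, "ablation", kind, inst)
      dec <- train_velocity_decoder(kind, session, train_ids,
                                    dataset = dataset, seed = iseed,
                                    opts = opts)
      pv <- predict_velocity(dec, session, folds$holdout, dataset = dataset)
      preds[[inst]] <- pv$pred
      traces <- rbind(traces, dec$model$loss_trace)
      rows[[length(rows) + 1]] <- data.frame(
        decoder = kind, instance = inst, seed = iseed,
        mse = mse(pv$pred, pv$true), stringsAsFactors = FALSE)
    }
    loss_traces[[kind]] <- traces
    deviation[kind] <- median_prediction_deviation(preds)
  }
  list(results = do.call(rbind, rows), loss_traces = loss_traces,
       deviation = deviation, holdout = folds$holdout,
       seed = as.integer(seed))
}

#' Context-generalization study on a multi-context session
#'
#' Builds the per-context fold structure, assembles the mixed and full
#' multi-context training sets, trains each rostered decoder on every
#' single-context fold plus mixed and full, and tests every decoder on every
#' context's holdout. Results are grouped as on-context (train = test
#' context), off-context (single-context train != test), mixed-context and
#' full-context.
#'
#' @param session a `binned_session` with >= 2 contexts.
#' @param roster decoder kinds.
#' @param fold_ids folds to run.
#' @param seed experiment seed.
#' @param n_keep,n_holdout per-context protocol sizes.
#' @param decoder_opts per-kind option lists.
#' @return list with `results` (data.frame with `group` column) and the fold
#'   structures.
#' @export
run_context_generalization <- function(session, roster = "rr", fold_ids = 1:5,
                                       seed = 1L, n_keep = 600,
                                       n_holdout = 100,
                                       decoder_opts = list()) {
  contexts <- unique(session$trials$context)
  if (length(contexts) < 2) {
    stop("run_context_generalization: need a multi-context session")
  }
  dataset <- make_decoder_dataset(session)
  folds_by_context <- lapply(stats::setNames(contexts, contexts), function(ctx)
    prepare_session_folds(session, context = ctx, n_keep = n_keep,
                          n_holdout = n_holdout,
                          seed = derive_seed(seed, "folds", ctx)))
  splits_only <- lapply(folds_by_context, `[[`, "split")

  rows <- list()
  for (f in fold_ids) {
    sources <- c(as.list(stats::setNames(contexts, contexts)),
                 list(mixed = NULL, full = NULL))
    for (src in names(sources)) {
      train_ids <- if (src %in% c("mixed", "full")) {
        make_multi_context(splits_only, f, kind = src)$indices
      } else {
        folds_by_context[[src]]$split$folds[[f]]$train
      }
      for (kind in roster) {
        iseed <- derive_seed(seed, "ctx", f, src, kind)
        dec <- train_velocity_decoder(kind, session, train_ids,
                                      dataset = dataset, seed = iseed,
                                      opts = decoder_opts[[kind]] %||% list())
        for (tctx in contexts) {
          hold <- folds_by_context[[tctx]]$holdout
          pv <- predict_velocity(dec, session, hold, dataset = dataset)
          group <- if (src == "mixed") "mixed"
                   else if (src == "full") "full"
                   else if (src == tctx) "on" else "off"
          rows[[length(rows) + 1]] <- data.frame(
            decoder = kind, fold = f, source = src, test_context = tctx,
            group = group, mse = mse(pv$pred, pv$true),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  list(results = do.call(rbind, rows), folds_by_context = folds_by_context,
       seed = as.integer(seed))
}
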