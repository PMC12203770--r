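#' Build the window-level dataset for a session
#'
#' Windows are built once over the whole continuous session (the first
#' `n_history` bins yield none) and each window is attributed to the trial
#' containing its target bin, so trial-level fold selection just picks rows
#' and bins within a trial stay contiguous.
#'
#' @param session a `binned_session`.
#' @param n_history lookback bins (default 2).
#' @return list with `windows`, `velocity`, `bins` (1-based target bins),
#'   `trial_id` per window, `n_history`.
#' @export
make_decoder_dataset <- function(session, n_history = 2) {
  hw <- build_history_windows(session$sbp, n_history)
  trial_of_bin <- rep(NA_integer_, nrow(session$sbp))
  for (k in seq_len(nrow(session$trials))) {
    trial_of_bin[(session$trials$start_bin[k] + 1):session$trials$end_bin[k]] <-
      session$trials$trial[k]
  }
  list(windows = hw$windows,
       velocity = session$kinematics$velocity[hw$target_rows, , drop = FALSE],
       bins = hw$target_rows,
       trial_id = trial_of_bin[hw$target_rows],
       n_history = n_history)
}

dataset_rows <- function(dataset, trial_ids) {
  which(dataset$trial_id %in% trial_ids)
}

#' Train a velocity decoder of any supported family
#'
#' Uniform training contract over the benchmarked decoder families:
#' \describe{
#'   \item{rr}{ridge regression on 3-bin windows (lambda 0.001).}
#'   \item{ds}{dual-state movement/posture decoder.}
#'   \item{tcn, tcn-onlybn, tcn-onlydp, tcn-nobndp}{the temporally-convolved
#'     network and its regularization ablations.}
#'   \item{lstm}{the recurrent decoder on 20-bin sequences.}
#' }
#'
#' @param kind decoder family id.
#' @param session a `binned_session`.
#' @param trial_ids training trial ids.
#' @param dataset a [make_decoder_dataset()] result for `session` (built on
#'   demand if NULL).
#' @param seed instance seed (network initialization and training noise).
#' @param opts named list of family-specific overrides: for networks
#'   `tcn_config` / `lstm_config` fields or `train_config` fields.
#' @return a `velocity_decoder` wrapper with the fitted model.
#' @export
train_velocity_decoder <- function(kind, session, trial_ids, dataset = NULL,
                                   seed = 1L, opts = list()) {
  if (is.null(dataset)) dataset <- make_decoder_dataset(session)
  rows <- dataset_rows(dataset, trial_ids)
  X <- dataset$windows[rows, , drop = FALSE]
  Y <- dataset$velocity[rows, , drop = FALSE]
  model <- switch(kind,
    rr = fit_ridge(X, Y, lambda = opts$lambda %||% 0.001),
    ds = fit_dual_state(X, Y, lambda = opts$lambda %||% 0.001),
    lstm = {
      cfg <- utils::modifyList(
        lstm_config(n_channels = ncol(session$sbp), seed = seed),
        opts)
      cfg$seed <- as.integer(seed)
      train_lstm(session$sbp, session$kinematics$velocity,
                 train_bins = dataset$bins[rows], trials = session$trials,
                 cfg = cfg)
    },
    {
      variant <- switch(kind, tcn = "tcn", `tcn-onlybn` = "onlybn",
                        `tcn-onlydp` = "onlydp", `tcn-nobndp` = "nobndp",
                        stop("unknown decoder kind: ", kind))
      arch_opts <- opts[names(opts) %in% c("n_filters", "hidden",
                                           "dropout_rate")]
      arch <- do.call(tcn_variant_config,
                      c(list(variant = variant,
                             n_channels = ncol(session$sbp),
                             n_history = dataset$n_history), arch_opts))
      default_epochs <- if (variant %in% c("nobndp", "onlydp")) 80 else 10
      tr_opts <- opts[names(opts) %in% c("lr", "weight_decay", "epochs",
                                         "iterations", "batch_size",
                                         "redistribute")]
      tcfg <- do.call(train_config,
                      c(list(seed = derive_seed(seed, "train"),
                             epochs = if ("iterations" %in% names(tr_opts))
                               NULL else tr_opts$epochs %||% default_epochs),
                        tr_opts[names(tr_opts) != "epochs"]))
      net <- build_tcn(arch, seed = derive_seed(seed, "init"))
      train_network(net, X, Y, tcfg)
    })
  structure(list(kind = kind, model = model, seed = as.integer(seed),
                 n_history = dataset$n_history),
            class = "velocity_decoder")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict velocities for a set of trials with any trained decoder
#'
#' @param decoder a [train_velocity_decoder()] result.
#' @param session the session to decode.
#' @param trial_ids trials to predict.
#' @param dataset optional cached [make_decoder_dataset()].
#' @return list with `pred` (N x 2), `true` (N x 2), `bins`.
#' @export
predict_velocity <- function(decoder, session, trial_ids, dataset = NULL) {
  if (is.null(dataset)) dataset <- make_decoder_dataset(session)
  rows <- dataset_rows(dataset, trial_ids)
  X <- dataset$windows[rows, , drop = FALSE]
  pred <- switch(decoder$kind,
    rr = predict_ridge(decoder$model, X),
    ds = predict_dual_state(decoder$model, X)$velocity,
    lstm = predict_lstm(decoder$model, session$sbp, dataset$bins[rows],
                        session$trials),
    predict_network(decoder$model, X))
  list(pred = pred, true = dataset$velocity[rows, , drop = FALSE],
       bins = dataset$bins[rows])
}
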