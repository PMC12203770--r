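#' TCN architecture configuration
#'
#' The temporally-convolved feedforward network applies multiple time-wise
#' convolutions across the history bins of each channel independently (the
#' filter bank is shared across channels but never mixes them), flattens,
#' and passes through fully connected layers with optional batch
#' normalization and neuron dropout. Disabling both flags yields the
#' "noBNDP" ablation; batchnorm-only is "onlyBN", dropout-only is "onlyDP".
#'
#' @param n_channels input channels C.
#' @param n_history lookback bins (default 2, i.e. 3-bin / 150 ms windows).
#' @param n_filters temporal convolution filters per channel (default 8).
#' @param hidden integer vector of hidden-layer widths (default c(96, 96)).
#' @param use_batchnorm,use_dropout regularization flags.
#' @param dropout_rate neuron dropout probability (default 0.25).
#' @return a `tcn_config` list.
#' @export
tcn_config <- function(n_channels = 96, n_history = 2, n_filters = 8,
                       hidden = c(96, 96), use_batchnorm = TRUE,
                       use_dropout = TRUE, dropout_rate = 0.25) {
  structure(list(n_channels = n_channels, n_history = n_history,
                 n_filters = n_filters, hidden = hidden,
                 use_batchnorm = use_batchnorm, use_dropout = use_dropout,
                 dropout_rate = dropout_rate, n_out = 2L),
            class = "tcn_config")
}

#' Named TCN ablation variants
#'
#' @param variant one of "tcn", "onlybn", "onlydp", "nobndp".
#' @param ... passed to [tcn_config()].
#' @return a `tcn_config`.
#' @export
tcn_variant_config <- function(variant = c("tcn", "onlybn", "onlydp", "nobndp"),
                               ...) {
  variant <- match.arg(variant)
  tcn_config(...,
             use_batchnorm = variant %in% c("tcn", "onlybn"),
             use_dropout = variant %in% c("tcn", "onlydp"))
}

#' Build an untrained TCN
#'
#' @param config a [tcn_config()].
#' @param seed parameter-initialization seed.
#' @return an untrained network object (list of layers).
#' @export
build_tcn <- function(config, seed = 1L) {
  C <- config$n_channels
  H <- config$n_history + 1
  F <- config$n_filters
  with_seed(seed, {
    layers <- list(nn_layer_conv_time(C, H, F))
    width <- C * F
    if (config$use_batchnorm) layers <- c(layers, list(nn_layer_batchnorm(width)))
    layers <- c(layers, list(nn_layer_relu()))
    if (config$use_dropout) {
      layers <- c(layers, list(nn_layer_dropout(config$dropout_rate)))
    }
    for (h in config$hidden) {
      layers <- c(layers, list(nn_layer_dense(width, h)))
      if (config$use_batchnorm) layers <- c(layers, list(nn_layer_batchnorm(h)))
      layers <- c(layers, list(nn_layer_relu()))
      if (config$use_dropout) {
        layers <- c(layers, list(nn_layer_dropout(config$dropout_rate)))
      }
      width <- h
    }
    layers <- c(layers, list(nn_layer_dense(width, config$n_out)))
    structure(list(layers = layers, config = config, seed = as.integer(seed)),
              class = "tcn_net")
  })
}

#' Training configuration for feedforward decoders
#'
#' Adam with the study's offline defaults: learning rate 1e-4, weight decay
#' 1e-2, MSE loss, 10 epochs, no velocity redistribution. Exactly one of
#' `epochs`/`iterations` may be set; ablated (noBNDP/onlyDP) runs use 80
#' epochs and normalized-data runs 15.
#'
#' @param lr learning rate.
#' @param weight_decay L2 weight decay (added to gradients, PyTorch Adam style).
#' @param epochs epoch budget (NULL if `iterations` given).
#' @param iterations optimizer-step budget (NULL if `epochs` given).
#' @param batch_size minibatch size (default 64).
#' @param seed training seed (shuffling, dropout).
#' @param redistribute "none" or "triangular" velocity redistribution.
#' @param normalize_inputs standardize feature columns with training stats.
#' @param normalize_targets z-score velocity targets per DOF; predictions are
#'   mapped back through a fitted [fit_output_rescaler()].
#' @return a `train_config` list.
#' @export
train_config <- function(lr = 1e-4, weight_decay = 1e-2, epochs = 10,
                         iterations = NULL, batch_size = 64, seed = 1L,
                         redistribute = c("none", "triangular"),
                         normalize_inputs = TRUE, normalize_targets = TRUE) {
  redistribute <- match.arg(redistribute)
  if (is.null(epochs) == is.null(iterations)) {
    stop("train_config: exactly one of epochs or iterations must be set")
  }
  structure(list(lr = lr, weight_decay = weight_decay, epochs = epochs,
                 iterations = iterations, batch_size = batch_size,
                 seed = as.integer(seed), redistribute = redistribute,
                 normalize_inputs = normalize_inputs,
                 normalize_targets = normalize_targets),
            class = "train_config")
}

#' Train a network decoder to predict velocities
#'
#' Minimizes MSE between predicted and true (normalized) velocities with
#' Adam, shuffling each epoch with the seeded generator. After training, a
#' per-DOF scalar output rescaler is fit on the training data to map
#' normalized predictions back to flex/s. The per-epoch mean training loss
#' is recorded.
#'
#' @param net a [build_tcn()] network.
#' @param X N x (C*H) training windows.
#' @param Y N x 2 training velocities (flex/s).
#' @param cfg a [train_config()].
#' @return a `trained_decoder` with elements `net`, `norm` (input/target
#'   constants), `rescaler`, `loss_trace` (per epoch), `iterations`.
#' @export
train_network <- function(net, X, Y, cfg = train_config()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  stopifnot(nrow(X) == nrow(Y))

  norm <- make_normalizer(X, Y, cfg)
  Xs <- apply_input_norm(norm, X)
  Yt <- apply_target_norm(norm, Y)

  if (cfg$redistribute == "triangular") {
    rows <- redistribute_velocities(seq_len(nrow(Xs)), Y, mode = "triangular",
                                    seed = derive_seed(cfg$seed, "redist"))
    Xs <- Xs[rows, , drop = FALSE]
    Yt <- Yt[rows, , drop = FALSE]
  }

  fit <- with_seed(cfg$seed, nn_train_loop(net, Xs, Yt, cfg))

  preds_norm <- nn_predict(fit$net, Xs)
  rescaler <- if (cfg$normalize_targets) {
    fit_output_rescaler(preds_norm, if (cfg$redistribute == "triangular")
      Y[rows, , drop = FALSE] else Y)
  } else {
    NULL
  }
  structure(list(net = fit$net, norm = norm, rescaler = rescaler,
                 loss_trace = fit$loss_trace, iter_loss = fit$iter_loss,
                 iterations = fit$iterations, cfg = cfg),
            class = "trained_decoder")
}

nn_train_loop <- function(net, Xs, Yt, cfg, adam_state = NULL, t0 = 0L) {
  n <- nrow(Xs)
  bs <- min(cfg$batch_size, n)
  state <- if (is.null(adam_state)) nn_adam_init(net) else adam_state
  iters_per_epoch <- ceiling(n / bs)
  total_iters <- if (!is.null(cfg$iterations)) cfg$iterations
                 else cfg$epochs * iters_per_epoch
  loss_trace <- numeric(0)
  iter_loss <- numeric(total_iters)
  t <- t0
  it <- 0L
  epoch_losses <- numeric(0)
  while (it < total_iters) {
    ord <- sample.int(n)
    for (b0 in seq(1, n, by = bs)) {
      if (it >= total_iters) break
      idx <- ord[b0:min(b0 + bs - 1, n)]
      xb <- Xs[idx, , drop = FALSE]
      yb <- Yt[idx, , drop = FALSE]
      fw <- nn_forward(net, xb, training = TRUE)
      err <- fw$out - yb
      loss <- mean(err^2)
      if (!is.finite(loss)) {
        stop(sprintf("train_network: non-finite loss at iteration %d", it + 1))
      }
      dout <- 2 * err / length(err)
      grads <- vector("list", length(net$layers))
      dx <- dout
      for (i in rev(seq_along(net$layers))) {
        bw <- nn_layer_backward(net$layers[[i]], fw$caches[[i]], dx)
        dx <- bw$dx
        grads[i] <- list(bw$grads)  # keep NULL placeholders for param-free layers
      }
      net <- nn_update_bn_running(net, fw$caches)
      t <- t + 1L
      st <- nn_adam_step(net, grads, state, cfg$lr, cfg$weight_decay, t)
      net <- st$net
      state <- st$state
      it <- it + 1L
      iter_loss[it] <- loss
      epoch_losses <- c(epoch_losses, loss)
    }
    loss_trace <- c(loss_trace, mean(epoch_losses))
    epoch_losses <- numeric(0)
  }
  list(net = net, loss_trace = loss_trace, iter_loss = iter_loss,
       iterations = it, adam_state = state, adam_t = t)
}

make_normalizer <- function(X, Y, cfg) {
  if (cfg$normalize_inputs) {
    x_mean <- colMeans(X)
    x_sd <- apply(X, 2, stats::sd)
    x_sd[x_sd == 0 | !is.finite(x_sd)] <- 1
  } else {
    x_mean <- rep(0, ncol(X)); x_sd <- rep(1, ncol(X))
  }
  if (cfg$normalize_targets) {
    y_mean <- colMeans(Y)
    y_sd <- apply(Y, 2, stats::sd)
    y_sd[y_sd == 0 | !is.finite(y_sd)] <- 1
  } else {
    y_mean <- rep(0, ncol(Y)); y_sd <- rep(1, ncol(Y))
  }
  list(x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd)
}

apply_input_norm <- function(norm, X) {
  sweep(sweep(as.matrix(X), 2, norm$x_mean), 2, norm$x_sd, `/`)
}

apply_target_norm <- function(norm, Y) {
  sweep(sweep(as.matrix(Y), 2, norm$y_mean), 2, norm$y_sd, `/`)
}

#' Predict final velocities with a trained network decoder
#'
#' @param decoder a [train_network()] result.
#' @param X feature windows.
#' @return N x 2 velocities in flex/s (rescaled through the output rescaler
#'   when target normalization was used).
#' @export
predict_network <- function(decoder, X) {
  Xs <- apply_input_norm(decoder$norm, X)
  out <- nn_predict(decoder$net, Xs)
  if (!is.null(decoder$rescaler)) {
    out <- apply_output_rescaler(decoder$rescaler, out)
  }
  out
}

#' Fit the per-DOF output rescaler
#'
#' Two independent single-weight, single-bias linear regressions mapping the
#' network's normalized IDX/MRS predictions to final flex/s velocities.
#'
#' @param normalized_preds N x 2 normalized predictions.
#' @param true_velocities N x 2 velocities in flex/s.
#' @return an `output_rescaler` with `w` and `b`, length 2 each.
#' @export
fit_output_rescaler <- function(normalized_preds, true_velocities) {
  P <- as.matrix(normalized_preds); Yv <- as.matrix(true_velocities)
  stopifnot(nrow(P) >= 2)
  w <- numeric(ncol(P)); b <- numeric(ncol(P))
  for (d in seq_len(ncol(P))) {
    v <- stats::var(P[, d])
    if (v == 0) stop("fit_output_rescaler: zero-variance predictions in DOF ", d)
    w[d] <- stats::cov(P[, d], Yv[, d]) / v
    b[d] <- mean(Yv[, d]) - w[d] * mean(P[, d])
  }
  structure(list(w = w, b = b), class = "output_rescaler")
}

apply_output_rescaler <- function(rescaler, preds) {
  sweep(sweep(as.matrix(preds), 2, rescaler$w, `*`), 2, rescaler$b, `+`)
}

#' ReFIT velocity relabeling (intention estimation)
#'
#' Per DOF and bin: if the position is outside the target and the recorded
#' velocity points away from the target center, the velocity's sign is
#' flipped (magnitude preserved); inside the target the velocity is set to
#' zero; velocities already pointing toward the target are unchanged.
#'
#' @param velocities N x 2 recorded decode velocities.
#' @param positions N x 2 positions (flex).
#' @param target_centers N x 2 per-bin target centers.
#' @param target_width scalar or N-vector target width.
#' @return N x 2 corrected velocities.
#' @export
refit_relabel <- function(velocities, positions, target_centers,
                          target_width = 0.15) {
  V <- as.matrix(velocities); P <- as.matrix(positions)
  Tc <- as.matrix(target_centers)
  half <- target_width / 2
  out <- V
  for (d in seq_len(ncol(V))) {
    inside <- abs(P[, d] - Tc[, d]) <= half
    toward <- sign(Tc[, d] - P[, d])
    away <- !inside & sign(V[, d]) != 0 & sign(V[, d]) != toward
    out[inside, d] <- 0
    out[away, d] <- -V[away, d]
  }
  out
}

#' Fine-tune a trained network on relabeled data
#'
#' Continues optimization for a fixed number of iterations (default 500) at
#' learning rate 2e-4 with all other hyperparameters inherited from the base
#' decoder's training configuration. Input/target normalization constants and
#' the rescaler are refit on the relabeled data.
#'
#' @param decoder a [train_network()] result.
#' @param X relabeled training windows.
#' @param Y relabeled velocities.
#' @param iterations optimizer steps (default 500).
#' @param lr fine-tune learning rate (default 2e-4).
#' @param seed fine-tune seed.
#' @return a `trained_decoder`.
#' @export
refit_finetune <- function(decoder, X, Y, iterations = 500, lr = 2e-4,
                           seed = decoder$cfg$seed) {
  if (iterations == 0) return(decoder)
  cfg <- decoder$cfg
  cfg$lr <- lr
  cfg$epochs <- NULL
  cfg$iterations <- iterations
  cfg$seed <- as.integer(seed)
  # inherit the base decoder's normalization so the network sees inputs on
  # the scale it was trained on; only the rescaler is refit
  norm <- decoder$norm
  Xs <- apply_input_norm(norm, as.matrix(X))
  Yt <- apply_target_norm(norm, as.matrix(Y))
  fit <- with_seed(cfg$seed, nn_train_loop(decoder$net, Xs, Yt, cfg))
  preds_norm <- nn_predict(fit$net, Xs)
  rescaler <- if (cfg$normalize_targets) {
    fit_output_rescaler(preds_norm, as.matrix(Y))
  } else {
    NULL
  }
  structure(list(net = fit$net, norm = norm, rescaler = rescaler,
                 loss_trace = fit$loss_trace, iter_loss = fit$iter_loss,
                 iterations = fit$iterations, cfg = cfg),
            class = "trained_decoder")
}

#' Resample a training set toward a triangular speed density
#'
#' Importance-resamples training rows (with replacement, size preserved) so
#' the sampled pooled-speed density approximates a triangular density on
#' \[0, max speed] peaking at half the maximum. Counteracts the extreme
#' dominance of near-zero speeds in hold-heavy training data.
#'
#' @param rows row indices to resample from.
#' @param velocities N x 2 velocities aligned with `rows`' source.
#' @param mode "none" (identity) or "triangular".
#' @param seed resampling seed.
#' @param n_bins histogram bins for the empirical speed density.
#' @return resampled row indices, same length as `rows`.
#' @export
redistribute_velocities <- function(rows, velocities, mode = c("triangular",
                                                               "none"),
                                    seed = 1L, n_bins = 50) {
  mode <- match.arg(mode)
  if (mode == "none") return(rows)
  sp <- sqrt(rowSums(as.matrix(velocities)[rows, , drop = FALSE]^2))
  smax <- max(sp)
  if (smax == 0) return(rows)
  peak <- 0.5 * smax
  tri <- function(s) {
    ifelse(s <= peak, s / peak, (smax - s) / (smax - peak)) * 2 / smax
  }
  edges <- seq(0, smax, length.out = n_bins + 1)
  bin <- pmin(findInterval(sp, edges, rightmost.closed = TRUE), n_bins)
  emp <- tabulate(bin, n_bins) / length(sp) / diff(edges)[1]
  w <- tri(sp) / pmax(emp[bin], 1e-12)
  with_seed(seed, sample(rows, length(rows), replace = TRUE,
                         prob = w / sum(w)))
}
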