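#' LSTM decoder configuration
#'
#' Single-layer LSTM over 20-bin input sequences with zero-initialized
#' hidden state; the loss is computed on the final output of each sequence.
#' Training follows the recurrent-decoder recipe: Adam at learning rate
#' 2e-4, weight decay 0.003, a plateau learning-rate scheduler (patience 800
#' iterations, at most 2 steps, factor 0.5), and two kinds of noise injected
#' into the normalized inputs — a per-batch, per-channel bias (SD 0.1) and
#' per-point white noise (SD 0.2).
#'
#' @param n_channels input channels C.
#' @param hidden_size LSTM hidden units (default 300).
#' @param seq_len sequence length in bins (default 20).
#' @param lr,weight_decay Adam settings.
#' @param iterations optimizer-step budget.
#' @param batch_size sequences per batch.
#' @param noise_bias_sd,noise_white_sd injected noise SDs.
#' @param plateau_patience,plateau_steps,plateau_factor scheduler settings.
#' @param n_train_sequences training sequences sampled per run (NULL = one
#'   per eligible bin).
#' @param seed training seed.
#' @return an `lstm_config` list.
#' @export
lstm_config <- function(n_channels = 96, hidden_size = 300, seq_len = 20,
                        lr = 2e-4, weight_decay = 0.003, iterations = 1000,
                        batch_size = 256, noise_bias_sd = 0.1,
                        noise_white_sd = 0.2, plateau_patience = 800,
                        plateau_steps = 2, plateau_factor = 0.5,
                        n_train_sequences = NULL, seed = 1L) {
  structure(list(n_channels = n_channels, hidden_size = hidden_size,
                 seq_len = seq_len, lr = lr, weight_decay = weight_decay,
                 iterations = iterations, batch_size = batch_size,
                 noise_bias_sd = noise_bias_sd, noise_white_sd = noise_white_sd,
                 plateau_patience = plateau_patience,
                 plateau_steps = plateau_steps,
                 plateau_factor = plateau_factor,
                 n_train_sequences = n_train_sequences,
                 seed = as.integer(seed)),
            class = "lstm_config")
}

# gate order within the 4H stacked dimension: input, forget, cell, output
lstm_init_params <- function(C, Hd) {
  lim <- 1 / sqrt(Hd)
  list(Wx = matrix(stats::runif(C * 4 * Hd, -lim, lim), C, 4 * Hd),
       Wh = matrix(stats::runif(Hd * 4 * Hd, -lim, lim), Hd, 4 * Hd),
       b = stats::runif(4 * Hd, -lim, lim),
       Wy = matrix(stats::runif(Hd * 2, -lim, lim), Hd, 2),
       by = stats::runif(2, -lim, lim))
}

#' Number of parameters of the single-layer LSTM core
#'
#' The gate arithmetic 4 * ((C + H) * H + H), excluding the readout layer;
#' matches the standard packed weight layout with a single bias vector.
#'
#' @param n_channels input size C.
#' @param hidden_size hidden size H.
#' @return integer parameter count.
#' @export
lstm_core_param_count <- function(n_channels, hidden_size) {
  4 * ((n_channels + hidden_size) * hidden_size + hidden_size)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# forward over a batch of sequences; Xseq: n x T x C array
lstm_forward <- function(par, Xseq, keep_cache = FALSE) {
  n <- dim(Xseq)[1]; Tt <- dim(Xseq)[2]
  Hd <- ncol(par$Wh)  / 4
  h <- matrix(0, n, Hd)
  c_ <- matrix(0, n, Hd)
  cache <- if (keep_cache) vector("list", Tt) else NULL
  ii <- 1:Hd; ff <- Hd + ii; gg <- 2 * Hd + ii; oo <- 3 * Hd + ii
  for (t in seq_len(Tt)) {
    xt <- Xseq[, t, , drop = FALSE]
    dim(xt) <- c(n, dim(Xseq)[3])
    z <- xt %*% par$Wx + h %*% par$Wh
    z <- sweep(z, 2, par$b, `+`)
    i <- sigmoid(z[, ii, drop = FALSE])
    f <- sigmoid(z[, ff, drop = FALSE])
    g <- tanh(z[, gg, drop = FALSE])
    o <- sigmoid(z[, oo, drop = FALSE])
    c_prev <- c_
    c_ <- f * c_prev + i * g
    tc <- tanh(c_)
    h <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(xt = xt, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc, h_prev = if (t == 1)
                           matrix(0, n, Hd) else cache[[t - 1]]$h, h = h)
    }
  }
  y <- sweep(h %*% par$Wy, 2, par$by, `+`)
  list(y = y, h = h, cache = cache)
}

# backward for final-output loss; dy: n x 2
lstm_backward <- function(par, fw, dy) {
  cache <- fw$cache
  Tt <- length(cache)
  n <- nrow(dy)
  Hd <- ncol(par$Wh) / 4
  ii <- 1:Hd; ff <- Hd + ii; gg <- 2 * Hd + ii; oo <- 3 * Hd + ii
  gWx <- par$Wx * 0; gWh <- par$Wh * 0; gb <- par$b * 0
  gWy <- crossprod(fw$h, dy)
  gby <- colSums(dy)
  dh <- tcrossprod(dy, par$Wy)
  dc <- matrix(0, n, Hd)
  for (t in Tt:1) {
    cc <- cache[[t]]
    do <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$c_prev
    dz <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do * cc$o * (1 - cc$o))
    gWx <- gWx + crossprod(cc$xt, dz)
    gWh <- gWh + crossprod(cc$h_prev, dz)
    gb <- gb + colSums(dz)
    dh <- tcrossprod(dz, par$Wh)
    dc <- dc * cc$f
  }
  list(Wx = gWx, Wh = gWh, b = gb, Wy = gWy, by = gby)
}

#' Build within-trial input sequences for the LSTM
#'
#' One sequence per eligible bin: the `seq_len` bins ending at that bin,
#' clipped at the bin's trial start and front-padded with the trial's first
#' bin, so sequences never cross trial boundaries.
#'
#' @param features T x C binned feature matrix (a whole session).
#' @param bins 1-based bin indices to build sequences for.
#' @param trials trial table (`start_bin`, `end_bin`, 0-based half-open)
#'   restricted to the same session.
#' @param seq_len sequence length.
#' @return n x seq_len x C array.
#' @export
build_lstm_sequences <- function(features, bins, trials, seq_len = 20) {
  features <- as.matrix(features)
  C <- ncol(features)
  # map each bin to its trial's first bin (1-based)
  starts <- rep(NA_integer_, nrow(features))
  for (k in seq_len(nrow(trials))) {
    rows <- (trials$start_bin[k] + 1):trials$end_bin[k]
    starts[rows] <- trials$start_bin[k] + 1L
  }
  out <- array(0, dim = c(length(bins), seq_len, C))
  for (j in seq_along(bins)) {
    b <- bins[j]
    s0 <- starts[b]
    if (is.na(s0)) s0 <- max(1L, b - seq_len + 1L)
    idx <- (b - seq_len + 1):b
    idx[idx < s0] <- s0
    out[j, , ] <- features[idx, , drop = FALSE]
  }
  out
}

#' Train the LSTM velocity decoder
#'
#' @param features T x C binned SBP for the session.
#' @param velocities T x 2 aligned velocities (flex/s).
#' @param train_bins bin indices available for training (trial-restricted).
#' @param trials trial table for sequence construction.
#' @param cfg an [lstm_config()].
#' @return a `trained_lstm` with the fitted parameters, normalization
#'   constants, output rescaler, and per-iteration loss trace.
#' @export
train_lstm <- function(features, velocities, train_bins, trials,
                       cfg = lstm_config()) {
  features <- as.matrix(features); velocities <- as.matrix(velocities)
  norm <- list(x_mean = colMeans(features[train_bins, , drop = FALSE]),
               x_sd = apply(features[train_bins, , drop = FALSE], 2, stats::sd),
               y_mean = colMeans(velocities[train_bins, , drop = FALSE]),
               y_sd = apply(velocities[train_bins, , drop = FALSE], 2, stats::sd))
  norm$x_sd[norm$x_sd == 0 | !is.finite(norm$x_sd)] <- 1
  norm$y_sd[norm$y_sd == 0 | !is.finite(norm$y_sd)] <- 1
  Fs <- sweep(sweep(features, 2, norm$x_mean), 2, norm$x_sd, `/`)
  Yt <- sweep(sweep(velocities, 2, norm$y_mean), 2, norm$y_sd, `/`)

  with_seed(cfg$seed, {
    bins <- if (!is.null(cfg$n_train_sequences) &&
                cfg$n_train_sequences < length(train_bins)) {
      sort(sample(train_bins, cfg$n_train_sequences))
    } else {
      train_bins
    }
    Xseq <- build_lstm_sequences(Fs, bins, trials, cfg$seq_len)
    Yb <- Yt[bins, , drop = FALSE]
    par <- lstm_init_params(cfg$n_channels, cfg$hidden_size)
    state <- lapply(par, function(p) list(m = p * 0, v = p * 0))
    n <- dim(Xseq)[1]
    bs <- min(cfg$batch_size, n)
    lr <- cfg$lr
    best <- Inf; since_best <- 0L; steps_taken <- 0L
    iter_loss <- numeric(cfg$iterations)
    t_adam <- 0L
    it <- 0L
    while (it < cfg$iterations) {
      ord <- sample.int(n)
      for (b0 in seq(1, n, by = bs)) {
        if (it >= cfg$iterations) break
        idx <- ord[b0:min(b0 + bs - 1, n)]
        xb <- Xseq[idx, , , drop = FALSE]
        nb <- length(idx)
        # noise injection on normalized inputs
        if (cfg$noise_bias_sd > 0) {
          bias <- stats::rnorm(cfg$n_channels, 0, cfg$noise_bias_sd)
          xb <- xb + rep(bias, each = nb * cfg$seq_len)
        }
        if (cfg$noise_white_sd > 0) {
          xb <- xb + array(stats::rnorm(length(xb), 0, cfg$noise_white_sd),
                           dim = dim(xb))
        }
        yb <- Yb[idx, , drop = FALSE]
        fw <- lstm_forward(par, xb, keep_cache = TRUE)
        err <- fw$y - yb
        loss <- mean(err^2)
        if (!is.finite(loss)) stop("train_lstm: non-finite loss")
        grads <- lstm_backward(par, fw, 2 * err / length(err))
        t_adam <- t_adam + 1L
        bc1 <- 1 - 0.9^t_adam; bc2 <- 1 - 0.999^t_adam
        for (p in names(par)) {
          g <- grads[[p]] + cfg$weight_decay * par[[p]]
          state[[p]]$m <- 0.9 * state[[p]]$m + 0.1 * g
          state[[p]]$v <- 0.999 * state[[p]]$v + 0.001 * g^2
          par[[p]] <- par[[p]] - lr * (state[[p]]$m / bc1) /
            (sqrt(state[[p]]$v / bc2) + 1e-8)
        }
        it <- it + 1L
        iter_loss[it] <- loss
        # plateau scheduler on the training loss
        if (loss < best - 1e-6) {
          best <- loss; since_best <- 0L
        } else {
          since_best <- since_best + 1L
          if (since_best >= cfg$plateau_patience &&
              steps_taken < cfg$plateau_steps) {
            lr <- lr * cfg$plateau_factor
            steps_taken <- steps_taken + 1L
            since_best <- 0L
          }
        }
      }
    }
    # rescaler fit on noiseless training predictions
    preds_norm <- lstm_forward(par, Xseq)$y
    rescaler <- fit_output_rescaler(preds_norm, velocities[bins, , drop = FALSE])
    structure(list(par = par, norm = norm, rescaler = rescaler,
                   iter_loss = iter_loss, cfg = cfg, final_lr = lr),
              class = "trained_lstm")
  })
}

#' Predict velocities with a trained LSTM
#'
#' @param decoder a [train_lstm()] result.
#' @param features T x C binned SBP (same normalization basis as training).
#' @param bins bin indices to predict.
#' @param trials trial table for sequence construction.
#' @param chunk sequences per forward chunk.
#' @return length(bins) x 2 velocities in flex/s.
#' @export
predict_lstm <- function(decoder, features, bins, trials, chunk = 4096) {
  Fs <- sweep(sweep(as.matrix(features), 2, decoder$norm$x_mean), 2,
              decoder$norm$x_sd, `/`)
  out <- matrix(0, length(bins), 2)
  for (i0 in seq(1, length(bins), by = chunk)) {
    i1 <- min(i0 + chunk - 1, length(bins))
    Xseq <- build_lstm_sequences(Fs, bins[i0:i1], trials,
                                 decoder$cfg$seq_len)
    out[i0:i1, ] <- lstm_forward(decoder$par, Xseq)$y
  }
  apply_output_rescaler(decoder$rescaler, out)
}
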