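# Minimal feedforward network engine: per-channel temporal convolution,
# dense, batchnorm, ReLU and dropout layers with exact backprop and an Adam
# optimizer. All heavy operations are BLAS matrix products, so training is
# practical on a single CPU. Layouts follow build_history_windows():
# channel-major windows with H consecutive lags per channel.

nn_layer_conv_time <- function(C, H, F, seed_scale = NULL) {
  lim <- 1 / sqrt(H)
  list(type = "conv_time", C = C, H = H, F = F,
       K = matrix(stats::runif(H * F, -lim, lim), H, F),
       b = stats::runif(F, -lim, lim))
}

nn_layer_dense <- function(n_in, n_out) {
  lim <- 1 / sqrt(n_in)
  list(type = "dense",
       W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = stats::runif(n_out, -lim, lim))
}

nn_layer_batchnorm <- function(n, momentum = 0.1, eps = 1e-5) {
  list(type = "batchnorm", gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n),
       momentum = momentum, eps = eps)
}

nn_layer_relu <- function() list(type = "relu")

nn_layer_dropout <- function(rate) list(type = "dropout", rate = rate)

# forward through one layer; returns list(out, cache)
nn_layer_forward <- function(layer, x, training) {
  switch(layer$type,
    conv_time = {
      C <- layer$C; H <- layer$H; F <- layer$F
      n <- nrow(x)
      M <- matrix(t(x), nrow = H)            # H x (C*n), c fastest then n
      O <- crossprod(M, layer$K)             # (C*n) x F
      O <- sweep(O, 2, layer$b, `+`)
      out <- t(matrix(aperm(array(O, dim = c(C, n, F)), c(3, 1, 2)),
                      nrow = F * C))         # n x (C*F), f fastest within c
      list(out = out, cache = list(M = M, n = n))
    },
    dense = {
      list(out = sweep(x %*% layer$W, 2, layer$b, `+`), cache = list(x = x))
    },
    batchnorm = {
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2, mu)
        v <- colMeans(xc^2)
        inv_sd <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2, inv_sd, `*`)
        out <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
        list(out = out,
             cache = list(xhat = xhat, inv_sd = inv_sd, mu = mu, v = v,
                          n = nrow(x)))
      } else {
        xhat <- sweep(sweep(x, 2, layer$run_mean), 2,
                      1 / sqrt(layer$run_var + layer$eps), `*`)
        list(out = sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`),
             cache = NULL)
      }
    },
    relu = {
      out <- pmax(x, 0)
      list(out = out, cache = list(mask = x > 0))
    },
    dropout = {
      if (training && layer$rate > 0) {
        keep <- 1 - layer$rate
        mask <- matrix(stats::runif(length(x)) < keep, nrow(x)) / keep
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = NULL)
      }
    },
    stop("unknown layer type"))
}

# backward through one layer; returns list(dx, grads or NULL, stats or NULL)
nn_layer_backward <- function(layer, cache, dout) {
  switch(layer$type,
    conv_time = {
      C <- layer$C; F <- layer$F; n <- cache$n
      dO <- matrix(aperm(array(t(dout), dim = c(F, C, n)), c(2, 3, 1)),
                   ncol = F)                 # (C*n) x F
      dK <- cache$M %*% dO                   # H x F
      db <- colSums(dO)
      dM <- layer$K %*% t(dO)                # H x (C*n)
      dx <- t(matrix(dM, nrow = layer$H * C))
      list(dx = dx, grads = list(K = dK, b = db))
    },
    dense = {
      list(dx = tcrossprod(dout, layer$W),
           grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
    },
    batchnorm = {
      n <- cache$n
      dgamma <- colSums(dout * cache$xhat)
      dbeta <- colSums(dout)
      dxhat <- sweep(dout, 2, layer$gamma, `*`)
      # standard batchnorm backward, vectorized over columns
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
      dx <- sweep(t1 - t2, 2, cache$inv_sd, `*`)
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta),
           stats = list(mu = cache$mu, v = cache$v, n = n))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask, grads = NULL)
    },
    stop("unknown layer type"))
}

nn_forward <- function(net, x, training = FALSE) {
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    fw <- nn_layer_forward(net$layers[[i]], x, training)
    x <- fw$out
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches)
}

#' @keywords internal
nn_predict <- function(net, x, chunk = 8192) {
  x <- as.matrix(x)
  n <- nrow(x)
  out <- NULL
  for (i0 in seq(1, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1, n)
    o <- nn_forward(net, x[i0:i1, , drop = FALSE], training = FALSE)$out
    out <- rbind(out, o)
  }
  out
}

# parameter names per layer type (those that receive Adam updates)
nn_param_names <- function(layer) {
  switch(layer$type,
         conv_time = c("K", "b"),
         dense = c("W", "b"),
         batchnorm = c("gamma", "beta"),
         character(0))
}

nn_adam_init <- function(net) {
  lapply(net$layers, function(layer) {
    pn <- nn_param_names(layer)
    st <- lapply(pn, function(p) list(m = layer[[p]] * 0, v = layer[[p]] * 0))
    names(st) <- pn
    st
  })
}

# one Adam step (PyTorch-style L2 weight decay added to the gradient);
# mutates and returns list(net, state)
nn_adam_step <- function(net, grads, state, lr, weight_decay, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    pn <- nn_param_names(net$layers[[i]])
    for (p in pn) {
      g <- grads[[i]][[p]]
      if (weight_decay > 0) g <- g + weight_decay * net$layers[[i]][[p]]
      st <- state[[i]][[p]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      net$layers[[i]][[p]] <- net$layers[[i]][[p]] -
        lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
      state[[i]][[p]] <- st
    }
  }
  list(net = net, state = state)
}

# update batchnorm running statistics from a training-mode forward pass
nn_update_bn_running <- function(net, caches) {
  for (i in seq_along(net$layers)) {
    layer <- net$layers[[i]]
    if (layer$type == "batchnorm" && !is.null(caches[[i]])) {
      c_ <- caches[[i]]
      m <- layer$momentum
      unbiased <- c_$v * c_$n / max(c_$n - 1, 1)
      net$layers[[i]]$run_mean <- (1 - m) * layer$run_mean + m * c_$mu
      net$layers[[i]]$run_var <- (1 - m) * layer$run_var + m * unbiased
    }
  }
  net
}
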