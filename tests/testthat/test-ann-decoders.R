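tiny_regression <- function(n = 400, C = 6, seed = 50) {
  set.seed(seed)
  X <- matrix(rnorm(n * C * 3), n, C * 3)
  Y <- cbind(tanh(X[, 1] + 0.5 * X[, 4]) + 0.1 * rnorm(n),
             X[, 2]^2 * 0.3 - X[, 5] + 0.1 * rnorm(n))
  list(X = X, Y = Y)
}

test_that("build_tcn honors flags, spans the full history, and seeds init", {
  cfg <- tcn_config(n_channels = 6, n_filters = 4, hidden = c(16, 16))
  net <- build_tcn(cfg, seed = 3)
  types <- vapply(net$layers, `[[`, "", "type")
  expect_true("batchnorm" %in% types && "dropout" %in% types)
  expect_equal(net$layers[[1]]$H, 3)   # convolution consumes all 3 time steps
  expect_equal(nrow(net$layers[[1]]$K), 3)

  bare <- build_tcn(tcn_config(n_channels = 6, n_filters = 4,
                               hidden = c(16, 16), use_batchnorm = FALSE,
                               use_dropout = FALSE), seed = 3)
  bare_types <- vapply(bare$layers, `[[`, "", "type")
  expect_false(any(bare_types %in% c("batchnorm", "dropout")))

  net2 <- build_tcn(cfg, seed = 3)
  expect_identical(net, net2)
  expect_false(identical(net, build_tcn(cfg, seed = 4)))

  # variant flag table
  v <- tcn_variant_config("nobndp", n_channels = 6)
  expect_false(v$use_batchnorm || v$use_dropout)
  v <- tcn_variant_config("onlybn", n_channels = 6)
  expect_true(v$use_batchnorm); expect_false(v$use_dropout)
})

test_that("training is bit-deterministic and degrades gracefully to zero targets", {
  d <- tiny_regression()
  cfg <- tcn_config(n_channels = 6, n_filters = 4, hidden = c(16, 16))
  tcfg <- train_config(epochs = 3, batch_size = 64, seed = 9)
  a <- train_network(build_tcn(cfg, seed = 2), d$X, d$Y, tcfg)
  b <- train_network(build_tcn(cfg, seed = 2), d$X, d$Y, tcfg)
  Xn <- matrix(rnorm(60), 10, 18)
  expect_identical(predict_network(a, Xn), predict_network(b, Xn))
  expect_length(a$loss_trace, 3)

  # constant-zero targets: predictions collapse toward zero
  Y0 <- d$Y * 0
  z <- train_network(build_tcn(cfg, seed = 2), d$X, Y0,
                     train_config(lr = 5e-3, epochs = 40, batch_size = 64,
                                  seed = 9, normalize_targets = FALSE))
  expect_lt(mean(abs(predict_network(z, d$X))), 0.01 * stats::sd(d$Y))
})

test_that("networks trained on affinely transformed data predict identically", {
  d <- tiny_regression(seed = 51)
  cfg <- tcn_config(n_channels = 6, n_filters = 4, hidden = c(16, 16))
  tcfg <- train_config(epochs = 3, batch_size = 64, seed = 9)
  base <- train_network(build_tcn(cfg, seed = 2), d$X, d$Y, tcfg)
  # affine copies of the same data: inputs scaled/shifted, targets rescaled
  X2 <- sweep(d$X * 3.7, 2, seq_len(ncol(d$X)) * 0.1, `+`)
  Y2 <- d$Y * 2 + 5
  other <- train_network(build_tcn(cfg, seed = 2), X2, Y2, tcfg)
  Xn <- matrix(rnorm(120), 20, 18)
  Xn2 <- sweep(Xn * 3.7, 2, seq_len(ncol(d$X)) * 0.1, `+`)
  p1 <- predict_network(base, Xn)
  p2 <- predict_network(other, Xn2)
  expect_lt(max(abs((p2 - 5) / 2 - p1)), 1e-5)
})

test_that("output rescaler is two independent per-DOF affine maps", {
  set.seed(60)
  v <- matrix(rnorm(400, sd = c(0.4, 0.9)), 200, 2, byrow = TRUE)
  mu <- c(0.2, -0.4); sig <- c(0.4, 0.9)
  preds <- sweep(sweep(v, 2, mu), 2, sig, `/`)   # z-scored velocities
  r <- fit_output_rescaler(preds, v)
  expect_equal(r$w, sig, tolerance = 1e-8)
  expect_equal(r$b, mu, tolerance = 1e-8)

  # identity case
  r2 <- fit_output_rescaler(v, v)
  expect_equal(r2$w, c(1, 1), tolerance = 1e-10)
  expect_equal(r2$b, c(0, 0), tolerance = 1e-10)

  # DOFs independent: shuffling one column leaves the other's map unchanged
  shuf <- preds; shuf[, 2] <- sample(shuf[, 2])
  r3 <- fit_output_rescaler(shuf, v)
  expect_equal(r3$w[1], r$w[1], tolerance = 1e-10)
  expect_equal(r3$b[1], r$b[1], tolerance = 1e-10)

  expect_error(fit_output_rescaler(cbind(rep(1, 10), rnorm(10)), v[1:10, ]),
               "zero-variance")
})

test_that("LSTM parameter count follows the gate arithmetic and training is seeded", {
  expect_equal(lstm_core_param_count(96, 300), 4 * ((96 + 300) * 300 + 300))
  par <- with_seed(1, lstm_init_params(96, 300))
  expect_equal(length(par$Wx) + length(par$Wh) + length(par$b),
               lstm_core_param_count(96, 300))

  s <- fixture_session()
  ds <- make_decoder_dataset(s)
  rows <- dataset_rows(ds, 1:30)
  cfg <- lstm_config(n_channels = 12, hidden_size = 8, iterations = 30,
                     batch_size = 64, n_train_sequences = 300, seed = 77)
  a <- train_lstm(s$sbp, s$kinematics$velocity, ds$bins[rows], s$trials, cfg)
  b <- train_lstm(s$sbp, s$kinematics$velocity, ds$bins[rows], s$trials, cfg)
  bins <- ds$bins[dataset_rows(ds, 31:40)]
  expect_identical(predict_lstm(a, s$sbp, bins, s$trials),
                   predict_lstm(b, s$sbp, bins, s$trials))
})

test_that("LSTM sequences stay within trials and front-pad with the first bin", {
  feats <- matrix(seq_len(40), 40, 1)   # bin index as the single feature
  trials <- data.frame(trial = 1:2, start_bin = c(0, 20), end_bin = c(20, 40))
  sq <- build_lstm_sequences(feats, bins = c(25, 39), trials, seq_len = 10)
  # bin 25 is 5 bins into trial 2 (starts at bin index 21, 1-based):
  # front-padded with the trial's first bin, never reaching trial 1
  expect_equal(sq[1, , 1], c(rep(21, 6), 22:25))
  expect_equal(sq[2, , 1], 30:39)
})

test_that("ReFIT relabeling flips away-velocities and zeroes in-target bins", {
  pos <- cbind(c(0.2, 0.2, 0.50, 0.8), c(0.9, 0.9, 0.9, 0.52))
  tgt <- cbind(rep(0.5, 4), rep(0.5, 4))
  vel <- cbind(c(0.3, -0.3, 0.1, 0.2), c(-0.25, 0.25, 0.3, 0.4))
  out <- refit_relabel(vel, pos, tgt, target_width = 0.15)
  expect_equal(out[1, 1], 0.3)    # toward target, outside: unchanged
  expect_equal(out[2, 1], 0.3)    # away (target above): sign flipped
  expect_equal(out[3, 1], 0)      # inside target: zeroed
  expect_equal(out[1, 2], -0.25)  # toward target below: unchanged
  expect_equal(out[2, 2], -0.25)  # away: flipped
  expect_equal(out[4, 2], 0)      # inside: zeroed
})

test_that("ReFIT fine-tuning reduces wrong-way predictions on corrupted segments", {
  d <- tiny_regression(n = 600, seed = 52)
  cfg <- tcn_config(n_channels = 6, n_filters = 4, hidden = c(16, 16))
  base <- train_network(build_tcn(cfg, seed = 2), d$X, d$Y,
                        train_config(epochs = 4, batch_size = 64, seed = 9))

  expect_identical(refit_finetune(base, d$X, d$Y, iterations = 0), base)

  ft <- refit_finetune(base, d$X, d$Y, iterations = 500)
  expect_equal(ft$iterations, 500L)

  # corrupted replay: half the rows have their target velocities flipped;
  # relabeling restores the true sign, and fine-tuning on the corrected set
  # reduces the wrong-way fraction relative to a decoder trained on the
  # corrupted labels
  flip <- seq_len(300)
  Ybad <- d$Y; Ybad[flip, ] <- -Ybad[flip, ]
  bad <- train_network(build_tcn(cfg, seed = 2), d$X, Ybad,
                       train_config(epochs = 4, batch_size = 64, seed = 9))
  fixed <- refit_finetune(bad, d$X, d$Y, iterations = 500)
  wrong <- function(dec) mean(sign(predict_network(dec, d$X)) != sign(d$Y))
  expect_lt(wrong(fixed), wrong(bad))
})

test_that("triangular redistribution matches the analytic density", {
  set.seed(70)
  V <- matrix(rnorm(2e4, sd = 0.3), 1e4, 2)
  rows <- seq_len(1e4)
  out <- redistribute_velocities(rows, V, mode = "triangular", seed = 4)
  expect_length(out, 1e4)
  expect_identical(out, redistribute_velocities(rows, V, mode = "triangular",
                                                seed = 4))
  expect_identical(redistribute_velocities(rows, V, mode = "none"), rows)

  sp <- sqrt(rowSums(V^2))
  smax <- max(sp); peak <- smax / 2
  edges <- seq(0, smax, length.out = 41)
  emp <- tabulate(pmin(findInterval(sp[out], edges, rightmost.closed = TRUE),
                       40), 40) / 1e4
  mids <- (edges[-1] + edges[-41]) / 2
  tri <- ifelse(mids <= peak, mids / peak, (smax - mids) / (smax - peak)) *
    2 / smax
  tri_mass <- tri * diff(edges)[1]
  tv <- 0.5 * sum(abs(emp - tri_mass / sum(tri_mass)))
  expect_lt(tv, 0.1)
})
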