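test_that("task trials respect geometry, derivative identity, and seeding", {
  cfg <- task_config(n_trials = 20, target_width = 0.15, seed = 11)
  tk <- generate_task_trials(cfg)

  expect_true(all(tk$trials$target_width == 0.15))
  expect_true(all(tk$kinematics$position >= 0 & tk$kinematics$position <= 1))
  # targets +/- width/2 inside [0, 1]
  expect_true(all(tk$trials$target_idx - 0.075 >= 0 &
                    tk$trials$target_idx + 0.075 <= 1))

  dt <- cfg$bin_ms / 1000
  dv <- diff(tk$kinematics$position) / dt
  expect_lt(max(abs(dv - tk$kinematics$velocity[-1, ])), 1e-9)
  expect_equal(tk$kinematics$velocity[1, ], c(0, 0))

  # trials contiguous, non-overlapping, half-open
  expect_equal(tk$trials$start_bin[-1], tk$trials$end_bin[-nrow(tk$trials)])
  expect_equal(tk$trials$start_bin[1], 0)
  expect_equal(max(tk$trials$end_bin), nrow(tk$kinematics$position))

  tk2 <- generate_task_trials(cfg)
  expect_identical(tk, tk2)
})

test_that("task config validation names the offending field", {
  expect_error(task_config(target_width = 1.2), "target_width")
  expect_error(task_config(hold_time_ms = 11000, timeout_ms = 10000),
               "hold_time_ms")
  expect_error(task_config(bin_ms = 0), "bin_ms")
})

test_that("velocity distribution is zero-peaked, heavy-tailed, hold-dominated", {
  for (sd0 in 1:10) {
    tk <- generate_task_trials(task_config(n_trials = 40, seed = sd0))
    v <- as.vector(tk$kinematics$velocity)
    kurt <- mean((v - mean(v))^4) / stats::var(v)^2 - 3
    expect_gt(kurt, 0)
    sp <- abs(v)
    expect_gt(mean(sp < 0.1 * max(sp)), 0.5)
    # mode at zero: central bin of the histogram is the largest
    h <- hist(v, breaks = seq(min(v), max(v), length.out = 41), plot = FALSE)
    expect_equal(which.max(h$counts),
                 findInterval(0, h$breaks, rightmost.closed = TRUE))
  }
})

test_that("encoding model: cardinality, determinism, affine recoverability", {
  em <- generate_encoding_model(96, "saturating", seed = 5)
  expect_equal(nrow(em$weights), 96)
  expect_length(em$baseline, 96)
  expect_identical(em, generate_encoding_model(96, "saturating", seed = 5))

  # linear link, no noise: ridge on kinematic features recovers the affine
  # kinematics -> SBP map exactly, weights included
  eml <- generate_encoding_model(4, "linear", seed = 6, noise_frac = 0)
  tk <- generate_task_trials(task_config(n_trials = 20, seed = 7))
  sbp <- encode_sbp(tk$kinematics, eml, seed = 8)
  X <- cbind(tk$kinematics$velocity, tk$kinematics$position,
             abs(tk$kinematics$velocity))
  fit <- fit_ridge(X, sbp, lambda = 0)
  expect_lt(mse(predict_ridge(fit, X), sbp), 1e-10)
  slopes <- sweep(fit$W, 1, fit$x_sd, `/`)       # back to the original scale
  truth <- t(eml$weights * eml$gain)
  expect_lt(max(abs(slopes - truth)), 1e-6)
})

test_that("noiseless linear encoding is inverted by ridge to machine precision", {
  eml <- generate_encoding_model(8, "linear", seed = 61, noise_frac = 0)
  tk <- generate_task_trials(task_config(n_trials = 25, seed = 62))
  sbp <- encode_sbp(tk$kinematics, eml, seed = 63)
  hw <- build_history_windows(sbp)
  Y <- tk$kinematics$velocity[hw$target_rows, ]
  # lagged copies of an affine code are collinear across the window, so a
  # whisper of regularization is needed for the solve; accuracy is unharmed
  fit <- fit_ridge(hw$windows, Y, lambda = 1e-8)
  expect_lt(mse(predict_ridge(fit, hw$windows), Y), 1e-10)
})

test_that("encode_sbp: baseline degenerate case, noise seeding, nonnegativity", {
  em <- generate_encoding_model(6, "saturating", seed = 9, noise_frac = 0)
  em$weights[] <- 0
  em$offset[] <- -50  # softplus(-50) = 0 to machine precision
  tk <- generate_task_trials(task_config(n_trials = 5, seed = 10))
  sbp <- encode_sbp(tk$kinematics, em, seed = 11)
  expect_equal(sbp, matrix(em$baseline, nrow(sbp), 6, byrow = TRUE),
               tolerance = 1e-12)

  em2 <- generate_encoding_model(6, "saturating", seed = 9)
  s1 <- encode_sbp(tk$kinematics, em2, seed = 12)
  expect_identical(s1, encode_sbp(tk$kinematics, em2, seed = 12))
  expect_true(all(s1 >= 0))
})

test_that("high-SNR linear encoding: per-channel regression recovers tuning", {
  eml <- generate_encoding_model(5, "linear", seed = 21, noise_frac = 0.005)
  tk <- generate_task_trials(task_config(n_trials = 60, seed = 22))
  sbp <- encode_sbp(tk$kinematics, eml, seed = 23)
  X <- cbind(tk$kinematics$velocity, tk$kinematics$position,
             abs(tk$kinematics$velocity))
  for (c_ in 1:5) {
    fit <- stats::lm(sbp[, c_] ~ X)
    est <- stats::coef(fit)[-1]
    se <- summary(fit)$coefficients[-1, 2]
    truth <- eml$gain[c_] * eml$weights[c_, ]
    expect_true(all(abs(est - truth) < 3 * se))
  }
})

test_that("context shifts perturb the encoder but never the kinematics", {
  em <- generate_encoding_model(8, "saturating", seed = 31)
  tk <- generate_task_trials(task_config(n_trials = 5, seed = 32))
  a <- encode_sbp(tk$kinematics, em, context = "normal", seed = 33)
  b <- encode_sbp(tk$kinematics, em, context = "spring-wrist", seed = 33)
  expect_gt(max(abs(a - b)), 0)
  expect_error(encode_sbp(tk$kinematics, em, context = "zero-g"),
               "unknown context.*normal")
  # scaled to zero, every context collapses onto the identity encoder
  em0 <- generate_encoding_model(8, "saturating", seed = 31,
                                 context_shifts = scaled_context_shifts(0))
  expect_identical(encode_sbp(tk$kinematics, em0, "normal", seed = 33),
                   encode_sbp(tk$kinematics, em0, "spring-wrist", seed = 33))
})

test_that("generate_session assembles context blocks in order, reproducibly", {
  em <- generate_encoding_model(6, "saturating", seed = 41)
  cfg <- task_config(n_trials = 10, seed = 42)
  ctx <- c(normal = 12, spring = 10, wrist = 10, `spring-wrist` = 10)
  s <- generate_session(cfg, em, ctx, seed = 43)
  expect_equal(nrow(s$trials), 42)
  expect_equal(rle(s$trials$context)$values, names(ctx))
  expect_equal(as.vector(table(s$trials$context)[names(ctx)]),
               as.vector(ctx))
  expect_equal(s$trials$trial, seq_len(42))
  expect_equal(nrow(s$sbp), nrow(s$kinematics$position))
  s2 <- generate_session(cfg, em, ctx, seed = 43)
  expect_identical(s, s2)

  s1 <- generate_session(cfg, em, c(normal = 15), seed = 44)
  expect_equal(nrow(s1$trials), 15)
})

test_that("session container round-trips through the plain-text format", {
  s <- fixture_session()
  path <- file.path(tempdir(), "session-roundtrip")
  write_session(s, path)
  s2 <- read_session(path)
  expect_equal(s2$sbp, s$sbp, tolerance = 1e-12)
  expect_equal(s2$kinematics$velocity, s$kinematics$velocity,
               tolerance = 1e-12)
  expect_equal(s2$trials$start_bin, s$trials$start_bin)
  expect_equal(s2$meta$seed, s$meta$seed)
  unlink(path, recursive = TRUE)
})

test_that("raw segments have the requested length and band-limited power", {
  expect_identical(generate_raw_segment(0.5, 30000, power = 0), numeric(15000))
  x <- generate_raw_segment(1, 30000, band = c(300, 1000), power = 1, seed = 2)
  expect_length(x, 30000)
  expect_error(generate_raw_segment(1, 1000), "fs")

  # Welch power-spectrum oracle: > 90% of power inside the stated band
  sp <- stats::spec.pgram(stats::ts(x, frequency = 30000), spans = 31,
                          plot = FALSE, taper = 0)
  in_band <- sp$freq >= 300 & sp$freq <= 1000
  expect_gt(sum(sp$spec[in_band]) / sum(sp$spec), 0.9)
})
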