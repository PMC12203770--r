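# Shared fixtures, built once per test run. Sessions are kept deliberately
# small (few channels, few trials); the acceptance suite builds its own
# study-scale sessions.

.fixtures <- new.env(parent = emptyenv())

fixture_session <- function() {
  if (is.null(.fixtures$session)) {
    em <- generate_encoding_model(12, "saturating", seed = 301)
    .fixtures$session <- generate_session(
      task_config(n_trials = 60, seed = 302), em, c(normal = 60), seed = 303)
  }
  .fixtures$session
}

fixture_linear_session <- function() {
  if (is.null(.fixtures$linear)) {
    em <- generate_encoding_model(8, "linear", seed = 311, noise_frac = 0)
    .fixtures$linear <- generate_session(
      task_config(n_trials = 40, seed = 312, jitter_sd = 0),
      em, c(normal = 40), seed = 313)
  }
  .fixtures$linear
}

# independent gradient-descent ridge minimizer (oracle for fit_ridge)
ridge_gd_oracle <- function(X, Y, lambda, iters = 200000, lr = NULL) {
  Xs <- scale(X)
  mu_y <- colMeans(Y)
  Yc <- sweep(Y, 2, mu_y)
  W <- matrix(0, ncol(X), ncol(Y))
  if (is.null(lr)) lr <- 1 / (2 * (norm(Xs, "2")^2 + lambda))
  for (i in seq_len(iters)) {
    G <- 2 * (crossprod(Xs, Xs %*% W - Yc) + lambda * W)
    W <- W - lr * G
    if (max(abs(G)) < 1e-12) break
  }
  list(W = W, b = mu_y)
}
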