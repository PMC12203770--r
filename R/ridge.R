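#' Fit a ridge-regression velocity decoder
#'
#' Closed-form solution of min ||Y - Xs W - b||^2 + lambda ||W||^2, where Xs
#' is the feature matrix standardized with training-set mean and SD (lambda
#' is scale-sensitive, so standardization constants are stored in the model)
#' and the bias is unpenalized: on standardized features the bias equals the
#' target column means, so as lambda grows predictions shrink toward them.
#'
#' @param X N x P matrix of feature windows.
#' @param Y N x 2 matrix of target velocities (flex/s).
#' @param lambda L2 penalty (default 0.001).
#' @param standardize standardize columns of X first (default TRUE).
#' @return a `ridge_model` with `W` (P x 2), `b` (length 2), `lambda`,
#'   and the normalization constants.
#' @export
fit_ridge <- function(X, Y, lambda = 0.001, standardize = TRUE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X) || anyNA(Y)) stop("fit_ridge: missing values not allowed")
  if (nrow(X) == 0) stop("fit_ridge: no training rows")
  mu <- colMeans(X)
  if (standardize) {
    sd <- apply(X, 2, stats::sd)
    sd[sd == 0 | !is.finite(sd)] <- 1
  } else {
    sd <- rep(1, ncol(X))
  }
  Xs <- sweep(sweep(X, 2, mu), 2, sd, `/`)
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2, ym)
  G <- crossprod(Xs) + diag(lambda, ncol(Xs))
  W <- tryCatch(solve(G, crossprod(Xs, Yc)), error = function(e) {
    if (lambda == 0) {
      stop("fit_ridge: singular normal equations with lambda = 0; use lambda > 0")
    }
    stop(e)
  })
  # effective intercept so predictions are (X / sd) %*% W + b
  b <- ym - as.numeric(crossprod(W, mu / sd))
  structure(list(W = W, b = b, x_mean = mu, x_sd = sd, lambda = lambda),
            class = "ridge_model")
}

#' Predict velocities with a ridge model
#'
#' @param model a [fit_ridge()] model.
#' @param X N x P feature windows (same width as training).
#' @return N x 2 velocity predictions.
#' @export
predict_ridge <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(model$W)) {
    stop(sprintf("predict_ridge: expected %d feature columns, got %d",
                 nrow(model$W), ncol(X)))
  }
  sweep(sweep(X, 2, model$x_sd, `/`) %*% model$W, 2, model$b, `+`)
}
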