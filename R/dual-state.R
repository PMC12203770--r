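#' Label bins as movement ("fast") or posture ("slow")
#'
#' Pooled speed per bin is the Euclidean norm of the two-DOF velocity; the
#' split threshold is a percentile of that pooled speed (median by default).
#'
#' @param Y N x 2 velocities.
#' @param percentile split percentile in (0, 100), default 50.
#' @return logical vector, TRUE = fast/movement.
#' @export
speed_split_labels <- function(Y, percentile = 50) {
  sp <- sqrt(rowSums(as.matrix(Y)^2))
  sp > stats::quantile(sp, percentile / 100, type = 7)
}

#' Fit the dual-state movement/posture decoder
#'
#' Two linear regressions — a "movement" regression fit on fast-labeled bins
#' and a "posture" regression on slow-labeled bins — combined at inference
#' by an LDA state classifier trained on the same neural features and
#' labels. The classifier carries an adaptive decision threshold that nudges
#' itself to keep the long-run fraction of fast classifications at a target
#' ratio (1:1 by default) over a sliding window.
#'
#' @param X N x P feature windows.
#' @param Y N x 2 velocities.
#' @param fast logical fast/slow labels (default: median speed split).
#' @param lambda ridge penalty for the two sub-regressions.
#' @param target_fast_fraction long-run fast fraction to maintain (0.5 = 1:1).
#' @param window_bins sliding-window length for the adaptive threshold.
#' @param step threshold adjustment per bin.
#' @return a `dual_state_model`.
#' @export
fit_dual_state <- function(X, Y, fast = speed_split_labels(Y),
                           lambda = 0.001, target_fast_fraction = 0.5,
                           window_bins = 100, step = 0.01) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!any(fast) || all(fast)) {
    stop("fit_dual_state: both movement and posture classes must be nonempty")
  }
  movement <- fit_ridge(X[fast, , drop = FALSE], Y[fast, , drop = FALSE], lambda)
  posture <- fit_ridge(X[!fast, , drop = FALSE], Y[!fast, , drop = FALSE], lambda)
  # LDA on standardized features (standardization constants from full data)
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd); sd[sd == 0 | !is.finite(sd)] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sd, `/`)
  lda <- MASS::lda(Xs, grouping = factor(ifelse(fast, "fast", "slow"),
                                         levels = c("slow", "fast")))
  structure(list(movement = movement, posture = posture, lda = lda,
                 x_mean = mu, x_sd = sd,
                 target_fast_fraction = target_fast_fraction,
                 window_bins = window_bins, step = step,
                 init_threshold = 0.5),
            class = "dual_state_model")
}

#' Decode a window stream with the dual-state model
#'
#' Processes bins in order (the adaptive threshold is stateful). Each bin's
#' output is the LDA movement posterior times the movement regression plus
#' its complement times the posture regression. The bin is *classified* fast
#' when the posterior exceeds the current threshold; after each bin the
#' threshold moves by `step * (window fast fraction - target)`, clamped to
#' \[0, 1] — simple integral control toward the target state ratio.
#'
#' @param model a [fit_dual_state()] model.
#' @param X N x P feature windows, in temporal order.
#' @return list with `velocity` (N x 2), `p_fast` (posterior), `fast`
#'   (classified state), `threshold` (trace).
#' @export
predict_dual_state <- function(model, X) {
  X <- as.matrix(X)
  pred_m <- predict_ridge(model$movement, X)
  pred_p <- predict_ridge(model$posture, X)
  Xs <- sweep(sweep(X, 2, model$x_mean), 2, model$x_sd, `/`)
  post <- stats::predict(model$lda, Xs)$posterior[, "fast"]
  out <- post * pred_m + (1 - post) * pred_p

  n <- nrow(X)
  thr <- numeric(n)
  fast <- logical(n)
  cur <- model$init_threshold
  run_sum <- 0
  for (t in seq_len(n)) {
    thr[t] <- cur
    fast[t] <- post[t] >= cur
    run_sum <- run_sum + fast[t]
    if (t > model$window_bins) run_sum <- run_sum - fast[t - model$window_bins]
    frac <- run_sum / min(t, model$window_bins)
    cur <- min(max(cur + model$step * (frac - model$target_fast_fraction), 0), 1)
  }
  list(velocity = out, p_fast = post, fast = fast, threshold = thr)
}
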