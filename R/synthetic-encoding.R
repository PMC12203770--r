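#' Generate a ground-truth kinematics-to-SBP encoding model
#'
#' Each channel maps the instantaneous kinematic state
#' x = (v_idx, v_mrs, p_idx, p_mrs, |v_idx|, |v_mrs|) through a tuning drive
#' d = w . x + offset to an expected spiking-band-power value via one of
#' three links:
#' \describe{
#'   \item{linear}{b + gain * (w . x), with the baseline inflated so the
#'     affine map stays nonnegative over the whole kinematic range (used as
#'     the control condition under which ridge regression is near-optimal).}
#'   \item{saturating}{b + gain * softplus(d); smooth and nonnegative. The
#'     negative default offsets put most channels below threshold at rest,
#'     so they activate sparsely during movement — rectified tuning whose
#'     curvature an affine decoder cannot absorb.}
#'   \item{quadratic}{b + gain * d^2 / 2.}
#' }
#' Context shifts perturb the encoder while leaving kinematics untouched,
#' emulating manipulandum spring loads and wrist rotation: the velocity
#' tuning pair (w_vidx, w_vmrs) is rotated by a per-context angle, the gain
#' is multiplied, and the baseline offset added. The "normal" context is the
#' identity.
#'
#' @param n_channels number of channels (default 96).
#' @param nonlinearity one of "saturating", "linear", "quadratic".
#' @param seed integer seed.
#' @param noise_frac additive noise SD as a fraction of each channel's
#'   baseline (default 2.5; single-channel SBP carries far more noise than
#'   signal, so decoding must pool weak evidence across the array).
#' @param offset_mean,offset_sd distribution of the per-channel tuning
#'   threshold offset (defaults -2 and 1.5; forced to 0 for the linear
#'   link so the map stays exactly affine).
#' @param context_shifts named list of per-context perturbations, each a list
#'   with `angle` (radians), `gain_mult`, `baseline_offset`. Must contain a
#'   "normal" identity entry.
#' @return an `encoding_model` object.
#' @export
generate_encoding_model <- function(n_channels = 96,
                                    nonlinearity = c("saturating", "linear",
                                                     "quadratic"),
                                    seed = 1L, noise_frac = 2.5,
                                    offset_mean = -2, offset_sd = 1.5,
                                    context_shifts = default_context_shifts()) {
  nonlinearity <- match.arg(nonlinearity)
  if (n_channels < 1) stop("generate_encoding_model: n_channels must be >= 1")
  stopifnot(!is.null(context_shifts$normal))
  with_seed(seed, {
    # feature scales: velocities mostly within +/- 1.6 flex/s, positions [0,1]
    w <- cbind(matrix(stats::rnorm(2 * n_channels, 0, 2.0), n_channels, 2),
               matrix(stats::rnorm(2 * n_channels, 0, 0.75), n_channels, 2),
               matrix(stats::rnorm(2 * n_channels, 0, 1.0), n_channels, 2))
    gain <- stats::runif(n_channels, 0.5, 1.5)
    baseline <- exp(stats::rnorm(n_channels, 0, 0.3))
    offset <- stats::rnorm(n_channels, offset_mean, offset_sd)
    if (nonlinearity == "linear") {
      offset <- rep(0, n_channels)
      # inflate baselines so b + gain*(w.x) >= 0.1 everywhere in range:
      # no rectification ever binds and the map is exactly affine
      # (peak reach speeds stay below 5 flex/s)
      xmax <- c(5, 5, 1, 1, 5, 5)
      baseline <- 0.1 + gain * as.numeric(abs(w) %*% xmax)
    }
    structure(list(n_channels = n_channels, nonlinearity = nonlinearity,
                   weights = w, gain = gain, baseline = baseline,
                   offset = offset, noise_sd = noise_frac * baseline,
                   context_shifts = context_shifts, seed = as.integer(seed)),
              class = "encoding_model")
  })
}

#' Default context-shift parameters
#'
#' Four task contexts: normal (identity), spring (torsion springs on the
#' manipulandum), wrist (wrist rotated into flexion), and spring-wrist
#' (both). Magnitudes are fixed package defaults chosen to modulate neural
#' tuning clearly while behavior stays the same.
#' @return named list of shift parameter lists.
#' @export
default_context_shifts <- function() {
  list(
    normal         = list(angle = 0,     gain_mult = 1,    baseline_offset = 0),
    spring         = list(angle = 0.35,  gain_mult = 1.10, baseline_offset = 0.10),
    wrist          = list(angle = -0.45, gain_mult = 0.90, baseline_offset = -0.05),
    `spring-wrist` = list(angle = 0.70,  gain_mult = 1.20, baseline_offset = 0.15)
  )
}

#' Context shifts with scaled magnitude
#'
#' Returns the default shift set with every angle, gain deviation, and
#' baseline offset multiplied by `scale`; `scale = 0` gives identity shifts
#' for all contexts (the null control in which "contexts" differ in label
#' only).
#'
#' @param scale shift magnitude multiplier.
#' @return named list of shift parameter lists.
#' @export
scaled_context_shifts <- function(scale = 1) {
  lapply(default_context_shifts(), function(sh) {
    list(angle = sh$angle * scale,
         gain_mult = 1 + (sh$gain_mult - 1) * scale,
         baseline_offset = sh$baseline_offset * scale)
  })
}

# Apply a context shift to per-channel parameters.
shifted_params <- function(model, context) {
  sh <- model$context_shifts[[context]]
  if (is.null(sh)) {
    stop(sprintf("encode_sbp: unknown context '%s'; known contexts: %s",
                 context, paste(names(model$context_shifts), collapse = ", ")))
  }
  w <- model$weights
  ca <- cos(sh$angle); sa <- sin(sh$angle)
  wv <- w[, 1:2, drop = FALSE]
  w[, 1] <- ca * wv[, 1] - sa * wv[, 2]
  w[, 2] <- sa * wv[, 1] + ca * wv[, 2]
  list(weights = w, gain = model$gain * sh$gain_mult,
       baseline = pmax(model$baseline + sh$baseline_offset, 0.05),
       offset = model$offset)
}

encoding_features <- function(kin) {
  v <- kin$velocity
  p <- kin$position
  cbind(v, p, abs(v))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

#' Encode kinematics into spiking-band-power features
#'
#' Computes each channel's expected SBP under the (context-shifted) encoding
#' model, adds i.i.d. Gaussian noise per bin and channel, and rectifies at
#' zero, mirroring the nonnegativity of rectified band power.
#'
#' @param kin kinematics list (`position`, `velocity`, `bin_ms`).
#' @param model an [generate_encoding_model()] object.
#' @param context context label known to the model.
#' @param seed integer seed for the noise.
#' @return T x C nonnegative SBP matrix.
#' @export
encode_sbp <- function(kin, model, context = "normal", seed = 1L) {
  par <- shifted_params(model, context)
  X <- encoding_features(kin)
  drive <- sweep(X %*% t(par$weights), 2, par$offset, `+`)  # T x C
  mu <- switch(model$nonlinearity,
               linear = sweep(sweep(drive, 2, par$gain, `*`), 2,
                              par$baseline, `+`),
               saturating = sweep(sweep(softplus(drive), 2, par$gain, `*`), 2,
                                  par$baseline, `+`),
               quadratic = sweep(sweep(0.5 * drive^2, 2, par$gain, `*`), 2,
                                 par$baseline, `+`))
  with_seed(seed, {
    noise <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
    noise <- sweep(noise, 2, model$noise_sd, `*`)
    pmax(mu + noise, 0)
  })
}

#' Generate a complete binned session
#'
#' Concatenates one block of trials per requested context, in the given
#' order, encoding each block's kinematics under that context's shifted
#' tuning. Every downstream stage (feature windowing, fold construction,
#' decoder training, metrics) consumes this container.
#'
#' @param task_cfg a [task_config()]; its `n_trials` is overridden per block
#'   by `contexts`.
#' @param model an encoding model.
#' @param contexts named integer vector: trials per context, in block order.
#'   Default one 600-trial "normal" block.
#' @param seed session seed; per-block task and noise seeds are derived from
#'   it.
#' @return a `binned_session`: list with `sbp` (T x C), `kinematics`,
#'   `trials` (with per-trial `context`), `meta`.
#' @export
generate_session <- function(task_cfg, model, contexts = c(normal = 600),
                             seed = 1L) {
  if (any(contexts < 1)) stop("generate_session: all context counts must be >= 1")
  blocks <- vector("list", length(contexts))
  bin_off <- 0L
  trial_off <- 0L
  for (k in seq_along(contexts)) {
    ctx <- names(contexts)[k]
    cfg <- task_cfg
    cfg$n_trials <- as.integer(contexts[[k]])
    cfg$seed <- derive_seed(seed, "task", ctx, k)
    blk <- generate_task_trials(cfg, context = ctx)
    blk$sbp <- encode_sbp(blk$kinematics, model, context = ctx,
                          seed = derive_seed(seed, "noise", ctx, k))
    blk$trials$start_bin <- blk$trials$start_bin + bin_off
    blk$trials$end_bin <- blk$trials$end_bin + bin_off
    blk$trials$trial <- blk$trials$trial + trial_off
    bin_off <- bin_off + nrow(blk$kinematics$position)
    trial_off <- trial_off + nrow(blk$trials)
    blocks[[k]] <- blk
  }
  session <- list(
    sbp = do.call(rbind, lapply(blocks, `[[`, "sbp")),
    kinematics = list(
      position = do.call(rbind, lapply(blocks, function(b) b$kinematics$position)),
      velocity = do.call(rbind, lapply(blocks, function(b) b$kinematics$velocity)),
      bin_ms = task_cfg$bin_ms),
    trials = do.call(rbind, lapply(blocks, `[[`, "trials")),
    meta = list(seed = as.integer(seed), bin_ms = task_cfg$bin_ms,
                n_channels = model$n_channels,
                nonlinearity = model$nonlinearity,
                encoding_seed = model$seed, prebinned = TRUE,
                schema_version = 1L)
  )
  class(session) <- "binned_session"
  validate_session(session)
  session
}

validate_session <- function(session) {
  T <- nrow(session$sbp)
  stopifnot(nrow(session$kinematics$position) == T,
            nrow(session$kinematics$velocity) == T,
            !anyNA(session$sbp), all(session$sbp >= 0),
            all(session$trials$end_bin <= T),
            all(session$trials$start_bin >= 0))
  invisible(session)
}

#' Generate a band-limited broadband test segment
#'
#' Gaussian noise with its power concentrated in a stated frequency band,
#' used as a fixture for validating the SBP extraction chain.
#'
#' @param duration_s duration in seconds.
#' @param fs sampling rate in Hz (>= 2000).
#' @param band numeric length-2, band edges in Hz.
#' @param power target signal variance (0 gives an all-zero signal).
#' @param seed integer seed.
#' @return numeric vector of `duration_s * fs` samples.
#' @export
generate_raw_segment <- function(duration_s, fs, band = c(300, 1000),
                                 power = 1, seed = 1L) {
  if (fs < 2000) stop("generate_raw_segment: fs must be >= 2000")
  n <- round(duration_s * fs)
  if (power <= 0) return(numeric(n))
  with_seed(seed, {
    x <- stats::rnorm(n)
    bf <- signal::butter(4, band / (fs / 2), type = "pass")
    y <- signal::filtfilt(bf, x)
    y * sqrt(power / stats::var(y))
  })
}
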