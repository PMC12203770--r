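#' Task configuration for the simulated random-target finger task
#'
#' Describes a two degree-of-freedom (index vs middle-ring-small) random
#' target-acquisition task: pseudo-random targets per finger group, a
#' minimum-jerk reach to each target, then a hold. Positions live on the
#' normalized "flex" scale, the closed interval \[0, 1] from full extension
#' to full flexion; velocities are in flex/s.
#'
#' @param n_trials number of trials.
#' @param n_dof degrees of freedom (2: IDX, MRS).
#' @param target_width target size as a fraction of the movement range
#'   (default 0.15, i.e. 15\% of range).
#' @param hold_time_ms required in-target hold (default 500 ms, "testing" mode).
#' @param timeout_ms trial failure timeout (default 10000 ms).
#' @param bin_ms bin width (default 50 ms, non-overlapping).
#' @param reach_ms_range range of minimum-jerk primary-reach durations, drawn
#'   uniformly per trial.
#' @param react_ms_range range of pre-reach reaction/hold durations.
#' @param p_overshoot probability the primary reach misses and is followed by
#'   corrective submovements (produces the orbiting behavior real trials
#'   show).
#' @param max_corrections cap on corrective submovements per trial.
#' @param jitter_sd SD of the smoothed positional jitter during holds (flex).
#' @param fail_rate probability a trial is flagged unsuccessful.
#' @param seed integer seed.
#' @return a `task_config` list.
#' @export
task_config <- function(n_trials = 600, n_dof = 2, target_width = 0.15,
                        hold_time_ms = 500, timeout_ms = 10000, bin_ms = 50,
                        reach_ms_range = c(400, 900),
                        react_ms_range = c(200, 500),
                        p_overshoot = 0.6, max_corrections = 3,
                        jitter_sd = 0.002, fail_rate = 0, seed = 1L) {
  cfg <- list(n_trials = as.integer(n_trials), n_dof = as.integer(n_dof),
              target_width = target_width, hold_time_ms = hold_time_ms,
              timeout_ms = timeout_ms, bin_ms = bin_ms,
              reach_ms_range = reach_ms_range, react_ms_range = react_ms_range,
              p_overshoot = p_overshoot, max_corrections = max_corrections,
              jitter_sd = jitter_sd, fail_rate = fail_rate,
              seed = as.integer(seed))
  validate_task_config(cfg)
  structure(cfg, class = "task_config")
}

validate_task_config <- function(cfg) {
  if (cfg$n_trials < 1) stop("task_config: n_trials must be >= 1")
  if (cfg$target_width <= 0 || cfg$target_width >= 1) {
    stop("task_config: target_width must lie in (0, 1)")
  }
  if (cfg$hold_time_ms >= cfg$timeout_ms) {
    stop("task_config: hold_time_ms must be < timeout_ms")
  }
  if (cfg$bin_ms <= 0) stop("task_config: bin_ms must be > 0")
  if (cfg$fail_rate < 0 || cfg$fail_rate >= 1) {
    stop("task_config: fail_rate must lie in [0, 1)")
  }
  invisible(cfg)
}

# Minimum-jerk position profile s(tau) on [0, 1]; zero velocity/acceleration
# at both endpoints, which gives the fast-peaked reach speed shape.
min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Generate task kinematics and a trial table
#'
#' Each trial draws an independent uniform target per DOF (kept inside the
#' range so target +/- width/2 fits in \[0,1]), waits a reaction period,
#' executes a minimum-jerk primary reach, optionally overshoots and makes
#' corrective submovements back into the target (orbiting), pauses briefly
#' between submovements, then holds in-target for the hold time. Hold and
#' pause periods carry small smoothed positional jitter, so the session's
#' velocity distribution is strongly peaked at zero with heavy reach tails.
#'
#' @param config a [task_config()].
#' @param context context label stored on every trial (default "normal").
#' @return list with `kinematics` (list: `position` T x 2, `velocity` T x 2,
#'   `bin_ms`) and `trials` (data.frame: `trial`, `start_bin`, `end_bin`
#'   half-open 0-based, `target_idx`, `target_mrs`, `target_width`,
#'   `outcome`, `context`).
#' @export
generate_task_trials <- function(config, context = "normal") {
  validate_task_config(config)
  with_seed(config$seed, generate_task_trials_impl(config, context))
}

generate_task_trials_impl <- function(config, context) {
  dt <- config$bin_ms / 1000
  ndof <- config$n_dof
  w <- config$target_width
  hold_bins <- max(1L, round(config$hold_time_ms / config$bin_ms))

  pos_blocks <- vector("list", config$n_trials)
  trials <- vector("list", config$n_trials)
  cur <- rep(0.5, ndof)
  bin0 <- 0L
  for (i in seq_len(config$n_trials)) {
    react_bins <- round(stats::runif(1, config$react_ms_range[1],
                                     config$react_ms_range[2]) / config$bin_ms)
    reach_bins <- max(2L, round(stats::runif(1, config$reach_ms_range[1],
                                             config$reach_ms_range[2]) /
                                  config$bin_ms))
    target <- stats::runif(ndof, w / 2, 1 - w / 2)

    # segments: (positions-after, is_hold) pairs built up sequentially
    hold_segment <- function(p, n) matrix(p, n, ndof, byrow = TRUE)
    reach_segment <- function(from, to, n) {
      s <- min_jerk(seq_len(n) / n)
      out <- matrix(0, n, ndof)
      for (d in seq_len(ndof)) out[, d] <- from[d] + (to[d] - from[d]) * s
      out
    }
    segs <- list(hold_segment(cur, react_bins))
    jitter_rows <- list(seq_len(react_bins))
    off <- react_bins

    # primary reach, possibly missing the target
    overshoot <- stats::runif(1) < config$p_overshoot
    err <- if (overshoot) {
      stats::rnorm(ndof, 0, 0.9 * w) * sample(c(-1, 1), ndof, replace = TRUE)
    } else {
      rep(0, ndof)
    }
    land <- pmin(pmax(target + err, 0), 1)
    segs <- c(segs, list(reach_segment(cur, land, reach_bins)))
    off <- off + reach_bins
    pos <- land

    # corrective submovements: short pause, then a faster, smaller reach
    n_corr <- 0L
    while (any(abs(pos - target) > w / 4) && n_corr < config$max_corrections) {
      pause_bins <- round(stats::runif(1, 150, 400) / config$bin_ms)
      segs <- c(segs, list(hold_segment(pos, pause_bins)))
      jitter_rows <- c(jitter_rows, list(off + seq_len(pause_bins)))
      off <- off + pause_bins
      corr_bins <- max(2L, round(stats::runif(1, 250, 500) / config$bin_ms))
      n_corr <- n_corr + 1L
      landing_err <- if (n_corr >= config$max_corrections) rep(0, ndof)
                     else (pos - target) * stats::runif(ndof, -0.4, 0.4)
      new_pos <- pmin(pmax(target + landing_err, 0), 1)
      segs <- c(segs, list(reach_segment(pos, new_pos, corr_bins)))
      off <- off + corr_bins
      pos <- new_pos
    }

    segs <- c(segs, list(hold_segment(pos, hold_bins)))
    jitter_rows <- c(jitter_rows, list(off + seq_len(hold_bins)))
    n_bins <- off + hold_bins
    block <- do.call(rbind, segs)

    # smoothed (AR(1)) jitter on holds/pauses; reaches are left clean
    if (config$jitter_sd > 0) {
      jit_rows <- unlist(jitter_rows)
      for (d in seq_len(ndof)) {
        e <- stats::rnorm(length(jit_rows), 0, config$jitter_sd)
        block[jit_rows, d] <- block[jit_rows, d] +
          as.numeric(stats::filter(e, 0.7, method = "recursive"))
      }
    }

    outcome <- if (config$fail_rate > 0 &&
                   stats::runif(1) < config$fail_rate) "timeout" else "success"
    trials[[i]] <- data.frame(trial = i, start_bin = bin0,
                              end_bin = bin0 + n_bins,
                              target_idx = target[1], target_mrs = target[2],
                              target_width = w, outcome = outcome,
                              context = context,
                              stringsAsFactors = FALSE)
    pos_blocks[[i]] <- block
    cur <- target
    bin0 <- bin0 + n_bins
  }

  position <- do.call(rbind, pos_blocks)
  position <- pmin(pmax(position, 0), 1)
  velocity <- rbind(rep(0, ndof), diff(position) / dt)
  list(kinematics = list(position = position, velocity = velocity,
                         bin_ms = config$bin_ms),
       trials = do.call(rbind, trials))
}
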