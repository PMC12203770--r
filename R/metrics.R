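#' Mean-squared error between predicted and true velocities
#'
#' Mean over all bins and both DOFs of the squared error.
#'
#' @param pred N x 2 predictions.
#' @param true N x 2 true velocities.
#' @return scalar MSE.
#' @export
mse <- function(pred, true) {
  pred <- as.matrix(pred); true <- as.matrix(true)
  if (!all(dim(pred) == dim(true))) stop("mse: shape mismatch")
  mean((pred - true)^2)
}

#' Group mean and standard error of a metric across decoder instances
#'
#' @param values numeric vector (one value per instance).
#' @return list with `mean`, `se`, `n`.
#' @export
group_summary <- function(values) {
  list(mean = mean(values),
       se = stats::sd(values) / sqrt(length(values)),
       n = length(values))
}

#' High/low speed-regime masks
#'
#' Speeds are |velocity| per DOF, pooled over bins and DOFs within a
#' session. The high regime is pooled entries strictly above the 90th
#' percentile and the low regime strictly below the 10th (linear-
#' interpolation percentiles); with constant speeds both masks are empty.
#'
#' @param true_velocities N x 2 true velocities.
#' @param pct regime width in percent (default 10).
#' @return list with logical `high` and `low` masks over the pooled
#'   N*2 entries (column-major: DOF 1 then DOF 2), and the thresholds.
#' @export
speed_regime_masks <- function(true_velocities, pct = 10) {
  sp <- abs(as.vector(as.matrix(true_velocities)))
  if (length(sp) == 0) stop("speed_regime_masks: empty input")
  hi_thr <- stats::quantile(sp, 1 - pct / 100, type = 7, names = FALSE)
  lo_thr <- stats::quantile(sp, pct / 100, type = 7, names = FALSE)
  list(high = sp > hi_thr, low = sp < lo_thr,
       high_threshold = hi_thr, low_threshold = lo_thr)
}

#' Speed and error statistics per speed regime
#'
#' Mean predicted speed and MSE restricted to the pooled entries of each
#' regime; optionally relative differences against a reference decoder's
#' statistics.
#'
#' @param pred N x 2 predictions.
#' @param true N x 2 true velocities.
#' @param masks from [speed_regime_masks()] on the same session.
#' @param reference optional `regime_stats` result to compare against.
#' @return list with `high` and `low`, each `list(mean_speed, mean_true_speed,
#'   mse, n)` (NA when a mask is empty), plus `rel_diff` when a reference is
#'   given.
#' @export
regime_stats <- function(pred, true, masks, reference = NULL) {
  ps <- abs(as.vector(as.matrix(pred)))
  ts <- abs(as.vector(as.matrix(true)))
  err2 <- (as.vector(as.matrix(pred)) - as.vector(as.matrix(true)))^2
  one <- function(mask) {
    if (!any(mask)) {
      return(list(mean_speed = NA_real_, mean_true_speed = NA_real_,
                  mse = NA_real_, n = 0L))
    }
    list(mean_speed = mean(ps[mask]), mean_true_speed = mean(ts[mask]),
         mse = mean(err2[mask]), n = sum(mask))
  }
  out <- list(high = one(masks$high), low = one(masks$low))
  if (!is.null(reference)) {
    out$rel_diff <- list(
      high = list(mean_speed = (out$high$mean_speed - reference$high$mean_speed) /
                    reference$high$mean_speed,
                  mse = (out$high$mse - reference$high$mse) / reference$high$mse),
      low = list(mean_speed = (out$low$mean_speed - reference$low$mean_speed) /
                   reference$low$mean_speed,
                 mse = (out$low$mse - reference$low$mse) / reference$low$mse))
  }
  out
}

#' Empirical velocity probability mass function
#'
#' Histogram over the pooled (bins x DOFs) velocities on shared edges,
#' normalized to sum to one. Values outside the edge range are clipped into
#' the end bins so compared PMFs always share support.
#'
#' @param velocities N x 2 (or vector) velocities.
#' @param edges strictly increasing bin edges.
#' @return a `velocity_pmf`: list with `mass`, `edges`.
#' @export
velocity_pmf <- function(velocities, edges) {
  v <- as.vector(as.matrix(velocities))
  if (length(v) == 0) stop("velocity_pmf: empty input")
  if (any(diff(edges) <= 0)) stop("velocity_pmf: edges must be strictly increasing")
  v <- pmin(pmax(v, edges[1]), edges[length(edges)])
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1),
              length(edges) - 1)
  mass <- tabulate(bin, length(edges) - 1)
  structure(list(mass = mass / sum(mass), edges = edges),
            class = "velocity_pmf")
}

#' Shared histogram edges from a reference velocity distribution
#'
#' 100 equal-width bins spanning the pooled min/max of the reference
#' (hand-control) velocities; all compared PMFs must use these same edges.
#'
#' @param reference_velocities N x 2 reference velocities.
#' @param n_bins bin count (default 100).
#' @return numeric vector of edges.
#' @export
pmf_edges <- function(reference_velocities, n_bins = 100) {
  v <- as.vector(as.matrix(reference_velocities))
  seq(min(v), max(v), length.out = n_bins + 1)
}

#' Kullback-Leibler divergence between two velocity PMFs
#'
#' sum_i p_i log(p_i / q_i) in nats, with 0 * log(0/.) = 0 and q floored at
#' eps then renormalized so the divergence stays finite for empirical
#' histograms.
#'
#' @param p,q `velocity_pmf` objects on identical edges.
#' @param eps floor applied to q (default 1e-9).
#' @return nonnegative scalar (nats).
#' @export
kl_divergence <- function(p, q, eps = 1e-9) {
  if (!isTRUE(all.equal(p$edges, q$edges))) {
    stop("kl_divergence: PMFs must share identical edges")
  }
  qm <- pmax(q$mass, eps)
  qm <- qm / sum(qm)
  pm <- p$mass
  pos <- pm > 0
  sum(pm[pos] * log(pm[pos] / qm[pos]))
}

#' Median prediction deviation across decoder instances
#'
#' For each time point and DOF, the sample standard deviation (ddof 1) of
#' predictions across all instances of one decoder type; the median of the
#' resulting N x 2 values is a scalar convergence-consistency measure.
#'
#' @param prediction_sets list of >= 2 aligned N x 2 prediction matrices.
#' @return scalar median deviation.
#' @export
median_prediction_deviation <- function(prediction_sets) {
  if (length(prediction_sets) < 2) {
    stop("median_prediction_deviation: need >= 2 instances")
  }
  dims <- dim(as.matrix(prediction_sets[[1]]))
  arr <- vapply(prediction_sets, as.matrix, matrix(0, dims[1], dims[2]))
  sds <- apply(arr, c(1, 2), stats::sd)
  stats::median(sds)
}

#' Locate target acquisition events within one trial
#'
#' The in-target test per DOF is |position - center| <= width/2 (closed
#' interval). First acquisition is the first bin with both DOFs in-target;
#' final acquisition is the start of the terminal in-target run; the trial
#' succeeds if that run reaches the hold requirement before timeout.
#'
#' @param positions n_bins x 2 positions for the trial (bin 0 = trial start).
#' @param targets length-2 target centers.
#' @param width target width (scalar or length 2).
#' @param hold_time_ms required hold.
#' @param bin_ms bin width.
#' @param timeout_ms trial timeout.
#' @return list with `first_acq_bin`, `final_acq_bin` (0-based; NA if never
#'   acquired), `success`.
#' @export
trial_events <- function(positions, targets, width = 0.15, hold_time_ms = 500,
                         bin_ms = 50, timeout_ms = 10000) {
  P <- as.matrix(positions)
  half <- rep(width, length.out = 2) / 2
  inside <- abs(sweep(P, 2, targets)) <= matrix(half, nrow(P), 2, byrow = TRUE)
  both <- inside[, 1] & inside[, 2]
  hold_bins <- max(1L, round(hold_time_ms / bin_ms))
  timeout_bin <- floor(timeout_ms / bin_ms)
  if (!any(both)) {
    return(list(first_acq_bin = NA_integer_, final_acq_bin = NA_integer_,
                success = FALSE))
  }
  first_acq <- which(both)[1] - 1L  # 0-based
  # runs of consecutive in-target bins
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  in_runs <- which(r$values)
  # the successful run: first run that completes the hold before timeout
  for (k in in_runs) {
    if (r$lengths[k] >= hold_bins) {
      acq0 <- starts[k] - 1L
      if (acq0 + hold_bins <= timeout_bin) {
        return(list(first_acq_bin = first_acq, final_acq_bin = acq0,
                    success = TRUE))
      }
    }
  }
  # never held: final acquisition is the start of the terminal in-target run
  last_run <- in_runs[length(in_runs)]
  list(first_acq_bin = first_acq, final_acq_bin = starts[last_run] - 1L,
       success = FALSE)
}

#' Per-trial timing metrics and set-level summaries
#'
#' Time-to-target (TT) is the time from trial start to first simultaneous
#' acquisition; orbiting time (OT) runs from first acquisition to the start
#' of the final hold. Set summaries: orbiting rate OR = fraction of trials
#' with nonzero OT; mean TT excludes TT = 0 trials; mean OT uses nonzero OT
#' only (NA when the relevant set is empty).
#'
#' @param events list of [trial_events()] results.
#' @param bin_ms bin width.
#' @return list with per-trial `tt_ms`, `ot_ms`, `success`, and summary
#'   `mean_tt_ms`, `mean_ot_ms`, `orbiting_rate`.
#' @export
trial_metrics <- function(events, bin_ms = 50) {
  tt <- vapply(events, function(e) {
    if (is.na(e$first_acq_bin)) NA_real_ else e$first_acq_bin * bin_ms
  }, numeric(1))
  ot <- vapply(events, function(e) {
    if (is.na(e$first_acq_bin)) NA_real_
    else (e$final_acq_bin - e$first_acq_bin) * bin_ms
  }, numeric(1))
  success <- vapply(events, `[[`, logical(1), "success")
  nz_tt <- tt[!is.na(tt) & tt > 0]
  nz_ot <- ot[!is.na(ot) & ot > 0]
  list(tt_ms = tt, ot_ms = ot, success = success,
       mean_tt_ms = if (length(nz_tt)) mean(nz_tt) else NA_real_,
       mean_ot_ms = if (length(nz_ot)) mean(nz_ot) else NA_real_,
       orbiting_rate = mean(!is.na(ot) & ot > 0))
}

#' Fitts-law throughput of one trial
#'
#' Index of difficulty ID = sum over DOFs of log2(1 + D_d / W_d), with D_d
#' the distance from the position at trial start to the target center and
#' W_d the target width; throughput = ID / acquisition time.
#'
#' @param start_position length-2 position at trial start (flex).
#' @param targets length-2 target centers.
#' @param width target width (scalar or length 2).
#' @param acquisition_time_s acquisition time in seconds (> 0).
#' @return throughput in bits/s.
#' @export
fitts_throughput <- function(start_position, targets, width,
                             acquisition_time_s) {
  w <- rep(width, length.out = 2)
  if (any(w == 0)) stop("fitts_throughput: zero target width")
  if (acquisition_time_s <= 0) stop("fitts_throughput: acquisition time must be > 0")
  D <- abs(targets - start_position)
  sum(log2(1 + D / w)) / acquisition_time_s
}
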