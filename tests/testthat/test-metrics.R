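test_that("mse matches explicit summation and checks shapes", {
  p <- matrix(c(0.1, 0.4, -0.2, 0.9, 0.0, -0.5, 0.3, 0.2, 0.7, -0.1), 5, 2)
  t_ <- matrix(c(0.2, 0.1, -0.1, 0.5, 0.1, -0.2, 0.5, 0.1, 0.9, 0.0), 5, 2)
  hand <- sum((p - t_)^2) / 10
  expect_equal(mse(p, t_), hand, tolerance = 1e-12)
  expect_equal(mse(t_, t_), 0)
  expect_equal(mse(t_ + 1, t_), 1)
  expect_error(mse(p[1:3, ], t_), "shape")

  g <- group_summary(c(1, 2, 3, 4))
  expect_equal(g$mean, 2.5)
  expect_equal(g$se, stats::sd(1:4) / 2)
})

test_that("speed-regime masks select strict percentile tails of pooled speeds", {
  m <- speed_regime_masks(matrix(1:100, 100, 1), pct = 10)
  expect_equal(which(m$high), 91:100)
  expect_equal(which(m$low), 1:10)

  # constant speeds: strict inequalities leave both masks empty
  m0 <- speed_regime_masks(matrix(2, 50, 2))
  expect_false(any(m0$high) || any(m0$low))

  # pooled two-DOF toy against a sort-based oracle
  v <- matrix(c(0.1, -2, 0.3, 1.5, -0.05, 0.6, -1.1, 0.02), 4, 2)
  mk <- speed_regime_masks(v, pct = 25)
  sp <- abs(as.vector(v))
  ord <- order(sp)
  expect_equal(which(mk$low), sort(ord[1:2]))
  expect_equal(which(mk$high), sort(ord[7:8]))
})

test_that("regime statistics match a masked-mean oracle and scale linearly", {
  set.seed(80)
  t_ <- matrix(rnorm(400), 200, 2)
  masks <- speed_regime_masks(t_)
  rs0 <- regime_stats(t_, t_, masks)
  expect_equal(rs0$high$mse, 0)
  expect_equal(rs0$high$mean_speed, rs0$high$mean_true_speed)

  half <- regime_stats(0.5 * t_, t_, masks)
  expect_equal(half$high$mean_speed, 0.5 * rs0$high$mean_speed,
               tolerance = 1e-12)

  # direct filtered-mean oracle
  p <- matrix(rnorm(400), 200, 2)
  rs <- regime_stats(p, t_, masks)
  pv <- abs(as.vector(p)); tv <- as.vector(t_)
  expect_equal(rs$low$mean_speed, mean(pv[masks$low]), tolerance = 1e-12)
  expect_equal(rs$low$mse,
               mean((as.vector(p)[masks$low] - tv[masks$low])^2),
               tolerance = 1e-12)

  # relative difference against a reference decoder
  rel <- regime_stats(0.5 * t_, t_, masks, reference = rs0)
  expect_equal(rel$rel_diff$high$mean_speed, -0.5, tolerance = 1e-12)

  empty <- regime_stats(p, t_, list(high = rep(FALSE, 400), low = masks$low))
  expect_true(is.na(empty$high$mse))
})

test_that("velocity PMFs are normalized histograms on shared edges", {
  edges <- seq(-1, 1, length.out = 11)
  pm <- velocity_pmf(c(0.05, 0.05, 0.05), edges)
  expect_equal(sum(pm$mass), 1)
  expect_equal(sum(pm$mass > 0), 1)  # indicator PMF

  set.seed(90)
  v <- matrix(rnorm(200, sd = 0.4), 100, 2)
  pm2 <- velocity_pmf(v, edges)
  expect_equal(sum(pm2$mass), 1, tolerance = 1e-12)
  # counting oracle (values outside the edges clip into the end bins)
  vv <- pmin(pmax(as.vector(v), -1), 1)
  cnt <- table(cut(vv, edges, include.lowest = TRUE))
  expect_equal(pm2$mass, as.vector(cnt) / 200, tolerance = 1e-12)

  expect_error(velocity_pmf(numeric(0), edges), "empty")
  expect_error(velocity_pmf(v, c(0, 0, 1)), "increasing")
})

test_that("KL divergence: hand sum, identity, nonnegativity, monotone blends", {
  edges <- c(0, 1, 2)
  p <- structure(list(mass = c(0.5, 0.5), edges = edges), class = "velocity_pmf")
  q <- structure(list(mass = c(0.9, 0.1), edges = edges), class = "velocity_pmf")
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q),
               0.5 * log(0.5 / 0.9) + 0.5 * log(0.5 / 0.1), tolerance = 1e-12)

  set.seed(91)
  for (i in 1:100) {
    a <- stats::runif(10); a <- a / sum(a)
    b <- stats::runif(10); b <- b / sum(b)
    pa <- structure(list(mass = a, edges = 0:10), class = "velocity_pmf")
    pb <- structure(list(mass = b, edges = 0:10), class = "velocity_pmf")
    expect_gte(kl_divergence(pa, pb), 0)
  }

  q2 <- structure(list(mass = c(0.9, 0.1), edges = c(0, 1, 3)),
                  class = "velocity_pmf")
  expect_error(kl_divergence(p, q2), "edges")

  # KL falls monotonically to 0 as q blends toward p
  kls <- vapply(seq(0, 1, by = 0.25), function(alpha) {
    qa <- structure(list(mass = alpha * p$mass + (1 - alpha) * q$mass,
                         edges = edges), class = "velocity_pmf")
    kl_divergence(p, qa)
  }, numeric(1))
  expect_true(all(diff(kls) < 0))
  expect_equal(kls[5], 0)
})

test_that("median prediction deviation has the two-instance closed form", {
  set.seed(92)
  base <- matrix(rnorm(40), 20, 2)
  expect_equal(median_prediction_deviation(list(base, base, base)), 0)

  delta <- 0.37
  expect_equal(median_prediction_deviation(list(base, base + delta)),
               delta / sqrt(2), tolerance = 1e-12)

  inst <- list(base, base + matrix(rnorm(40), 20, 2),
               base + matrix(rnorm(40), 20, 2))
  expect_equal(median_prediction_deviation(inst),
               median_prediction_deviation(rev(inst)))
  expect_error(median_prediction_deviation(list(base)), "2 instances")
})

test_that("trial events locate first and final acquisition per the hold rule", {
  tgt <- c(0.5, 0.5)
  # starts inside both targets and stays: TT = 0, OT = 0
  inside <- matrix(0.5, 15, 2)
  ev <- trial_events(inside, tgt, width = 0.15, hold_time_ms = 500)
  expect_equal(ev$first_acq_bin, 0)
  expect_equal(ev$final_acq_bin, 0)
  expect_true(ev$success)

  # enters both targets at bin 10 and never exits: TT = 500 ms, OT = 0
  p <- matrix(0.2, 30, 2); p[11:30, ] <- 0.5
  ev2 <- trial_events(p, tgt, width = 0.15, hold_time_ms = 500)
  expect_equal(ev2$first_acq_bin, 10)
  expect_equal(ev2$final_acq_bin, 10)

  # enters at 500 ms, exits at 700 ms, re-enters at 900 ms and holds:
  # OT = 900 - 500 = 400 ms
  p3 <- matrix(0.2, 40, 2)
  p3[11:14, ] <- 0.5   # bins 10-13: in target (exit at bin 14 = 700 ms)
  p3[19:40, ] <- 0.5   # re-enter at bin 18 (900 ms) and hold
  ev3 <- trial_events(p3, tgt, width = 0.15, hold_time_ms = 500)
  expect_equal(ev3$first_acq_bin, 10)
  expect_equal(ev3$final_acq_bin, 18)
  mt <- trial_metrics(list(ev3))
  expect_equal(mt$tt_ms, 500)
  expect_equal(mt$ot_ms, 400)

  # never acquired
  ev4 <- trial_events(matrix(0, 10, 2), tgt)
  expect_true(is.na(ev4$first_acq_bin))
  expect_false(ev4$success)
})

test_that("trial metric summaries follow the exclusion rules", {
  evs <- list(
    list(first_acq_bin = 0, final_acq_bin = 0, success = TRUE),    # TT 0, OT 0
    list(first_acq_bin = 4, final_acq_bin = 4, success = TRUE),    # TT 200, OT 0
    list(first_acq_bin = 6, final_acq_bin = 14, success = TRUE))   # OT 400
  m <- trial_metrics(evs)
  expect_equal(m$orbiting_rate, 1 / 3)
  expect_equal(m$mean_ot_ms, 400)
  expect_equal(m$mean_tt_ms, mean(c(200, 300)))  # TT = 0 excluded

  all0 <- trial_metrics(list(evs[[1]], evs[[1]]))
  expect_equal(all0$orbiting_rate, 0)
  expect_true(is.na(all0$mean_tt_ms))
})

test_that("Fitts throughput follows the summed index of difficulty", {
  expect_equal(fitts_throughput(c(0.5, 0.5), c(0.5, 0.5), 0.15, 2), 0)
  # D = 0.45, W = 0.15 on both DOFs over 1 s: 2 * log2(4) = 4 bits/s
  expect_equal(fitts_throughput(c(0.05, 0.05), c(0.5, 0.5), 0.15, 1), 4)
  expect_equal(fitts_throughput(c(0.05, 0.05), c(0.5, 0.5), 0.15, 0.5), 8)
  expect_error(fitts_throughput(c(0, 0), c(0.5, 0.5), 0, 1), "width")
  expect_error(fitts_throughput(c(0, 0), c(0.5, 0.5), 0.15, 0), "> 0")
})
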