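test_that("paired t-test matches the textbook formula and handles degeneracy", {
  a <- c(2.1, 3.4, 1.9, 4.2, 3.3, 2.8)
  b <- c(1.8, 3.1, 2.2, 3.6, 2.9, 2.4)
  r <- paired_ttest(a, b, tail = "two")
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_equal(r$df, 5)

  r1 <- paired_ttest(a, b, tail = "greater")
  expect_equal(r1$p, stats::t.test(a, b, paired = TRUE,
                                   alternative = "greater")$p.value,
               tolerance = 1e-12)

  same <- paired_ttest(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)

  # constant positive difference: degenerate, one-tailed p reported as 0
  r2 <- paired_ttest(1:10 + 0.5, 1:10, tail = "greater")
  expect_true(r2$degenerate)
  expect_lt(r2$p, 1e-6)
  expect_true(r2$decision)

  expect_error(paired_ttest(1:3, 1:4), "length")
})

test_that("two-sample pooled t matches t.test(var.equal = TRUE)", {
  set.seed(100)
  a <- rnorm(12, 1); b <- rnorm(9)
  r <- two_sample_ttest(a, b, tail = "two")
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p, ref$p.value, tolerance = 1e-12)
  expect_equal(r$df, 19)

  w <- two_sample_ttest(a, b, tail = "two", welch = TRUE)
  refw <- stats::t.test(a, b)
  expect_equal(w$p, refw$p.value, tolerance = 1e-12)

  expect_equal(two_sample_ttest(a, a)$p, 1)
  expect_error(two_sample_ttest(a, numeric(1)), "n >= 2")
})

test_that("two-proportion z-test uses the pooled standard error", {
  r <- diff_of_proportions(90, 100, 10, 100, tail = "two")
  pp <- 0.5
  z_hand <- (0.9 - 0.1) / sqrt(pp * (1 - pp) * (2 / 100))
  expect_equal(r$statistic, z_hand, tolerance = 1e-12)
  expect_lt(r$p, 1e-10)

  expect_equal(diff_of_proportions(30, 60, 25, 50)$statistic, 0)
  expect_equal(diff_of_proportions(30, 60, 25, 50)$p, 1)

  # symmetry: swapping groups flips the sign
  r2 <- diff_of_proportions(10, 100, 90, 100, tail = "two")
  expect_equal(r2$statistic, -r$statistic)
  expect_equal(r2$p, r$p)

  # agreement with the continuity-uncorrected chi-square test
  pt <- stats::prop.test(c(40, 28), c(90, 95), correct = FALSE)
  r3 <- diff_of_proportions(40, 90, 28, 95, tail = "two")
  expect_equal(r3$statistic^2, unname(pt$statistic), tolerance = 1e-10)
  expect_equal(r3$p, pt$p.value, tolerance = 1e-10)

  expect_error(diff_of_proportions(5, 0, 1, 10), "zero group")
  expect_error(diff_of_proportions(11, 10, 1, 10), "\\[0, n\\]")
})

test_that("nested ANOVA reproduces a hand-computed 2x2x3 decomposition", {
  # 2 days x 2 runs x 3 replicates
  y <- c(1, 2, 3,  4, 5, 6,   7, 8, 9,  10, 11, 15)
  day <- rep(c("d1", "d2"), each = 6)
  run <- rep(c("r1", "r2", "r1", "r2"), each = 3)
  tab <- nested_anova(y, day, run)

  gm <- mean(y)
  ss_day <- 6 * (mean(y[1:6]) - gm)^2 + 6 * (mean(y[7:12]) - gm)^2
  ss_run <- 3 * ((mean(y[1:3]) - mean(y[1:6]))^2 +
                 (mean(y[4:6]) - mean(y[1:6]))^2 +
                 (mean(y[7:9]) - mean(y[7:12]))^2 +
                 (mean(y[10:12]) - mean(y[7:12]))^2)
  ss_tot <- sum((y - gm)^2)
  expect_equal(tab$ss[tab$effect == "day"], ss_day, tolerance = 1e-10)
  expect_equal(tab$ss[tab$effect == "run(day)"], ss_run, tolerance = 1e-10)
  expect_equal(sum(tab$ss), ss_tot, tolerance = 1e-8)
  expect_equal(tab$df, c(1, 2, 8))

  # agreement with aov's nested formula
  av <- summary(stats::aov(y ~ factor(day) / factor(run)))[[1]]
  expect_equal(tab$ss[1:2], av$`Sum Sq`[1:2], tolerance = 1e-8)
  expect_equal(tab$p[1:2], av$`Pr(>F)`[1:2], tolerance = 1e-8)

  # crossed variant reports an interaction row
  cr <- nested_anova(y, day, run, model = "crossed")
  expect_true(any(grepl(":", cr$effect)))

  # all-identical data: degenerate, no finite F
  z <- nested_anova(rep(1, 12), day, run)
  expect_true(all(is.na(z$F) | z$effect == "residual"))
  expect_warning(nested_anova(y[1:9], rep(c("d1", "d2"), c(6, 3)),
                              c(rep(c("r1", "r2"), each = 3), rep("r1", 3))),
                 "single run")
})

test_that("nested ANOVA detects an injected day effect but not a null run effect", {
  hits_day <- 0; hits_run <- 0
  for (rep_ in 1:20) {
    set.seed(200 + rep_)
    day <- rep(paste0("d", 1:4), each = 5 * 30)
    run <- rep(rep(paste0("r", 1:5), each = 30), times = 4)
    y <- rnorm(length(day)) + rep(rnorm(4, sd = 3), each = 150)  # 3-sigma day effect
    tab <- nested_anova(y, day, run)
    hits_day <- hits_day + (tab$p[tab$effect == "day"] < 0.01)
    hits_run <- hits_run + (tab$p[tab$effect == "run(day)"] >= 0.01)
  }
  expect_gte(hits_day, 18)
  expect_gte(hits_run, 18)
})

test_that("type-I error is calibrated at alpha 0.01 for all four tests", {
  n_rep <- 2000
  alpha <- 0.01
  set.seed(500)
  hits <- c(paired = 0, two_sample = 0, props = 0, anova = 0)
  for (i in seq_len(n_rep)) {
    a <- rnorm(10); b <- rnorm(10)
    hits["paired"] <- hits["paired"] + (paired_ttest(a, b)$p < alpha)
    hits["two_sample"] <- hits["two_sample"] +
      (two_sample_ttest(rnorm(12), rnorm(12))$p < alpha)
    hits["props"] <- hits["props"] +
      (diff_of_proportions(rbinom(1, 200, 0.4), 200,
                           rbinom(1, 200, 0.4), 200)$p < alpha)
    y <- rnorm(36)
    tab <- nested_anova(y, rep(1:3, each = 12), rep(rep(1:3, each = 4), 3))
    hits["anova"] <- hits["anova"] + (tab$p[1] < alpha)
  }
  rates <- hits / n_rep
  expect_true(all(rates >= 0.002 & rates <= 0.025))
})
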