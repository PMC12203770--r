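comparison_result <- function(test, statistic, p, tail, alpha, n, df = NA,
                              degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, p = p, tail = tail,
                 alpha = alpha, n = n, df = df,
                 decision = is.finite(p) && p < alpha,
                 degenerate = degenerate),
            class = "comparison_result")
}

tail_p <- function(t, df, tail) {
  switch(tail,
         two = 2 * stats::pt(-abs(t), df),
         greater = stats::pt(t, df, lower.tail = FALSE),
         less = stats::pt(t, df),
         stop("tail must be 'two', 'greater' or 'less'"))
}

#' Paired t-test on matched decoder results
#'
#' Standard paired t on the differences a - b; results must be paired by
#' (fold, seed, session). Zero-variance differences are reported as p = 0 or
#' 1 according to the tail and sign, flagged degenerate, rather than
#' dividing by zero.
#'
#' @param a,b equal-length numeric vectors.
#' @param tail "two", "greater" (a > b) or "less".
#' @param alpha significance level (default 0.01).
#' @return a `comparison_result`.
#' @export
paired_ttest <- function(a, b, tail = c("two", "greater", "less"),
                         alpha = 0.01) {
  tail <- match.arg(tail)
  if (length(a) != length(b)) stop("paired_ttest: length mismatch")
  d <- a - b
  n <- length(d)
  if (stats::sd(d) == 0) {
    p <- degenerate_p(mean(d), tail)
    return(comparison_result("paired t", ifelse(mean(d) == 0, 0,
                                                sign(mean(d)) * Inf),
                             p, tail, alpha, n, n - 1, degenerate = TRUE))
  }
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  comparison_result("paired t", t, tail_p(t, n - 1, tail), tail, alpha, n,
                    n - 1)
}

degenerate_p <- function(m, tail) {
  switch(tail,
         two = if (m == 0) 1 else 0,
         greater = if (m > 0) 0 else 1,
         less = if (m < 0) 0 else 1)
}

#' Two-sample t-test (pooled variance)
#'
#' Student's two-sample t with pooled variance (the study's unqualified
#' "two-sample t-test"); Welch's correction available by flag.
#'
#' @param a,b numeric vectors (each n >= 2).
#' @param tail "two", "greater" (mean a > mean b) or "less".
#' @param alpha significance level.
#' @param welch use Welch's unequal-variance form.
#' @return a `comparison_result`.
#' @export
two_sample_ttest <- function(a, b, tail = c("two", "greater", "less"),
                             alpha = 0.01, welch = FALSE) {
  tail <- match.arg(tail)
  if (length(a) < 2 || length(b) < 2) stop("two_sample_ttest: need n >= 2 per group")
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  if (v1 == 0 && v2 == 0) {
    m <- mean(a) - mean(b)
    return(comparison_result("two-sample t", ifelse(m == 0, 0, sign(m) * Inf),
                             degenerate_p(m, tail), tail, alpha, c(n1, n2),
                             degenerate = TRUE))
  }
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- se^4 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  t <- (mean(a) - mean(b)) / se
  comparison_result(if (welch) "Welch t" else "two-sample t", t,
                    tail_p(t, df, tail), tail, alpha, c(n1, n2), df)
}

#' Two-proportion z-test with pooled proportion
#'
#' @param k1,n1,k2,n2 successes and totals per group.
#' @param tail "two", "greater" (p1 > p2) or "less".
#' @param alpha significance level.
#' @return a `comparison_result`.
#' @export
diff_of_proportions <- function(k1, n1, k2, n2,
                                tail = c("two", "greater", "less"),
                                alpha = 0.01) {
  tail <- match.arg(tail)
  if (n1 == 0 || n2 == 0) stop("diff_of_proportions: zero group size")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2) {
    stop("diff_of_proportions: k must lie in [0, n]")
  }
  p1 <- k1 / n1; p2 <- k2 / n2
  pp <- (k1 + k2) / (n1 + n2)
  se <- sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  if (se == 0) {
    return(comparison_result("two-proportion z", 0, degenerate_p(0, tail),
                             tail, alpha, c(n1, n2), degenerate = TRUE))
  }
  z <- (p1 - p2) / se
  p <- switch(tail,
              two = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  comparison_result("two-proportion z", z, p, tail, alpha, c(n1, n2))
}

#' Nested two-way ANOVA: day and run-within-day
#'
#' Decomposes variance into a day (session) effect, a run-within-day effect
#' (runs are nested in days), and residual, with F tests against the
#' residual mean square. A crossed variant treating day and run as crossed
#' factors with an interaction is also available, since reported
#' "interactions" are only defined for the crossed layout.
#'
#' @param values numeric response (e.g. per-trial throughput).
#' @param day factor/vector of session labels.
#' @param run factor/vector of run labels within day.
#' @param model "nested" or "crossed".
#' @return data.frame with one row per effect: `effect`, `df`, `ss`, `ms`,
#'   `F`, `p`. Degenerate (zero-variance) inputs yield NA F and p.
#' @export
nested_anova <- function(values, day, run, model = c("nested", "crossed")) {
  model <- match.arg(model)
  day <- factor(day); run <- factor(run)
  if (nlevels(day) < 2) stop("nested_anova: need >= 2 days")
  if (model == "crossed") {
    fit <- stats::aov(values ~ day * run)
    tab <- summary(fit)[[1]]
    out <- data.frame(effect = trimws(rownames(tab)), df = tab$Df,
                      ss = tab$`Sum Sq`, ms = tab$`Mean Sq`,
                      F = tab$`F value`, p = tab$`Pr(>F)`,
                      stringsAsFactors = FALSE)
    return(out)
  }
  # nested SS by cell means (handles mild unbalance)
  cell <- interaction(day, run, drop = TRUE)
  gm <- mean(values)
  day_means <- tapply(values, day, mean)
  day_n <- tabulate(day)
  ss_day <- sum(day_n * (day_means - gm)^2)
  # runs nested within days: deviations of run cells from their day mean
  df_run <- 0L
  ss_run <- 0
  for (d in levels(day)) {
    sel <- day == d
    runs_d <- droplevels(run[sel])
    if (nlevels(runs_d) < 2) {
      warning(sprintf("nested_anova: day '%s' has a single run; its nested term is dropped", d))
      next
    }
    rm_ <- tapply(values[sel], runs_d, mean)
    rn <- tabulate(runs_d)
    ss_run <- ss_run + sum(rn * (rm_ - day_means[[d]])^2)
    df_run <- df_run + nlevels(runs_d) - 1L
  }
  ss_tot <- sum((values - gm)^2)
  ss_res <- ss_tot - ss_day - ss_run
  df_day <- nlevels(day) - 1L
  df_res <- length(values) - nlevels(cell)
  ms_res <- ss_res / df_res
  mk <- function(eff, df, ss) {
    ms <- ss / df
    if (ms_res <= 0 || df == 0) {
      data.frame(effect = eff, df = df, ss = ss, ms = ms, F = NA_real_,
                 p = NA_real_, stringsAsFactors = FALSE)
    } else {
      F <- ms / ms_res
      data.frame(effect = eff, df = df, ss = ss, ms = ms, F = F,
                 p = stats::pf(F, df, df_res, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }
  }
  rbind(mk("day", df_day, ss_day),
        mk("run(day)", df_run, ss_run),
        data.frame(effect = "residual", df = df_res, ss = ss_res,
                   ms = ss_res / df_res, F = NA_real_, p = NA_real_,
                   stringsAsFactors = FALSE))
}
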