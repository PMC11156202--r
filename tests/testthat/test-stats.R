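test_that("Mann-Whitney U equals the brute-force pair count on arbitrary inputs", {
  set.seed(101)
  for (i in 1:60) {
    n1 <- sample(1:8, 1); n2 <- sample(1:8, 1)
    x <- sample(0:6, n1, replace = TRUE)   # heavy ties on purpose
    y <- sample(0:6, n2, replace = TRUE)
    expect_equal(mann_whitney_u(x, y)$statistic, mw_u_brute(x, y))
  }
})

test_that("normal-approximation p stays within 0.05 of the exact permutation p", {
  # full enumeration: every 4/4 split of a fixed tie-free integer pool.
  # At n = 4 the 0.05 bound needs the continuity-corrected approximation;
  # the uncorrected normal deviates by up to 0.12 at the extreme splits.
  pool <- c(3, 7, 12, 18, 25, 33, 46, 60)
  splits <- utils::combn(8, 4)
  for (j in seq_len(ncol(splits))) {
    x <- pool[splits[, j]]; y <- pool[-splits[, j]]
    approx_p <- mann_whitney_u(x, y, continuity = "on")$p_value
    exact_p <- perm_mw_p(x, y)
    expect_lt(abs(approx_p - exact_p), 0.05)
  }
})

test_that("Mann-Whitney edge cases and continuity handling match the reference", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_lt(r$p_value, 0.1)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$statistic, 4.5)
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 1, tolerance = 1e-9)
  expect_equal(mann_whitney_u(rep(2, 4), rep(2, 5))$p_value, 1)  # zero variance
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
  # oracle: stats::wilcox.test normal approximation, with and without continuity
  set.seed(55)
  for (i in 1:25) {
    x <- rnorm(sample(2:9, 1)); y <- rnorm(sample(2:9, 1))
    w_on <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
    w_off <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = FALSE))
    expect_equal(mann_whitney_u(x, y, continuity = "on")$p_value, w_on$p.value,
                 tolerance = 1e-10)
    expect_equal(mann_whitney_u(x, y, continuity = "off")$p_value, w_off$p.value,
                 tolerance = 1e-10)
  }
})

test_that("Fisher exact matches full enumeration on all small tables", {
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p_value, 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(0, 0, 3, 4), 2))$p_value, 1)  # zero margin
  expect_error(fisher_exact(matrix(c(1.5, 1, 1, 1), 2)), "integers")
  # probability-ordering oracle: stats::fisher.test over random tables N <= 40
  set.seed(202)
  for (i in 1:150) {
    repeat {
      tb <- matrix(rmultinom(1, sample(4:40, 1), prob = runif(4, 0.05, 1)), 2)
      if (all(rowSums(tb) > 0) && all(colSums(tb) > 0)) break
    }
    expect_equal(fisher_exact(tb)$p_value, stats::fisher.test(tb)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Kaplan-Meier equals the empirical survival function without censoring", {
  km <- km_estimate(1:4, rep(TRUE, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  allc <- km_estimate(c(3, 8, 10), rep(FALSE, 3))
  expect_true(all(allc$surv == 1))
  # interleaved censoring, hand-applied product-limit: S(2)=2/3, S(4)=0
  km2 <- km_estimate(c(2, 3, 4), c(TRUE, FALSE, TRUE))
  expect_equal(km_at(km2, 2)$surv, 2 / 3)
  expect_equal(km_at(km2, 4)$surv, 0)
  # property: no censoring -> empirical survival, any sample
  set.seed(33)
  for (i in 1:20) {
    times <- sample(1:30, sample(3:15, 1), replace = TRUE)
    km3 <- km_estimate(times, rep(TRUE, length(times)))
    for (t in unique(times)) {
      expect_equal(km_at(km3, t)$surv, empirical_surv(times, t), tolerance = 1e-12)
    }
  }
  expect_error(km_estimate(c(0, 1), c(TRUE, TRUE)), "positive")
})

test_that("Greenwood intervals match the survival package and shrink with n", {
  skip_if_not_installed("survival")
  set.seed(44)
  time <- rexp(40, 0.05); event <- runif(40) < 0.7
  km <- km_estimate(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, conf.type = "plain")
  sm <- summary(sf, times = km$time)
  expect_equal(km$surv, sm$surv, tolerance = 1e-10)
  ok <- sm$surv > 0   # survival returns NaN std.err once S hits 0
  expect_equal(km$std_err[ok], sm$std.err[ok], tolerance = 1e-10)
  expect_equal(pmax(km$lower[ok], 0), pmax(sm$lower[ok], 0), tolerance = 1e-10)
  # interval width at the median event time decreases as n grows
  widths <- vapply(c(50, 500, 5000), function(n) {
    t <- rexp(n, 0.05)
    k <- km_estimate(t, rep(TRUE, n))
    a <- km_at(k, stats::median(t)); a$upper - a$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("log-rank test matches survdiff and handles degenerate groups", {
  skip_if_not_installed("survival")
  set.seed(66)
  for (i in 1:15) {
    ta <- rexp(12, 0.05); tb <- rexp(10, 0.12)
    ea <- runif(12) < 0.8; eb <- runif(10) < 0.8
    if (!any(ea) && !any(eb)) next
    r <- logrank(ta, ea, tb, eb)
    sd_ <- survival::survdiff(survival::Surv(c(ta, tb), c(ea, eb)) ~
                                rep(1:2, c(12, 10)))
    expect_equal(r$statistic, sd_$chisq, tolerance = 1e-10)
    expect_equal(r$p_value, stats::pchisq(sd_$chisq, 1, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  # identical event-time multisets split in two -> chi-square 0, p 1
  same <- c(2, 5, 9, 14)
  r0 <- logrank(same, rep(TRUE, 4), same, rep(TRUE, 4))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  # complete separation is detected as significant
  r1 <- logrank(1:5, rep(TRUE, 5), 11:15, rep(TRUE, 5))
  expect_lt(r1$p_value, 0.05)
  # all censored -> note and p = 1
  r2 <- logrank(c(5, 6), c(FALSE, FALSE), c(7, 8), c(FALSE, FALSE))
  expect_equal(r2$p_value, 1)
  expect_match(r2$note, "no events")
})

test_that("effect summaries reproduce fold and reduction arithmetic", {
  e <- effect_summaries(13.1, 4.9)
  expect_equal(e$fold_rounded, 2.7)
  expect_equal(effect_summaries(10, 10)$fold, 1)
  expect_equal(effect_summaries(10, 10)$percent_reduction, 0)
  expect_equal(effect_summaries(5.9, 10.9)$percent_reduction_rounded, 46)
  expect_error(effect_summaries(1, 0), "positive")
})
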