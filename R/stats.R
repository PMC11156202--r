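#' Nonparametric cohort statistics
#'
#' The statistical toolkit used by the study's reporting: Mann-Whitney U
#' with normal approximation and tie correction (continuity correction
#' applied when ties are present), the two-sided Fisher exact test by
#' probability ordering, the Kaplan-Meier product-limit estimator with
#' Greenwood 95 percent intervals, the two-group log-rank test, and the
#' fold-change / percent-reduction summaries.  All routines are implemented
#' from the defining formulas; the pre-installed `stats` and `survival`
#' equivalents serve only as independent oracles in the test suite.
#'
#' @name cohort-stats
NULL

new_test_result <- function(test, statistic, p_value, n, note = "") {
  if (is.finite(p_value)) p_value <- min(max(p_value, 0), 1)
  structure(list(test = test, statistic = statistic, p_value = p_value,
                 n = n, note = note),
            class = "uvm_test")
}

#' @export
print.uvm_test <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, p = %.4g (n = %s)%s\n",
              x$test, x$statistic, x$p_value, paste(x$n, collapse = "/"),
              if (nzchar(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Mann-Whitney U test, normal approximation with tie correction
#'
#' U is computed from midranks as `R1 - n1(n1+1)/2`, i.e. the number of
#' `(x, y)` pairs with `x > y` plus half the tied pairs.  The z statistic
#' uses the tie-corrected variance
#' `n1 n2 / 12 * (N + 1 - sum(t^3 - t) / (N (N - 1)))` and, per the
#' reporting convention, a 0.5 continuity correction towards zero when ties
#' are present (`continuity = "auto"`); it can be forced on or off.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param continuity `"auto"` (apply iff ties are present), `"on"`, or
#'   `"off"`.
#' @return A `uvm_test` with `statistic` = U (of `x`), two-sided normal
#'   `p_value`, and a note describing ties/continuity handling.
#' @export
mann_whitney_u <- function(x, y, continuity = c("auto", "on", "off")) {
  continuity <- match.arg(continuity)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L) abort("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("samples contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))                       # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  mu <- n1 * n2 / 2
  use_cc <- switch(continuity, auto = has_ties, on = TRUE, off = FALSE)
  if (sigma2 <= 0) {
    return(new_test_result("mann-whitney-u", U, 1, c(n1, n2),
                           "zero variance (all observations tied)"))
  }
  cc <- if (use_cc) 0.5 else 0
  num <- U - mu
  z <- (num - sign(num) * min(cc, abs(num))) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  note <- sprintf("ties=%s, continuity=%s", has_ties, use_cc)
  new_test_result("mann-whitney-u", U, p, c(n1, n2), note)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' With both margins fixed, every admissible table's hypergeometric
#' probability is enumerated and the two-sided p-value is the sum over
#' tables at most as probable as the observed one (probability-ordering
#' criterion, with relative tolerance 1e-7 guarding floating-point ties).
#' A zero margin makes the table degenerate: p = 1 with a note.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return A `uvm_test` with the observed table probability as `statistic`.
#' @examples
#' fisher_exact(matrix(c(15, 16, 20, 3), 2))   # p ~ 0.004
#' @export
fisher_exact <- function(table) {
  tb <- as.matrix(table)
  if (!all(dim(tb) == c(2L, 2L))) abort("`table` must be 2x2")
  if (anyNA(tb) || any(tb < 0) || any(tb != floor(tb))) {
    abort("counts must be non-negative integers")
  }
  rs <- rowSums(tb); cs <- colSums(tb); N <- sum(tb)
  if (any(rs == 0) || any(cs == 0)) {
    return(new_test_result("fisher-exact", NA_real_, 1, N,
                           "degenerate table (zero margin)"))
  }
  # k = count in cell [1,1]; hypergeometric over admissible range
  k_obs <- tb[1, 1]
  k_min <- max(0, cs[1] - rs[2])
  k_max <- min(rs[1], cs[1])
  k <- k_min:k_max
  logp <- stats::dhyper(k, m = cs[1], n = cs[2], k = rs[1], log = TRUE)
  lp_obs <- logp[k == k_obs]
  keep <- logp <= lp_obs + log(1 + 1e-7)
  p <- sum(exp(logp[keep]))
  new_test_result("fisher-exact", exp(lp_obs), p, N,
                  "two-sided, probability ordering")
}

#' Kaplan-Meier product-limit estimate with Greenwood intervals
#'
#' Computes the survival step function over observed event times, the
#' Greenwood variance, and 95 percent confidence intervals either on the
#' plain survival scale clipped to `[0, 1]` (default) or via the
#' complementary log-log transform.  Subjects without the event by the end
#' of their follow-up (or lost to other causes) enter as censored.
#'
#' @param time Positive follow-up times (months).
#' @param event Logical or 0/1: `TRUE` when the event (metastasis) was
#'   observed, `FALSE` for censoring.
#' @param conf_level Confidence level for the intervals.
#' @param conf_type `"plain"` or `"loglog"`.
#' @return A `km_fit` data frame with one row per distinct event-or-censor
#'   time: `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `std_err`,
#'   `lower`, `upper`.
#' @export
km_estimate <- function(time, event, conf_level = 0.95,
                        conf_type = c("plain", "loglog")) {
  conf_type <- match.arg(conf_type)
  time <- as.numeric(time)
  event <- as.logical(event)
  if (length(time) < 1L) abort("at least one record is required")
  if (length(event) != length(time)) abort("`time` and `event` lengths differ")
  if (anyNA(time) || anyNA(event)) abort("missing values in survival records")
  if (any(time <= 0)) abort("follow-up times must be positive")
  ut <- sort(unique(time))
  n <- length(time)
  n_risk <- vapply(ut, function(t) sum(time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(time == t & event), numeric(1))
  n_censor <- vapply(ut, function(t) sum(time == t & !event), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  # Greenwood: var(S) = S^2 * sum d / (n (n - d))
  gw <- cumsum(ifelse(n_risk > n_event, n_event / (n_risk * (n_risk - n_event)), 0))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (conf_type == "plain") {
    lower <- pmax(surv - z * se, 0)
    upper <- pmin(surv + z * se, 1)
  } else {
    # on log(-log S); undefined at S in {0, 1}
    ok <- surv > 0 & surv < 1
    lower <- upper <- rep(NA_real_, length(surv))
    se_ll <- ifelse(ok, sqrt(gw) / abs(log(surv)), NA_real_)
    lower[ok] <- surv[ok]^exp(z * se_ll[ok])
    upper[ok] <- surv[ok]^exp(-z * se_ll[ok])
    lower[!ok] <- surv[!ok]; upper[!ok] <- surv[!ok]
  }
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv, std_err = se,
                    lower = lower, upper = upper)
  class(out) <- c("km_fit", "data.frame")
  attr(out, "n") <- n
  attr(out, "conf_type") <- conf_type
  out
}

#' Survival probability at a given time from a `km_fit`
#'
#' @param fit A [km_estimate()] result.
#' @param t Time point.
#' @return List with `surv`, `lower`, `upper` at the last event-or-censor
#'   time not exceeding `t` (1 before the first).
#' @export
km_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  i <- findInterval(t, fit$time)
  if (i == 0L) return(list(surv = 1, lower = 1, upper = 1))
  list(surv = fit$surv[i], lower = fit$lower[i], upper = fit$upper[i])
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected chi-square with one degree of freedom
#' over the pooled distinct event times.  When neither group has an event,
#' or the variance degenerates (no time with both groups at risk), p = 1
#' with an explanatory note.
#'
#' @param time_a,event_a,time_b,event_b Survival records per group, as in
#'   [km_estimate()].
#' @return A `uvm_test` with the chi-square statistic.
#' @export
logrank <- function(time_a, event_a, time_b, event_b) {
  if (length(time_a) < 1L || length(time_b) < 1L) abort("both groups must be non-empty")
  time <- c(time_a, time_b)
  event <- as.logical(c(event_a, event_b))
  grp <- rep(c(1L, 2L), c(length(time_a), length(time_b)))
  if (any(time <= 0)) abort("follow-up times must be positive")
  if (!any(event)) {
    return(new_test_result("log-rank", 0, 1, c(length(time_a), length(time_b)),
                           "no events in either group"))
  }
  ts <- sort(unique(time[event]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at <- time >= t
    n <- sum(at); n1 <- sum(at & grp == 1L)
    d <- sum(time == t & event); d1 <- sum(time == t & event & grp == 1L)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    return(new_test_result("log-rank", 0, 1, c(length(time_a), length(time_b)),
                           "degenerate variance (groups never concurrently at risk)"))
  }
  chisq <- (O1 - E1)^2 / V
  p <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
  new_test_result("log-rank", chisq, p, c(length(time_a), length(time_b)))
}

#' Fold change and percent reduction between two group means
#'
#' `fold = mean_a / mean_b` and `percent_reduction = 100 (1 - mean_a /
#' mean_b)`; the rounded values follow the reporting precision (one decimal
#' for folds, whole percent for reductions).
#'
#' @param mean_a,mean_b Group means; `mean_b` is the reference and must be
#'   positive.
#' @return List with `fold`, `percent_reduction` and their `*_rounded`
#'   companions.
#' @examples
#' effect_summaries(13.1, 4.9)$fold_rounded   # 2.7
#' @export
effect_summaries <- function(mean_a, mean_b) {
  if (!is.numeric(mean_b) || mean_b <= 0) abort("reference mean must be positive")
  fold <- mean_a / mean_b
  red <- 100 * (1 - mean_a / mean_b)
  list(fold = fold, fold_rounded = round(fold, 1),
       percent_reduction = red, percent_reduction_rounded = round(red))
}
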