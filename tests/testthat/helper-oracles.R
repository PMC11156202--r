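# Independent oracles, kept deliberately naive: brute-force enumerations and
# closed forms that never share code with the implementations they check.

# Mann-Whitney U by direct pair counting (+1/2 per tied pair)
mw_u_brute <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# exact two-sided permutation p-value for the U statistic (|U - mu| ordering)
perm_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  mu <- n1 * length(y) / 2
  u_obs <- mw_u_brute(x, y)
  splits <- utils::combn(length(pooled), n1)
  us <- apply(splits, 2, function(idx) mw_u_brute(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

# best threshold by brute force over all candidate cuts between sorted values
otsu_brute <- function(x) {
  v <- sort(unique(as.numeric(x)))
  cuts <- (v[-1] + v[-length(v)]) / 2
  bcv <- vapply(cuts, function(ct) {
    lo <- x[x <= ct]; hi <- x[x > ct]
    w0 <- length(lo) / length(x)
    w0 * (1 - w0) * (mean(hi) - mean(lo))^2
  }, numeric(1))
  cuts[which.max(bcv)]
}

# empirical survival function (no censoring): P(T > t)
empirical_surv <- function(times, t) mean(times > t)

# a small synthetic field_quant for aggregation tests
fq <- function(analyzed, positive, id = "f") {
  structure(list(field_id = id, analyzed_px = analyzed, positive_px = positive,
                 threshold_used = NA_real_, threshold_method = "fixed"),
            class = "field_quant")
}
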