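#' Grouped descriptive and test report
#'
#' Builds the study-style summary table: for every numeric variable, the
#' per-group mean, SD, median, min and max with a Mann-Whitney p-value; for
#' every categorical variable, per-group counts and percentages with a
#' two-sided Fisher exact p-value (2x2 tables; larger tables are summarised
#' without a test).  Missing values are excluded pairwise and footnoted via
#' the `n_missing` column.  Tests are computed only when the grouping
#' factor has exactly two levels.
#'
#' @param records Data frame of patient records.
#' @param grouping Name of the grouping column in `records`.
#' @param numeric_cols,categorical_cols Character vectors of columns to
#'   summarise; by default every remaining numeric / non-numeric column.
#' @param continuity Continuity-correction mode for [mann_whitney_u()].
#' @return A `cohort_report`: list of data frames `numeric`, `categorical`,
#'   `tests`.
#' @export
build_report <- function(records, grouping,
                         numeric_cols = NULL, categorical_cols = NULL,
                         continuity = "auto") {
  if (!is.data.frame(records)) abort("`records` must be a data frame")
  if (!grouping %in% names(records)) abort("grouping column '%s' not found", grouping)
  g <- factor(records[[grouping]])
  if (nlevels(g) < 2L) abort("grouping needs at least two levels")
  rest <- setdiff(names(records), grouping)
  if (is.null(numeric_cols)) {
    numeric_cols <- rest[vapply(records[rest], is.numeric, logical(1))]
  }
  if (is.null(categorical_cols)) {
    categorical_cols <- setdiff(rest, numeric_cols)
    categorical_cols <- categorical_cols[vapply(records[categorical_cols], function(x) {
      is.character(x) || is.factor(x) || is.logical(x)
    }, logical(1))]
  }
  bad <- setdiff(c(numeric_cols, categorical_cols), names(records))
  if (length(bad)) abort("unknown column(s): %s", paste(bad, collapse = ", "))
  two_groups <- nlevels(g) == 2L
  lv <- levels(g)

  num_rows <- list(); cat_rows <- list(); test_rows <- list()
  for (v in numeric_cols) {
    x <- records[[v]]
    if (!is.numeric(x)) abort("column '%s' declared numeric but is %s", v, class(x)[1])
    for (l in lv) {
      xi <- x[g == l]
      ok <- xi[!is.na(xi)]
      num_rows[[length(num_rows) + 1L]] <- data.frame(
        variable = v, group = l, n = length(ok), n_missing = sum(is.na(xi)),
        mean = if (length(ok)) mean(ok) else NA_real_,
        sd = if (length(ok) > 1) stats::sd(ok) else NA_real_,
        median = if (length(ok)) stats::median(ok) else NA_real_,
        min = if (length(ok)) min(ok) else NA_real_,
        max = if (length(ok)) max(ok) else NA_real_,
        stringsAsFactors = FALSE)
    }
    if (two_groups) {
      x1 <- x[g == lv[1] & !is.na(x)]; x2 <- x[g == lv[2] & !is.na(x)]
      tr <- if (length(x1) && length(x2)) {
        mann_whitney_u(x1, x2, continuity = continuity)
      } else new_test_result("mann-whitney-u", NA_real_, NA_real_, c(length(x1), length(x2)),
                             "empty group after missing-data exclusion")
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        variable = v, test = tr$test, statistic = tr$statistic,
        p_value = tr$p_value, note = tr$note, stringsAsFactors = FALSE)
    }
  }
  for (v in categorical_cols) {
    x <- factor(records[[v]])
    tab <- table(x, g)
    for (l in lv) for (lev in rownames(tab)) {
      cat_rows[[length(cat_rows) + 1L]] <- data.frame(
        variable = v, level = lev, group = l, count = tab[lev, l],
        pct = 100 * tab[lev, l] / max(sum(tab[, l]), 1L),
        stringsAsFactors = FALSE)
    }
    if (two_groups) {
      tr <- if (nrow(tab) == 2L && all(colSums(tab) > 0)) {
        fisher_exact(unclass(tab)[, , drop = FALSE])
      } else {
        new_test_result("fisher-exact", NA_real_, NA_real_, sum(tab),
                        sprintf("%d levels: only 2x2 tables are tested", nrow(tab)))
      }
      test_rows[[length(test_rows) + 1L]] <- data.frame(
        variable = v, test = tr$test, statistic = tr$statistic,
        p_value = tr$p_value, note = tr$note, stringsAsFactors = FALSE)
    }
  }
  structure(list(
    numeric = if (length(num_rows)) do.call(rbind, num_rows) else NULL,
    categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL,
    tests = if (length(test_rows)) do.call(rbind, test_rows) else NULL,
    grouping = grouping, groups = lv), class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> grouped by '%s' (%s)\n", x$grouping,
              paste(x$groups, collapse = " / ")))
  if (!is.null(x$numeric)) {
    cat("numeric variables:\n"); print(x$numeric, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$categorical)) {
    cat("categorical variables:\n"); print(x$categorical, digits = 3, row.names = FALSE)
  }
  if (!is.null(x$tests)) {
    cat("tests:\n"); print(x$tests, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Metastasis-free survival stratified by a factor
#'
#' Runs [km_estimate()] per stratum and the two-group [logrank()] test.
#' The default stratification in the pipeline is TUNEL percentage above
#' versus below the cohort median.
#'
#' @param time,event Survival records (months from primary diagnosis;
#'   event = metastasis observed).
#' @param strata Factor with exactly two levels.
#' @param conf_type Interval construction, see [km_estimate()].
#' @return List with `curves` (named list of `km_fit`), `logrank`
#'   (`uvm_test`), and `table` (long data frame of curve points with an
#'   added `stratum` column).
#' @export
km_by_group <- function(time, event, strata, conf_type = "plain") {
  strata <- factor(strata)
  if (nlevels(strata) != 2L) abort("exactly two strata are required")
  lv <- levels(strata)
  curves <- lapply(lv, function(l) {
    km_estimate(time[strata == l], event[strata == l], conf_type = conf_type)
  })
  names(curves) <- lv
  lr <- logrank(time[strata == lv[1]], event[strata == lv[1]],
                time[strata == lv[2]], event[strata == lv[2]])
  tab <- do.call(rbind, lapply(lv, function(l) {
    cbind(stratum = l, as.data.frame(curves[[l]]))
  }))
  list(curves = curves, logrank = lr, table = tab)
}
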