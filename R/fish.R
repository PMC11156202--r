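#' Chromosome 3 status from per-cell FISH signal counts
#'
#' Monosomy 3 — loss of one chromosome 3 copy — is the dominant cytogenetic
#' risk factor for uveal melanoma metastasis.  From centromeric FISH signal
#' counts in marker-positive tumor cells, two per-tumor statistics are
#' computed: the percentage of cells showing exactly one signal
#' (`pct_monosomy`) and the chromosome 3 index (total signals per nucleus,
#' about 2 in diploid tissue).  Because no absolute cutoff is established,
#' both are binarised at their *cohort* median (computed per clinic, since
#' storage time affects hybridisation quality), concordant scores decide the
#' call directly, and discordant ("mixed") tumors are resolved by a
#' stringent 40 percent cutoff or an index at least one SD below the
#' full-cohort mean.
#'
#' @name fish-chr3
NULL

#' Per-tumor chromosome 3 profile
#'
#' @param counts Integer vector of per-cell chromosome 3 signal counts
#'   (marker-positive, non-necrotic cells only).
#' @param tumor_id,cohort_id Labels; the cohort identifies the clinic whose
#'   median is used for binarisation.
#' @param min_cells Minimum evaluated nuclei before a low-count *warning*
#'   (not an error — one small tumor in the study had only 88 nuclei).
#' @param drop_zero_signal Exclude 0-signal nuclei (hybridisation failures)
#'   from both statistics?  Off by default: all evaluated nuclei count in
#'   the denominators.
#' @return A `chr3_profile`: list with `tumor_id`, `cohort_id`,
#'   `pct_monosomy`, `chr3_index`, `n_cells`.
#' @examples
#' profile_tumor(rep(2, 100), "T1", min_cells = 50)   # pure disomy
#' @export
profile_tumor <- function(counts, tumor_id = "tumor", cohort_id = "cohort",
                          min_cells = 203L, drop_zero_signal = FALSE) {
  if (length(counts) < 1L) abort("tumor '%s': empty cell list", tumor_id)
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0) || any(counts != floor(counts))) {
    abort("tumor '%s': signal counts must be non-negative integers", tumor_id)
  }
  if (drop_zero_signal) {
    counts <- counts[counts > 0]
    if (length(counts) < 1L) abort("tumor '%s': no cells left after dropping 0-signal nuclei", tumor_id)
  }
  n <- length(counts)
  if (n < min_cells) {
    warning(sprintf("tumor '%s': only %d cells evaluated (minimum %d)",
                    tumor_id, n, min_cells), call. = FALSE)
  }
  structure(list(tumor_id = as.character(tumor_id),
                 cohort_id = as.character(cohort_id),
                 pct_monosomy = 100 * mean(counts == 1),
                 chr3_index = sum(counts) / n,
                 n_cells = n),
            class = "chr3_profile")
}

profiles_to_df <- function(profiles) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "chr3_profile")))
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(tumor_id = p$tumor_id, cohort_id = p$cohort_id,
               pct_monosomy = p$pct_monosomy, chr3_index = p$chr3_index,
               n_cells = p$n_cells, stringsAsFactors = FALSE)
  }))
}

#' Binarise profiles at their cohort medians
#'
#' Within each cohort, `score_pct = 1` iff `pct_monosomy >= median(pct)` and
#' `score_index = 1` iff `chr3_index <= median(index)` (ties at the median
#' follow these inequalities exactly).  Tumors scoring 1 on both are
#' `monosomy`, 0 on both `disomy`, otherwise `mixed`.
#'
#' @param profiles List of `chr3_profile` objects (or a data frame with
#'   columns `tumor_id`, `cohort_id`, `pct_monosomy`, `chr3_index`).
#' @return Data frame adding `median_pct`, `median_index`, `score_pct`,
#'   `score_index`, `combined_state`.
#' @export
cohort_binarize <- function(profiles) {
  df <- if (is.data.frame(profiles)) profiles else profiles_to_df(profiles)
  need <- c("tumor_id", "cohort_id", "pct_monosomy", "chr3_index")
  if (!all(need %in% names(df))) {
    abort("profiles need columns: %s", paste(need, collapse = ", "))
  }
  sizes <- table(df$cohort_id)
  if (any(sizes < 2L)) {
    abort("cohort(s) with a single tumor (%s): a median split is undefined",
          paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  med_pct <- stats::ave(df$pct_monosomy, df$cohort_id, FUN = stats::median)
  med_idx <- stats::ave(df$chr3_index, df$cohort_id, FUN = stats::median)
  df$median_pct <- med_pct
  df$median_index <- med_idx
  df$score_pct <- as.integer(df$pct_monosomy >= med_pct)
  df$score_index <- as.integer(df$chr3_index <= med_idx)
  df$combined_state <- ifelse(df$score_pct + df$score_index == 2L, "monosomy",
                       ifelse(df$score_pct + df$score_index == 0L, "disomy", "mixed"))
  df
}

#' Resolve one tumor's final chromosome 3 call
#'
#' Concordant scores decide directly.  A mixed tumor is called `monosomy3`
#' if its `pct_monosomy` exceeds the stringent cutoff (strictly greater
#' than 40 percent by default) or its index lies at least `sd_mult` SDs
#' below the reference-cohort mean index (inclusive); otherwise it defaults
#' to `disomy3`.
#'
#' @param combined_state `"disomy"`, `"monosomy"` or `"mixed"`.
#' @param pct_monosomy,chr3_index The tumor's profile values.
#' @param cohort_index_mean,cohort_index_sd Mean and SD of `chr3_index`
#'   over the reference set (the entire combined cohort by default
#'   upstream).
#' @param pct_cutoff Percent-monosomy cutoff for mixed tumors (default 40,
#'   strict inequality).
#' @param sd_mult SD multiplier for the low-index rescue rule (default 1).
#' @return A `chr3_call`: list with `final` (`"disomy3"`/`"monosomy3"`) and
#'   `reason` (one of `both-scores`, `pct>cutoff`, `index<=mean-sd`,
#'   `mixed-default-disomy`).
#' @export
resolve_call <- function(combined_state, pct_monosomy, chr3_index,
                         cohort_index_mean, cohort_index_sd,
                         pct_cutoff = 40, sd_mult = 1) {
  combined_state <- match.arg(combined_state, c("disomy", "monosomy", "mixed"))
  if (combined_state == "monosomy") {
    final <- "monosomy3"; reason <- "both-scores"
  } else if (combined_state == "disomy") {
    final <- "disomy3"; reason <- "both-scores"
  } else if (pct_monosomy > pct_cutoff) {
    final <- "monosomy3"; reason <- sprintf("pct>%g", pct_cutoff)
  } else if (chr3_index <= cohort_index_mean - sd_mult * cohort_index_sd) {
    final <- "monosomy3"; reason <- "index<=mean-sd"
  } else {
    final <- "disomy3"; reason <- "mixed-default-disomy"
  }
  structure(list(final = final, reason = reason), class = "chr3_call")
}

#' Classify chromosome 3 status for a whole cohort table
#'
#' Full pipeline: per-tumor profiles, per-cohort median binarisation, and
#' mixed-case resolution against the reference set (all profiles by
#' default, matching a full-cohort mean/SD).
#'
#' @param cells Data frame with columns `tumor_id`, `cohort_id`,
#'   `n_signals`, and optionally `marker_positive` (cells failing the
#'   marker filter are dropped).
#' @param min_cells,drop_zero_signal Passed to [profile_tumor()].
#' @param pct_cutoff,sd_mult Passed to [resolve_call()].
#' @param reference Tumor ids forming the mean/SD reference set, or `NULL`
#'   for all tumors.
#' @return Data frame: one row per tumor with profile values, scores,
#'   `combined_state`, `final_call` and `reason`.
#' @export
chr3_classify <- function(cells, min_cells = 203L, drop_zero_signal = FALSE,
                          pct_cutoff = 40, sd_mult = 1, reference = NULL) {
  need <- c("tumor_id", "cohort_id", "n_signals")
  if (!is.data.frame(cells) || !all(need %in% names(cells))) {
    abort("`cells` needs columns: %s", paste(need, collapse = ", "))
  }
  if ("marker_positive" %in% names(cells)) {
    cells <- cells[as.logical(cells$marker_positive), , drop = FALSE]
  }
  if (nrow(cells) == 0L) abort("no marker-positive cells")
  split_cells <- split(cells, cells$tumor_id)
  profiles <- lapply(split_cells, function(d) {
    profile_tumor(d$n_signals, tumor_id = d$tumor_id[1], cohort_id = d$cohort_id[1],
                  min_cells = min_cells, drop_zero_signal = drop_zero_signal)
  })
  scored <- cohort_binarize(profiles)
  ref <- if (is.null(reference)) scored else scored[scored$tumor_id %in% reference, , drop = FALSE]
  if (nrow(ref) < 2L) abort("reference set needs at least 2 tumors")
  mu <- mean(ref$chr3_index)
  sdv <- stats::sd(ref$chr3_index)
  calls <- lapply(seq_len(nrow(scored)), function(i) {
    resolve_call(scored$combined_state[i], scored$pct_monosomy[i],
                 scored$chr3_index[i], mu, sdv,
                 pct_cutoff = pct_cutoff, sd_mult = sd_mult)
  })
  scored$final_call <- vapply(calls, `[[`, character(1), "final")
  scored$reason <- vapply(calls, `[[`, character(1), "reason")
  attr(scored, "reference_index_mean") <- mu
  attr(scored, "reference_index_sd") <- sdv
  scored
}
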