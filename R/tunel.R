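#' TUNEL-positive area quantification
#'
#' The TUNEL concentration plane from colour deconvolution is thresholded
#' into a positive mask, exclusion regions (vessels) are removed, and a
#' tumor's DNA-damage burden is reported as the *pooled* positive area
#' fraction: total positive pixels over total analysed pixels across all
#' fields, not the mean of per-field percentages.  Necrotic areas are
#' deliberately analysed, not masked out.
#'
#' @name tunel-area
NULL

#' Threshold a TUNEL concentration plane
#'
#' Negative concentrations are clipped to zero first.  In `automatic` mode
#' the threshold maximises the between-class variance of a 256-bin histogram
#' (Otsu's criterion), which assumes a bimodal positive/background split; a
#' constant plane is rejected with instructions to use `fixed` mode.
#' Pixels strictly above the threshold are positive.
#'
#' @param plane Numeric matrix of concentrations for one stain.
#' @param method `"automatic"` (between-class variance maximisation) or
#'   `"fixed"`.
#' @param fixed_value Threshold concentration, required for `method = "fixed"`.
#' @param nbins Histogram resolution for automatic mode.
#' @return Logical matrix of the same dimensions; attribute `threshold`
#'   records the value used, `method` the mode.
#' @examples
#' pl <- matrix(c(rep(0.1, 60), rep(1, 40)), 10, 10)
#' mean(threshold_tunel(pl))  # 0.4
#' @export
threshold_tunel <- function(plane, method = c("automatic", "fixed"),
                            fixed_value = NULL, nbins = 256L) {
  method <- match.arg(method)
  if (!is.matrix(plane) || !is.numeric(plane)) abort("`plane` must be a numeric matrix")
  if (anyNA(plane) || any(!is.finite(plane))) abort("`plane` contains non-finite values")
  clipped <- pmax(plane, 0)
  if (method == "fixed") {
    if (is.null(fixed_value) || !is.numeric(fixed_value) || length(fixed_value) != 1L) {
      abort("fixed mode requires a single numeric `fixed_value`")
    }
    thr <- fixed_value
  } else {
    rng <- range(clipped)
    if (diff(rng) == 0) {
      abort(paste("constant concentration plane: the histogram is degenerate,",
                  "use method = 'fixed' with an explicit threshold"))
    }
    thr <- otsu_threshold(clipped, nbins = nbins)
  }
  mask <- clipped > thr
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

# Between-class variance maximisation on a fixed-width histogram.
# Returns the upper edge of the best split bin (midpoint of the best run
# when several adjacent splits are equivalent, e.g. an empty gap between
# two well-separated modes).
otsu_threshold <- function(x, nbins = 256L) {
  rng <- range(x)
  edges <- seq(rng[1], rng[2], length.out = nbins + 1L)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins)
  p <- counts / sum(counts)
  mids <- (edges[-1] + edges[-(nbins + 1L)]) / 2
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nbins]
  w1 <- 1 - w0
  # between-class variance for a split after each bin k (k = 1..nbins-1)
  k <- seq_len(nbins - 1L)
  num <- (mu_t * w0[k] - mu0[k])^2
  den <- w0[k] * w1[k]
  bcv <- ifelse(den > 0, num / den, -Inf)
  best <- which(bcv >= max(bcv) - 1e-12 * max(abs(bcv), 1))
  # ties form a contiguous empty-gap run; split in its middle
  mean(edges[range(best) + 1L])
}

#' Count analysed and positive pixels in one field
#'
#' The analysed region is the tumor region minus the exclusion mask
#' (vascular areas); positives are counted only inside it.  No necrosis
#' mask is subtracted: necrotic areas stay in the quantification.
#'
#' @param positive Logical matrix, TUNEL-positive pixels
#'   (from [threshold_tunel()]).
#' @param tumor_region Logical matrix delimiting tumor tissue, or `NULL`
#'   for the whole field.
#' @param exclusion Logical matrix of pixels to drop (vessels), or `NULL`.
#' @param field_id Field label.
#' @return A `field_quant`: list with `field_id`, `analyzed_px`,
#'   `positive_px`, `threshold_used`, `threshold_method`.
#' @export
quantify_field <- function(positive, tumor_region = NULL, exclusion = NULL,
                           field_id = "field") {
  dm <- dim(positive)
  if (is.null(tumor_region)) tumor_region <- matrix(TRUE, dm[1], dm[2])
  if (is.null(exclusion)) exclusion <- matrix(FALSE, dm[1], dm[2])
  for (m in list(tumor_region, exclusion)) {
    if (!identical(dim(m), dm)) abort("masks are not co-registered (dimension mismatch)")
  }
  analyzed <- tumor_region & !exclusion
  structure(list(field_id = as.character(field_id),
                 analyzed_px = sum(analyzed),
                 positive_px = sum(positive & analyzed),
                 threshold_used = attr(positive, "threshold"),
                 threshold_method = attr(positive, "method")),
            class = "field_quant")
}

#' Pool fields into a per-tumor TUNEL percentage
#'
#' `tunel_pct = 100 * sum(positive_px) / sum(analyzed_px)` — the pooled
#' ratio, which is invariant to how fields are split and differs from the
#' mean of per-field percentages whenever field sizes differ.
#'
#' @param fields List of `field_quant` objects.
#' @param tumor_id Tumor label.
#' @return A `tumor_quant`: list with `tumor_id`, `n_fields`,
#'   `analyzed_px`, `positive_px`, `tunel_pct`, and the `fields`.
#' @export
aggregate_tumor <- function(fields, tumor_id = "tumor") {
  if (length(fields) < 1L) abort("at least one field is required")
  if (!all(vapply(fields, inherits, logical(1), "field_quant"))) {
    abort("`fields` must be a list of field_quant objects")
  }
  analyzed <- sum(vapply(fields, `[[`, numeric(1), "analyzed_px"))
  positive <- sum(vapply(fields, `[[`, numeric(1), "positive_px"))
  if (analyzed <= 0) abort("tumor '%s': no analyzable area in any field", tumor_id)
  structure(list(tumor_id = as.character(tumor_id),
                 n_fields = length(fields),
                 analyzed_px = analyzed,
                 positive_px = positive,
                 tunel_pct = 100 * positive / analyzed,
                 fields = fields),
            class = "tumor_quant")
}

#' @export
print.tumor_quant <- function(x, ...) {
  cat(sprintf("<tumor_quant '%s'> %d field(s), %d / %d px positive, TUNEL %.1f%%\n",
              x$tumor_id, x$n_fields, x$positive_px, x$analyzed_px, x$tunel_pct))
  invisible(x)
}

#' Select representative fields for quantification
#'
#' If more fields are available than the target, a seeded uniform sample
#' without replacement of exactly `target_n` is drawn; smaller tumors are
#' quantified entirely (all fields kept).  The default target of 20 fields
#' matches the acquisition protocol.
#'
#' @param available List (or vector) of field identifiers/images.
#' @param target_n Number of fields to keep.
#' @param seed Integer seed making the selection reproducible.
#' @return The selected subset, in sampled order; attribute `selected`
#'   holds the chosen indices.
#' @export
sample_fields <- function(available, target_n = 20L, seed = 1L) {
  n <- length(available)
  if (n < 1L) abort("no fields available")
  if (!is.numeric(target_n) || target_n < 1L) abort("`target_n` must be >= 1")
  idx <- if (n <= target_n) seq_len(n) else with_seed(seed, sample.int(n, target_n))
  out <- available[idx]
  attr(out, "selected") <- idx
  out
}
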