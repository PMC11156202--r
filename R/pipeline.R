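#' End-to-end image quantification
#'
#' Chains the stages for one field and for one tumor: RGB to optical
#' density, colour deconvolution, thresholding of the TUNEL plane, mask
#' arithmetic, and pooled aggregation.
#'
#' @name pipeline
NULL

#' Quantify one field image
#'
#' In automatic mode the Otsu threshold is additionally floored at
#' `threshold_floor` concentration units: a field with (nearly) no positive
#' signal has a unimodal concentration histogram, where an unconstrained
#' between-class split would label acquisition noise as positive.  A
#' degenerate (constant) plane falls back to the floor as a fixed
#' threshold.  Set `threshold_floor = 0` for the bare Otsu behaviour.
#'
#' @param image H x W x 3 RGB intensity array.
#' @param m Stain matrix.
#' @param i0,epsilon Optical density transform parameters, see
#'   [rgb_to_od()].
#' @param threshold_mode `"automatic"` or `"fixed"`.
#' @param threshold_value Concentration threshold for fixed mode.
#' @param threshold_floor Lower bound on the automatic threshold.
#' @param tumor_region,exclusion Optional logical masks, see
#'   [quantify_field()].
#' @param field_id Field label.
#' @return A `field_quant` with extra element `negative_fraction` (the
#'   deconvolution clipping diagnostic).
#' @export
quantify_tunel_field <- function(image, m = stain_matrix_default(),
                                 i0 = 255, epsilon = 1,
                                 threshold_mode = c("automatic", "fixed"),
                                 threshold_value = NULL,
                                 threshold_floor = 0.1,
                                 tumor_region = NULL, exclusion = NULL,
                                 field_id = "field") {
  threshold_mode <- match.arg(threshold_mode)
  od <- rgb_to_od(image, i0 = i0, epsilon = epsilon)
  conc <- deconvolve(od, m)
  plane <- conc[, , "tunel"]
  mask <- if (threshold_mode == "fixed") {
    threshold_tunel(plane, "fixed", fixed_value = threshold_value)
  } else {
    mk <- tryCatch(threshold_tunel(plane, "automatic"),
                   error = function(e) NULL)
    if (is.null(mk) || attr(mk, "threshold") < threshold_floor) {
      mk <- threshold_tunel(plane, "fixed", fixed_value = threshold_floor)
      attr(mk, "method") <- "automatic-floored"
    }
    mk
  }
  fq <- quantify_field(mask, tumor_region = tumor_region,
                       exclusion = exclusion, field_id = field_id)
  fq$negative_fraction <- attr(conc, "negative_fraction")
  fq
}

#' Quantify a tumor from a set of field images
#'
#' Selects up to `target_fields` fields (seeded, see [sample_fields()]),
#' quantifies each with [quantify_tunel_field()], and pools them.
#'
#' @param images List of H x W x 3 arrays (one per available field).
#' @param tumor_id Tumor label.
#' @param target_fields Number of representative fields to analyse.
#' @param seed Field-selection seed.
#' @param masks Optional list of per-field lists with elements
#'   `tumor_region` and/or `exclusion` (same order as `images`).
#' @param ... Passed to [quantify_tunel_field()].
#' @return A `tumor_quant`.
#' @export
quantify_tunel_tumor <- function(images, tumor_id = "tumor",
                                 target_fields = 20L, seed = 1L,
                                 masks = NULL, ...) {
  if (length(images) < 1L) abort("no field images supplied")
  idx <- attr(sample_fields(seq_along(images), target_n = target_fields, seed = seed),
              "selected")
  fields <- lapply(idx, function(i) {
    mk <- if (is.null(masks)) list() else masks[[i]]
    quantify_tunel_field(images[[i]],
                         tumor_region = mk$tumor_region,
                         exclusion = mk$exclusion,
                         field_id = sprintf("%s_f%02d", tumor_id, i), ...)
  })
  aggregate_tumor(fields, tumor_id = tumor_id)
}

#' Run one full synthetic study replicate
#'
#' The complete loop the package automates, on generated data: simulate a
#' clinical cohort (default group sizes 31/8/15 and TUNEL moments), render
#' one synthetic stained field per tumor with the patient's true TUNEL
#' fraction, quantify it through deconvolution and thresholding, classify
#' chromosome 3 status from simulated FISH counts planted to match the
#' cohort's calls, and build the grouped report.  Image size is kept small
#' by default so that replicated power checks stay cheap; the estimate's
#' accuracy at 64 px fields is still well inside the group differences
#' being tested.
#'
#' @param seed Integer seed driving every stage.
#' @param image_size Field edge length in pixels.
#' @param n_cells FISH nuclei per tumor.
#' @return List: `cohort` (records with added `tunel_est`), `ordering_ok`
#'   (are the estimated group means ordered fSRT > sdSRT > noRT?), `mw_p`
#'   (Mann-Whitney p, estimated TUNEL pct fSRT vs noRT), `chr3_accuracy`
#'   (fraction of classifier calls matching the planted labels), `report`
#'   (the SRT-vs-noRT `cohort_report`).
#' @export
run_synthetic_study <- function(seed = 1L, image_size = 64L, n_cells = 203L) {
  cohort <- generate_clinical_cohort(seed = seed)
  est <- vapply(seq_len(nrow(cohort)), function(i) {
    sim <- generate_tunel_image(image_size, image_size,
                                true_positive_fraction = cohort$tunel_pct[i] / 100,
                                seed = seed + i * 101L)
    fq <- quantify_tunel_field(sim$image)
    100 * fq$positive_px / fq$analyzed_px
  }, numeric(1))
  cohort$tunel_est <- est
  means <- tapply(est, cohort$rt_group, mean)
  ordering_ok <- means[["fSRT"]] > means[["sdSRT"]] && means[["sdSRT"]] > means[["noRT"]]
  mw <- mann_whitney_u(est[cohort$rt_group == "fSRT"], est[cohort$rt_group == "noRT"])
  fish <- generate_fish_counts(nrow(cohort),
                               ifelse(cohort$chr3_call == "monosomy3", 0.8, 0.05),
                               dropout_p = 0.02, n_cells = n_cells,
                               cohort_id = cohort$rt_group, tumor_ids = cohort$id,
                               seed = seed + 7L)
  calls <- suppressWarnings(chr3_classify(fish, min_cells = n_cells))
  acc <- mean(calls$final_call[match(cohort$id, calls$tumor_id)] == cohort$chr3_call)
  cohort$rt_any <- ifelse(cohort$rt_group == "noRT", "noRT", "SRT")
  report <- build_report(cohort[setdiff(names(cohort), c("id", "rt_group"))],
                         grouping = "rt_any")
  list(cohort = cohort, ordering_ok = ordering_ok, mw_p = mw$p_value,
       chr3_accuracy = acc, report = report)
}
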