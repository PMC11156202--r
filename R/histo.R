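#' Histopathological marker quantification
#'
#' Vessel area fraction from a vWF-positive mask, macrophage density from
#' CD68 cell counts, and the categorical morphology and necrosis rules.
#' Mitotic figures are identified manually on H&E sections; this module
#' only books the supplied per-40-high-power-field count.
#'
#' @name histo-markers
NULL

#' Vessel area as percent of tumor area
#'
#' `100 * |vwf & tumor| / |tumor|`; anything outside the tumor mask (normal
#' choroid) is ignored.
#'
#' @param vwf_mask Logical matrix of vWF-positive pixels.
#' @param tumor_mask Logical matrix delimiting the tumor body.
#' @return Percentage in `[0, 100]`.
#' @export
vessel_area_pct <- function(vwf_mask, tumor_mask) {
  if (!identical(dim(vwf_mask), dim(tumor_mask))) {
    abort("masks are not co-registered (dimension mismatch)")
  }
  n_tumor <- sum(tumor_mask)
  if (n_tumor == 0) abort("empty tumor mask")
  100 * sum(vwf_mask & tumor_mask) / n_tumor
}

#' Macrophage density in cells per square millimetre
#'
#' @param n_cells Number of CD68-positive cells in the tumor.
#' @param tumor_area_px Tumor area in pixels.
#' @param um_per_px Pixel edge length in micrometres.
#' @return Cells per mm^2.
#' @examples
#' macrophage_density(33, 1e6, 1)   # 1 mm^2 -> 33 cells/mm^2
#' @export
macrophage_density <- function(n_cells, tumor_area_px, um_per_px) {
  if (!is.numeric(um_per_px) || um_per_px <= 0) abort("`um_per_px` must be positive")
  if (!is.numeric(tumor_area_px) || tumor_area_px <= 0) abort("tumor area must be positive")
  if (!is.numeric(n_cells) || n_cells < 0) abort("`n_cells` must be non-negative")
  area_mm2 <- tumor_area_px * um_per_px^2 / 1e6
  n_cells / area_mm2
}

#' Dominant-cell-type morphology category
#'
#' Strictly more than 90 percent epithelioid cells classifies as
#' `epithelioid`; strictly more than 90 percent spindle cells (epithelioid
#' fraction below 0.10) as `spindle`; everything else, boundaries included,
#' is `mixed`.
#'
#' @param epithelioid_fraction Proportion of epithelioid cells in `[0, 1]`.
#' @return `"epithelioid"`, `"spindle"` or `"mixed"`.
#' @export
classify_morphology <- function(epithelioid_fraction) {
  f <- epithelioid_fraction
  if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1) {
    abort("`epithelioid_fraction` must be a single value in [0, 1]")
  }
  if (f > 0.90) "epithelioid" else if (f < 0.10) "spindle" else "mixed"
}

#' Necrosis extent category
#'
#' Bins match the reporting convention: up to 10 percent inclusive is
#' `"0-10%"`, above 10 up to 33 is `">10-33%"`, above 33 is flagged
#' `"out-of-range"` (not observed in the study cohort).
#'
#' @param pct Necrotic percentage of tumor area, `>= 0`.
#' @return Category string.
#' @export
necrosis_category <- function(pct) {
  if (!is.numeric(pct) || length(pct) != 1L || is.na(pct) || pct < 0) {
    abort("`pct` must be a single non-negative percentage")
  }
  if (pct <= 10) "0-10%" else if (pct <= 33) ">10-33%" else "out-of-range"
}

#' Assemble a per-tumor marker record
#'
#' @param tumor_id Label.
#' @param vwf_area_pct,cd68_density Quantified marker values.
#' @param epithelioid_fraction Proportion used for the morphology rule.
#' @param necrosis_pct Necrotic percentage for binning.
#' @param mitotic_count Optional mitoses per 40 high-power fields (manual
#'   count, stored as-is).
#' @return One-row data frame mirroring the clinical-table marker columns.
#' @export
marker_record <- function(tumor_id, vwf_area_pct, cd68_density,
                          epithelioid_fraction, necrosis_pct,
                          mitotic_count = NA_integer_) {
  if (vwf_area_pct < 0 || vwf_area_pct > 100) abort("vWF area %% out of [0, 100]")
  if (cd68_density < 0) abort("CD68 density must be non-negative")
  data.frame(tumor_id = as.character(tumor_id),
             vwf_area_pct = vwf_area_pct,
             cd68_density = cd68_density,
             morphology = classify_morphology(epithelioid_fraction),
             necrosis_category = necrosis_category(necrosis_pct),
             mitotic_count = as.integer(mitotic_count),
             stringsAsFactors = FALSE)
}
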