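#' Stain absorbance vectors and colour deconvolution
#'
#' Brightfield histology obeys the Beer-Lambert law: each stain absorbs light
#' along a characteristic direction in RGB optical-density (OD) space.  An
#' image is converted to OD, and linear unmixing against a matrix of stain
#' absorbance vectors recovers one concentration plane per stain.  The
#' convention throughout is *stains as rows*: a pixel's OD row-vector equals
#' its concentration row-vector times the stain matrix, so concentrations are
#' recovered by multiplying OD by the matrix inverse on the right.
#'
#' @name stain-separation
NULL

#' Construct a stain absorbance vector
#'
#' @param components Numeric length-3 vector of non-negative absorbance
#'   weights for the red, green and blue channels.
#' @param name Label for the stain.
#' @return An object of class `stain_vector` with unit Euclidean norm
#'   components (the raw components are kept in attribute `raw`).
#' @examples
#' stain_vector(c(0.776, 0.501, 0.382), "tunel")
#' @export
stain_vector <- function(components, name = "stain") {
  components <- as.numeric(components)
  if (length(components) != 3L || anyNA(components) || any(!is.finite(components))) {
    abort("a stain vector needs 3 finite components (got %d)", length(components))
  }
  if (any(components < 0)) abort("stain '%s': absorbance components must be non-negative", name)
  nrm <- sqrt(sum(components^2))
  if (nrm == 0) abort("stain '%s': all components are zero", name)
  structure(components / nrm,
            raw = components, name = name, class = "stain_vector")
}

#' @export
print.stain_vector <- function(x, ...) {
  cat(sprintf("<stain_vector '%s'> R=%.4f G=%.4f B=%.4f (unit norm)\n",
              attr(x, "name"), x[1], x[2], x[3]))
  invisible(x)
}

#' Build a 3-stain deconvolution matrix
#'
#' Rows are the unit-normalised absorbance vectors in the fixed order
#' nuclei, TUNEL, pigmentation.  The inverse is computed once and cached;
#' a nearly rank-deficient matrix (condition number above `max_condition`)
#' is rejected because unmixing would amplify noise without bound.
#'
#' @param nuclei,tunel,pigment `stain_vector` objects or length-3 numeric
#'   vectors for the nuclear counterstain, the TUNEL chromogen and melanin
#'   pigmentation.
#' @param max_condition Largest acceptable 2-norm condition number.
#' @return An object of class `stain_matrix`: list with the normalised
#'   matrix `M` (stains x channels), its cached `inverse`, and `stains`.
#' @seealso [stain_matrix_default()] for the study's calibrated vectors.
#' @examples
#' m <- build_stain_matrix(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
#' m$M %*% m$inverse   # identity
#' @export
build_stain_matrix <- function(nuclei, tunel, pigment, max_condition = 1e6) {
  as_sv <- function(x, nm) if (inherits(x, "stain_vector")) x else stain_vector(x, nm)
  rows <- list(as_sv(nuclei, "nuclei"), as_sv(tunel, "tunel"), as_sv(pigment, "pigment"))
  M <- do.call(rbind, lapply(rows, as.numeric))
  rownames(M) <- c("nuclei", "tunel", "pigment")
  colnames(M) <- c("R", "G", "B")
  cond <- kappa(M, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition) {
    abort("stain matrix is singular or ill-conditioned (condition number %.3g > %.3g)",
          cond, max_condition)
  }
  structure(list(M = M, inverse = solve(M), condition = cond,
                 stains = rownames(M)),
            class = "stain_matrix")
}

#' The study's calibrated stain matrix
#'
#' The nine user-calibrated RGB absorbance components for the nuclear fast
#' red counterstain, the HRP-green TUNEL chromogen, and brown melanin
#' pigmentation in uveal melanoma sections:
#' nuclei (0.482, 0.719, 0.501), TUNEL (0.776, 0.501, 0.382),
#' pigmentation (0.446, 0.616, 0.649).
#'
#' @return A `stain_matrix`.
#' @export
stain_matrix_default <- function() {
  build_stain_matrix(nuclei  = c(0.482, 0.719, 0.501),
                     tunel   = c(0.776, 0.501, 0.382),
                     pigment = c(0.446, 0.616, 0.649))
}

#' @export
print.stain_matrix <- function(x, ...) {
  cat("<stain_matrix> rows = stains (unit norm), cols = RGB\n")
  print(round(x$M, 4))
  cat(sprintf("condition number: %.3f\n", x$condition))
  invisible(x)
}

#' Convert an RGB intensity image to optical density
#'
#' Applies the absorbance transform `OD = log10(i0 / max(I, epsilon))`
#' channel-wise.  Background pixels at intensity `i0` map to OD 0; the
#' transform is strictly decreasing in intensity, and `epsilon` guards the
#' logarithm against zero-intensity pixels.
#'
#' @param image Numeric H x W x 3 array of intensities in `[0, i0]`.
#' @param i0 Background (blank-field) intensity; 255 for 8-bit input.
#' @param epsilon Small positive intensity floor, in `(0, i0)`.
#' @return H x W x 3 array of optical densities (attribute `i0` records the
#'   transform's background intensity).
#' @export
rgb_to_od <- function(image, i0 = 255, epsilon = 1) {
  check_rgb_array(image)
  if (!is.numeric(i0) || length(i0) != 1L || !is.finite(i0) || i0 <= 0) {
    abort("`i0` must be a single positive intensity")
  }
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0 || epsilon >= i0) {
    abort("`epsilon` must lie in (0, i0)")
  }
  od <- log10(i0 / pmax(image, epsilon))
  od[od < 0] <- 0  # intensities above i0 (glare) carry no absorbance
  attr(od, "i0") <- i0
  od
}

#' Unmix an OD image into per-stain concentration planes
#'
#' Each pixel's OD row-vector is multiplied by the cached inverse of the
#' stain matrix.  Negative concentrations (OD outside the cone spanned by
#' the stain vectors, e.g. from noise) are *retained* so that composition
#' round-trips exactly; the fraction of negative entries is reported as a
#' diagnostic and clipping is deferred to thresholding.
#'
#' @param od H x W x 3 optical-density array (see [rgb_to_od()]).
#' @param m A `stain_matrix`.
#' @return H x W x 3 array of concentrations, third dimension ordered as
#'   `m$stains`; attribute `negative_fraction` gives the proportion of
#'   negative entries.
#' @export
deconvolve <- function(od, m) {
  check_rgb_array(od, what = "od")
  stopifnot(inherits(m, "stain_matrix"))
  dm <- dim(od)
  flat <- matrix(od, ncol = 3L)           # pixels x channels
  conc <- flat %*% m$inverse              # pixels x stains
  out <- array(conc, dim = dm)
  dimnames(out) <- list(NULL, NULL, m$stains)
  attr(out, "negative_fraction") <- mean(conc < 0)
  out
}

#' Compose an RGB image from stain concentration planes
#'
#' Forward Beer-Lambert synthesis: `I = i0 * 10^-(C %*% M)` per pixel,
#' clipped to `[0, i0]`.  Zero concentrations everywhere give a blank field
#' at intensity `i0`.  This is the exact inverse of
#' [rgb_to_od()] + [deconvolve()] when no clipping occurs, which the
#' synthetic generator and the round-trip tests rely on.
#'
#' @param conc H x W x 3 concentration array, stain order matching `m`.
#' @param m A `stain_matrix`.
#' @param i0 Background intensity of the synthesised image.
#' @param quantize Round intensities to integers (8-bit style acquisition)?
#' @return H x W x 3 intensity array in `[0, i0]`.
#' @export
compose <- function(conc, m, i0 = 255, quantize = FALSE) {
  check_rgb_array(conc, what = "concentration")
  stopifnot(inherits(m, "stain_matrix"))
  dm <- dim(conc)
  flat <- matrix(conc, ncol = 3L) %*% m$M     # pixels x channels (OD)
  img <- i0 * 10^(-flat)
  img[img < 0] <- 0
  img[img > i0] <- i0
  if (quantize) img <- round(img)
  array(img, dim = dm)
}

check_rgb_array <- function(x, what = "image") {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3] != 3L) {
    abort("%s must be an H x W x 3 numeric array", what)
  }
  if (dim(x)[1] < 1L || dim(x)[2] < 1L) abort("%s has zero extent", what)
  if (anyNA(x) || any(!is.finite(x))) abort("%s contains non-finite values", what)
  invisible(TRUE)
}
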