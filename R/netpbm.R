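#' NetPBM image input/output
#'
#' Field images and masks travel as NetPBM files: PPM (colour) for RGB
#' fields and PGM (greyscale) for masks, where any nonzero pixel is true.
#' Both the plain-text (`P3`/`P2`) and binary (`P6`/`P5`, 8-bit) variants
#' are supported; plain text is the default for writing so that fixtures
#' stay diff-able.  Pixel size in micrometres per pixel is never inferred
#' from a file — it is supplied through the run configuration.
#'
#' @name netpbm
NULL

#' Write an RGB image as PPM
#'
#' @param image H x W x 3 numeric array of intensities.
#' @param path Output file.
#' @param maxval Maximum intensity value declared in the header.
#' @param binary Write binary `P6` instead of plain `P3`?
#' @return `path`, invisibly.
#' @export
write_ppm <- function(image, path, maxval = 255L, binary = FALSE) {
  check_rgb_array(image)
  h <- dim(image)[1]; w <- dim(image)[2]
  px <- round(aperm(image, c(3, 2, 1)))    # channel-major, column-major -> row order
  px[px < 0] <- 0; px[px > maxval] <- maxval
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(c("P6", paste(w, h), as.character(maxval)), con)
    writeBin(as.integer(px), con, size = 1L)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P3", paste(w, h), as.character(maxval)), con)
    writeLines(paste(as.integer(px), collapse = " "), con)
  }
  invisible(path)
}

#' Write a logical mask as PGM
#'
#' @param mask Logical matrix; `TRUE` pixels are written as `maxval`.
#' @param path Output file.
#' @param maxval Intensity used for true pixels.
#' @param binary Write binary `P5` instead of plain `P2`?
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mask, path, maxval = 255L, binary = FALSE) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix")
  px <- t(mask) * maxval                   # row-major order
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(c("P5", paste(ncol(mask), nrow(mask)), as.character(maxval)), con)
    writeBin(as.integer(px), con, size = 1L)
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("P2", paste(ncol(mask), nrow(mask)), as.character(maxval)), con)
    writeLines(paste(as.integer(px), collapse = " "), con)
  }
  invisible(path)
}

# read header tokens (magic, width, height, maxval), skipping comments
.pnm_header <- function(con) {
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) abort("truncated NetPBM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "\n") break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  tokens
}

#' Read a PPM or PGM image
#'
#' @param path NetPBM file (`P2`, `P3`, `P5` or `P6`).
#' @return For colour input an H x W x 3 numeric array; for greyscale a
#'   logical matrix (nonzero = `TRUE`) with the raw values in attribute
#'   `values`.
#' @export
read_pnm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hd <- .pnm_header(con)
  magic <- hd[1]
  w <- as.integer(hd[2]); h <- as.integer(hd[3]); maxval <- as.integer(hd[4])
  nch <- if (magic %in% c("P3", "P6")) 3L else if (magic %in% c("P2", "P5")) 1L else
    abort("unsupported NetPBM magic '%s'", magic)
  n <- w * h * nch
  vals <- if (magic %in% c("P5", "P6")) {
    as.numeric(readBin(con, "integer", n = n, size = 1L, signed = FALSE))
  } else {
    v <- scan(con, what = numeric(), n = n, quiet = TRUE)
    if (length(v) < n) abort("truncated pixel data in '%s'", path)
    v
  }
  if (nch == 3L) {
    aperm(array(vals, dim = c(3L, w, h)), c(3, 2, 1))
  } else {
    raw <- t(matrix(vals, nrow = w, ncol = h))
    m <- raw != 0
    attr(m, "values") <- raw
    m
  }
}
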