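#' Run configuration
#'
#' A flat key-value configuration carrying every tunable of the pipeline.
#' All defaults equal the study's printed constants where the study prints
#' one (stain vectors, 20 target fields, 203 minimum cells, the 40 percent
#' mixed-case cutoff, one SD, alpha 0.05), so running with an untouched
#' configuration reproduces the published analysis choices.  The file
#' format is DCF (`key: value` lines) and round-trips losslessly.
#'
#' @param ... Named overrides of any default field.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    stain_nuclei = c(0.482, 0.719, 0.501),
    stain_tunel = c(0.776, 0.501, 0.382),
    stain_pigment = c(0.446, 0.616, 0.649),
    i0 = 255, epsilon = 1,
    threshold_mode = "automatic", threshold_value = NA_real_,
    threshold_floor = 0.1,
    target_fields = 20L, field_seed = 1L,
    min_cells = 203L, pct_cutoff = 40, sd_mult = 1,
    continuity = "auto", alpha = 0.05,
    um_per_px = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Write a run configuration to a DCF file
#'
#' @param cfg A `run_config`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  flat <- vapply(cfg, function(v) paste(format(v, digits = 17), collapse = " "),
                 character(1))
  write.dcf(matrix(flat, nrow = 1, dimnames = list(NULL, names(cfg))), path)
  invisible(path)
}

#' Read a run configuration from a DCF file
#'
#' Unspecified keys keep their defaults; types are restored from the
#' defaults' prototypes.
#'
#' @param path DCF file written by [write_run_config()] or by hand.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file '%s' not found", path)
  raw <- read.dcf(path)
  base <- run_config()
  vals <- stats::setNames(as.list(raw[1, ]), colnames(raw))
  unknown <- setdiff(names(vals), names(base))
  if (length(unknown)) abort("unknown config field(s) in %s: %s", path,
                             paste(unknown, collapse = ", "))
  for (k in names(vals)) {
    proto <- base[[k]]
    parts <- strsplit(trimws(vals[[k]]), "[[:space:]]+")[[1]]
    if (is.character(proto)) {
      base[[k]] <- parts
    } else {
      num <- suppressWarnings(as.numeric(parts))
      if (any(is.na(num) & parts != "NA")) {
        abort("config field '%s': cannot parse '%s' as a number", k, vals[[k]])
      }
      base[[k]] <- if (is.integer(proto)) as.integer(num) else num
    }
  }
  structure(base, class = "run_config")
}

config_stain_matrix <- function(cfg) {
  build_stain_matrix(cfg$stain_nuclei, cfg$stain_tunel, cfg$stain_pigment)
}
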