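#' Pipeline configuration
#'
#' All tunable parameters of the segmentation pipeline with their defaults.
#' Structuring-element radii default to `NULL`, meaning they are derived from
#' the image width at run time: top-hat `round(width / 32)` (10 px at 320),
#' closing `round(width / 64)` (5 px) and opening `round(width / 53)` (6 px),
#' so the same configuration transfers across rasters of different size.
#'
#' @param ... Named overrides using dotted keys, e.g.
#'   `faz_config(grow.tolerance_frac = 0.25)`. Unknown keys are rejected.
#'
#' @section Keys:
#' \describe{
#'   \item{tophat.selem_radius}{Disc radius (px) of the white top-hat
#'     structuring element; `NULL` = `round(width / 32)`.}
#'   \item{canny.sigma}{Gaussian smoothing scale in pixels (default 1).}
#'   \item{canny.low_frac, canny.high_frac}{Hysteresis thresholds as
#'     multiples of the mean image intensity (defaults 0.66 and 1.33).}
#'   \item{morph.close_radius}{Disc radius of the edge-sealing closing;
#'     `NULL` = `round(width / 64)`.}
#'   \item{morph.open_radius}{Disc radius of the speckle-removing opening;
#'     `NULL` = `round(width / 53)`.}
#'   \item{fp.border_margin_frac}{Candidates whose bounding box comes within
#'     this fraction of `min(height, width)` of any border are peripheral
#'     (default 0.05).}
#'   \item{fp.max_center_offset_frac}{Maximum allowed centroid offset from
#'     the image center, as a fraction of `min(height, width) / 2`
#'     (default 0.8).}
#'   \item{fp.min_solidity}{Minimum pixel-count / bounding-box-area ratio; a
#'     candidate below it is disperse (default 0.3).}
#'   \item{grow.tolerance_frac}{Relative intensity tolerance of the region
#'     growing acceptance interval `[ARV - tol x ARV, ARV + tol x ARV]`
#'     (default 0.3).}
#'   \item{grow.seed_erosion_radius}{Disc radius of the seed erosion
#'     (default 3 px).}
#'   \item{grow.max_iterations}{Sweep cap of the region growing loop
#'     (default 100).}
#'   \item{grow.abs_floor}{Optional absolute widening of the acceptance
#'     interval (default 0.05, about twice the typical intensity-noise scale);
#'     guards against the multiplicative interval
#'     collapsing as ARV approaches 0.}
#' }
#'
#' @return A named list of class `faz_config`.
#' @examples
#' cfg <- faz_config(canny.sigma = 1.5)
#' cfg$canny.sigma
#' @export
faz_config <- function(...) {
  defaults <- list(
    tophat.selem_radius = NULL,
    canny.sigma = 1.0,
    canny.low_frac = 0.66,
    canny.high_frac = 1.33,
    morph.close_radius = NULL,
    morph.open_radius = NULL,
    fp.border_margin_frac = 0.05,
    fp.max_center_offset_frac = 0.8,
    fp.min_solidity = 0.3,
    grow.tolerance_frac = 0.3,
    grow.seed_erosion_radius = 3L,
    grow.max_iterations = 100L,
    grow.abs_floor = 0.05
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(defaults))
    if (length(bad)) {
      stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    defaults[names(overrides)] <- overrides
  }
  cfg <- structure(defaults, class = "faz_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  pos_or_null <- function(key) {
    v <- cfg[[key]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || v < 1)) {
      stop("config `", key, "` must be NULL or a radius >= 1", call. = FALSE)
    }
  }
  pos_or_null("tophat.selem_radius")
  pos_or_null("morph.close_radius")
  pos_or_null("morph.open_radius")
  if (cfg$canny.sigma <= 0) stop("canny.sigma must be > 0", call. = FALSE)
  if (!(cfg$canny.low_frac > 0 && cfg$canny.low_frac < cfg$canny.high_frac)) {
    stop("need 0 < canny.low_frac < canny.high_frac", call. = FALSE)
  }
  frac01 <- function(key) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || v < 0 || v > 1) {
      stop("config `", key, "` must be in [0, 1]", call. = FALSE)
    }
  }
  frac01("fp.border_margin_frac")
  frac01("fp.max_center_offset_frac")
  frac01("fp.min_solidity")
  if (!(cfg$grow.tolerance_frac > 0 && cfg$grow.tolerance_frac < 1)) {
    stop("grow.tolerance_frac must be in (0, 1)", call. = FALSE)
  }
  if (cfg$grow.seed_erosion_radius < 1) {
    stop("grow.seed_erosion_radius must be >= 1", call. = FALSE)
  }
  if (cfg$grow.max_iterations < 1) {
    stop("grow.max_iterations must be >= 1", call. = FALSE)
  }
  if (cfg$grow.abs_floor < 0) stop("grow.abs_floor must be >= 0", call. = FALSE)
  invisible(cfg)
}

#' Load a pipeline configuration from a YAML file
#'
#' The file holds a flat mapping of the dotted keys documented in
#' [faz_config()]; missing keys keep their defaults and unknown keys are
#' rejected.
#'
#' @param path YAML file path, or `NULL` for the default configuration.
#' @return A `faz_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) return(faz_config())
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) return(faz_config())
  if (!is.list(vals) || is.null(names(vals)) || any(names(vals) == "")) {
    stop("config file must be a named mapping", call. = FALSE)
  }
  do.call(faz_config, vals)
}

# resolve NULL (width-relative) radii for a concrete image
resolve_config <- function(cfg, width) {
  if (is.null(cfg$tophat.selem_radius)) {
    cfg$tophat.selem_radius <- max(1L, round(width / 32))
  }
  if (is.null(cfg$morph.close_radius)) {
    cfg$morph.close_radius <- max(1L, round(width / 64))
  }
  if (is.null(cfg$morph.open_radius)) {
    cfg$morph.open_radius <- max(1L, round(width / 53))
  }
  cfg
}
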