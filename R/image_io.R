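#' Grayscale en-face OCT-A image
#'
#' Container for a single-channel en-face OCT-A intensity raster together
#' with the physical width of the imaged field. Pixel intensities are stored
#' min-max normalized to `[0, 1]` in a plain numeric matrix, row-major with
#' the origin at the top-left corner; coordinates throughout the package are
#' 1-based `(row, col)`.
#'
#' @param pixels Numeric matrix of intensities in `[0, 1]`.
#' @param field_mm Physical width of the imaged field in millimeters
#'   (3 or 6 for the usual en-face protocols; any positive value is allowed).
#' @param normalize If `TRUE` (default), min-max normalize `pixels` to
#'   `[0, 1]` first.
#'
#' @return An object of class `faz_gray_image`: a list with elements
#'   `pixels`, `height`, `width` and `field_mm`.
#' @examples
#' img <- gray_image(matrix(runif(64), 8, 8), field_mm = 3)
#' range(img$pixels)
#' @export
gray_image <- function(pixels, field_mm, normalize = TRUE) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    stop("image must have positive dimensions", call. = FALSE)
  }
  if (!is.numeric(field_mm) || length(field_mm) != 1L || field_mm <= 0) {
    stop("`field_mm` must be a single positive number", call. = FALSE)
  }
  if (anyNA(pixels)) stop("`pixels` contains NA", call. = FALSE)
  if (normalize) {
    pixels <- normalize01(pixels)
  } else if (min(pixels) < 0 || max(pixels) > 1) {
    stop("`pixels` must lie in [0, 1] when normalize = FALSE", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      height = nrow(pixels),
      width = ncol(pixels),
      field_mm = as.numeric(field_mm)
    ),
    class = "faz_gray_image"
  )
}

#' @export
print.faz_gray_image <- function(x, ...) {
  cat(sprintf(
    "<faz_gray_image> %d x %d px, field %g mm, intensities [%.3f, %.3f]\n",
    x$height, x$width, x$field_mm, min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' Min-max normalize a matrix to [0, 1]
#'
#' Degenerate (constant) inputs are rejected: an image with zero dynamic
#' range carries no vascular signal and cannot be segmented.
#'
#' @param x Numeric matrix.
#' @return Matrix rescaled so `min(x) == 0` and `max(x) == 1`.
#' @export
normalize01 <- function(x) {
  rng <- range(x)
  if (rng[2] - rng[1] <= 0) {
    stop("degenerate input: image has zero dynamic range", call. = FALSE)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Read an en-face OCT-A image from a PNG or TIFF file
#'
#' Intensities are min-max normalized to `[0, 1]`. RGB inputs are averaged
#' across channels to grayscale (en-face exports are often saved as RGB with
#' identical channels). 8- and 16-bit rasters are supported through EBImage,
#' which maps integer sample values onto `[0, 1]` before the normalization.
#'
#' @param path Path to a PNG or TIFF file.
#' @param field_mm Physical field width in millimeters (3 or 6).
#' @return A [gray_image()] object.
#' @export
load_image <- function(path, field_mm) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- try(EBImage::readImage(path), silent = TRUE)
  if (inherits(img, "try-error")) {
    stop("could not decode image file: ", path, call. = FALSE)
  }
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 3L) dat <- rowMeans(dat, dims = 2L)
  # EBImage stores (x, y); transpose to (row, col)
  gray_image(t(dat), field_mm = field_mm)
}

#' Validate a binary mask
#'
#' Masks are plain logical matrices on the same grid as their source image.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return The mask as a logical matrix.
#' @export
as_mask <- function(mask) {
  if (inherits(mask, "Image")) mask <- t(EBImage::imageData(mask))
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  if (is.numeric(mask)) {
    if (!all(mask %in% c(0, 1))) {
      stop("numeric mask values must be strictly 0/1", call. = FALSE)
    }
    mask <- mask > 0.5
  }
  if (!is.logical(mask)) stop("mask must be logical or 0/1 numeric", call. = FALSE)
  if (anyNA(mask)) stop("mask contains NA", call. = FALSE)
  mask
}

#' Write a binary mask as a lossless PNG (0/255)
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @seealso [load_mask()] for the bit-exact inverse.
#' @export
save_mask <- function(mask, path) {
  mask <- as_mask(mask)
  ok <- try(
    EBImage::writeImage(EBImage::Image(t(mask * 1)), path, type = "png"),
    silent = TRUE
  )
  if (inherits(ok, "try-error")) stop("could not write mask: ", path, call. = FALSE)
  invisible(path)
}

#' Read a binary mask from a PNG/TIFF file
#'
#' Any pixel above half intensity is foreground, so 0/255 and 0/1 encodings
#' both round-trip bit-exactly.
#'
#' @param path Mask file path.
#' @return Logical matrix.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 3L) dat <- rowMeans(dat, dims = 2L)
  t(dat) > 0.5
}

#' Write a per-image segmentation report as JSON
#'
#' The report records the derived biomarkers (area in mm^2, circularity),
#' the final and preliminary centroids, convergence information, and the
#' exact configuration used, so every result is reproducible from the
#' report alone.
#'
#' @param result A `faz_segmentation` object from [segment_faz()].
#' @param path Output JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(result, path) {
  stopifnot(inherits(result, "faz_segmentation"))
  rec <- list(
    package = "fazseg",
    version = as.character(utils::packageVersion("fazseg")),
    found = result$found,
    area_mm2 = result$area_mm2,
    circularity = result$circularity,
    centroid = result$centroid,
    preliminary_centroid = result$preliminary_centroid,
    converged = result$converged,
    iterations = result$iterations,
    field_mm = result$field_mm,
    config = result$config
  )
  ok <- try(
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, null = "null"),
    silent = TRUE
  )
  if (inherits(ok, "try-error")) stop("could not write report: ", path, call. = FALSE)
  invisible(path)
}

#' Read a segmentation report written by [write_report()]
#'
#' @param path JSON report path.
#' @return A list with the report fields.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
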