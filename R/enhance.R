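#' Disc structuring element
#'
#' Flat disc of the given radius (EBImage brush of odd size
#' `2 * radius + 1`), the structuring element used by every morphological
#' step of the pipeline.
#'
#' @param radius Disc radius in pixels (>= 1).
#' @return 0/1 numeric matrix.
#' @export
disc_brush <- function(radius) {
  radius <- as.integer(round(radius))
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  EBImage::makeBrush(2L * radius + 1L, shape = "disc")
}

#' Vascular enhancement by the grayscale white top-hat
#'
#' Subtracts the morphological opening (disc structuring element) from the
#' image. Bright structures thinner than the disc -- the vessels -- are
#' preserved at full contrast while the broad macular background is
#' flattened, so avascular areas keep low intensity profiles. The transform
#' is anti-extensive (output <= input) and non-negative.
#'
#' @param img A [gray_image()] object.
#' @param selem_radius Disc radius in pixels; default `round(width / 32)`
#'   (10 px at 320 px width) passes capillaries and removes the background.
#' @return A `faz_gray_image` holding the enhanced intensities (not
#'   re-normalized; values stay in `[0, 1]`).
#' @examples
#' img <- gray_image(matrix(runif(1024), 32, 32), field_mm = 3)
#' enh <- white_tophat(img, selem_radius = 3)
#' all(enh$pixels <= img$pixels)
#' @export
white_tophat <- function(img, selem_radius = NULL) {
  stopifnot(inherits(img, "faz_gray_image"))
  if (is.null(selem_radius)) selem_radius <- max(1L, round(img$width / 32))
  if (selem_radius < 1) stop("selem_radius must be >= 1", call. = FALSE)
  if (selem_radius >= min(img$height, img$width) / 2) {
    stop("selem_radius too large for the image", call. = FALSE)
  }
  kern <- disc_brush(selem_radius)
  out <- EBImage::whiteTopHat(img$pixels, kern)
  out <- pmin(pmax(out, 0), 1)
  dim(out) <- dim(img$pixels)
  structure(
    list(
      pixels = out, height = img$height, width = img$width,
      field_mm = img$field_mm
    ),
    class = "faz_gray_image"
  )
}
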