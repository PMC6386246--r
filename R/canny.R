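#' Parameters of the adaptive Canny detector
#'
#' The hysteresis thresholds are expressed as multiples of the mean image
#' intensity, so the detector adapts to the global brightness of each
#' OCT-A capture and the edge map is invariant to a global intensity
#' rescaling.
#'
#' @param sigma Gaussian smoothing scale in pixels (> 0).
#' @param low_frac,high_frac Low/high hysteresis thresholds as multiples of
#'   `mean(img)`; `0 < low_frac < high_frac`.
#' @return A list of class `faz_canny_params`.
#' @export
canny_params <- function(sigma = 1.0, low_frac = 0.66, high_frac = 1.33) {
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  if (!(low_frac > 0 && low_frac < high_frac)) {
    stop("need 0 < low_frac < high_frac", call. = FALSE)
  }
  structure(
    list(sigma = sigma, low_frac = low_frac, high_frac = high_frac),
    class = "faz_canny_params"
  )
}

# replicate-padded 3x3 convolution (correlation with flipped kernel is
# irrelevant here: Sobel kernels are passed pre-oriented)
conv3 <- function(x, k) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(1L, seq_len(nr), nr)
  ci <- c(1L, seq_len(nc), nc)
  p <- x[ri, ci]
  out <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    kv <- k[di + 2L, dj + 2L]
    if (kv != 0) out <- out + kv * p[(2L + di):(nr + 1L + di),
                                     (2L + dj):(nc + 1L + dj)]
  }
  out
}

shift_mat <- function(x, dr, dc, fill = 0) {
  nr <- nrow(x); nc <- ncol(x)
  out <- matrix(fill, nr, nc)
  rs <- max(1L, 1L + dr):min(nr, nr + dr)
  cs <- max(1L, 1L + dc):min(nc, nc + dc)
  out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

#' Vessel edge detection with mean-adaptive Canny
#'
#' Standard Canny stages -- Gaussian smoothing, Sobel gradients,
#' non-maximum suppression, hysteresis -- with the two hysteresis
#' thresholds computed from the image itself:
#' `low = low_frac * mean(img)` and `high = high_frac * mean(img)`
#' (clamped to `(0, 1)`). Because the gradient magnitude scales linearly
#' with intensity, the resulting edge map is unchanged when all intensities
#' are multiplied by a constant, which is what makes the detector robust
#' across OCT-A captures of different overall brightness.
#'
#' @param img A [gray_image()] object, typically the white top-hat output.
#' @param params A [canny_params()] object.
#' @return Logical edge mask (thin, 8-connected curves along vessel
#'   boundaries).
#' @export
adaptive_canny <- function(img, params = canny_params()) {
  stopifnot(inherits(img, "faz_gray_image"), inherits(params, "faz_canny_params"))
  x <- img$pixels
  mu <- mean(x)
  if (mu <= 0) stop("degenerate input: mean intensity is zero", call. = FALSE)
  eps <- 1e-9
  lo <- min(max(params$low_frac * mu, eps), 1 - 2 * eps)
  hi <- min(max(params$high_frac * mu, lo + eps), 1 - eps)

  sm <- EBImage::gblur(x, sigma = params$sigma)
  sm <- matrix(as.numeric(sm), nrow(x), ncol(x))

  sobel_r <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3, byrow = TRUE)
  gr <- conv3(sm, sobel_r)        # gradient along rows (down)
  gc <- conv3(sm, t(sobel_r))     # gradient along cols (right)
  mag <- sqrt(gr^2 + gc^2)

  # non-maximum suppression: quantize gradient direction into 4 sectors
  ang <- atan2(gr, gc)                      # (-pi, pi]
  ang[ang < 0] <- ang[ang < 0] + pi         # fold to [0, pi)
  sector <- as.integer(floor((ang + pi / 8) / (pi / 4))) %% 4L
  # sector 0: horizontal gradient -> compare left/right neighbours
  # sector 1: diagonal (down-right gradient) -> compare down-right/up-left
  # sector 2: vertical gradient -> compare up/down
  # sector 3: anti-diagonal -> compare down-left/up-right
  n1 <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  keep <- matrix(FALSE, nrow(x), ncol(x))
  for (s in 0:3) {
    d <- n1[[s + 1L]]
    a <- shift_mat(mag, d[1], d[2])
    b <- shift_mat(mag, -d[1], -d[2])
    keep <- keep | (sector == s & mag >= a & mag >= b)
  }
  cand <- keep & mag >= lo
  strong <- cand & mag >= hi
  if (!any(strong)) return(matrix(FALSE, nrow(x), ncol(x)))
  # hysteresis: keep weak-edge components that contain a strong pixel
  lab <- label_components(cand)
  good <- sort(unique(lab[strong]))
  matrix(lab %in% good, nrow(x), ncol(x)) & cand
}
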