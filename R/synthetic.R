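#' Specification of a synthetic OCT-A phantom
#'
#' Parameters of an artificial en-face OCT-A image with a known
#' ground-truth FAZ. The phantom emulates the features the pipeline relies
#' on: a bright meandering capillary mesh on a dark background, a central
#' avascular region bounded by a perifoveal capillary ring, lower
#' vessel/background contrast and blur for deep-plexus style images, and an
#' optional dark capture-artifact band along one border.
#'
#' @param size_px Raster side length (default 320).
#' @param field_mm Physical field width, 3 or 6 mm (default 3).
#' @param faz_radius_mm Mean FAZ contour radius in millimeters
#'   (default 0.32, i.e. about 0.32 mm^2 of avascular area).
#' @param irregularity Amplitude in `[0, 1]` of the low-order Fourier
#'   perturbation of the FAZ contour radius,
#'   `r(theta) = r0 (1 + irregularity * sum_k a_k cos(k theta + phi_k))`
#'   with harmonics `k = 2..6`; 0 gives a near-circle, 0.6 a strongly
#'   irregular diabetic-style contour.
#' @param vessel_density Capillary mesh density in `[0, 1]` (default 0.7);
#'   0 yields a degenerate avascular image (flagged, see below).
#' @param depth_style `"superficial"` (crisp, high contrast) or `"deep"`
#'   (diffuse, low contrast).
#' @param artifact_band If `TRUE`, darken a band along one image border,
#'   emulating a capture error.
#' @param noise_sigma Gaussian intensity noise scale (default 0.03).
#' @param seed Integer RNG seed; fixes the phantom bit-exactly.
#' @return A list of class `faz_phantom_spec`.
#' @export
phantom_spec <- function(size_px = 320, field_mm = 3, faz_radius_mm = 0.32,
                         irregularity = 0.2, vessel_density = 0.7,
                         depth_style = c("superficial", "deep"),
                         artifact_band = FALSE, noise_sigma = 0.03,
                         seed = 1L) {
  depth_style <- match.arg(depth_style)
  if (size_px < 32) stop("size_px must be >= 32", call. = FALSE)
  if (!field_mm > 0) stop("field_mm must be > 0", call. = FALSE)
  if (2 * faz_radius_mm * (1 + irregularity) >= 0.9 * field_mm) {
    stop("FAZ too large for the field", call. = FALSE)
  }
  if (irregularity < 0 || irregularity > 1) {
    stop("irregularity must be in [0, 1]", call. = FALSE)
  }
  if (vessel_density < 0 || vessel_density > 1) {
    stop("vessel_density must be in [0, 1]", call. = FALSE)
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  structure(
    list(
      size_px = as.integer(size_px), field_mm = field_mm,
      faz_radius_mm = faz_radius_mm, irregularity = irregularity,
      vessel_density = vessel_density, depth_style = depth_style,
      artifact_band = isTRUE(artifact_band), noise_sigma = noise_sigma,
      seed = as.integer(seed)
    ),
    class = "faz_phantom_spec"
  )
}

# rasterize one meandering stroke; returns (row, col) integer steps
stroke_path <- function(start, theta0, length_px, turn_sd, n) {
  turns <- stats::rnorm(length_px, 0, turn_sd)
  theta <- theta0 + cumsum(turns)
  r <- start[1] + cumsum(sin(theta))
  c <- start[2] + cumsum(cos(theta))
  keep <- r >= 1 & r <= n & c >= 1 & c <= n
  cbind(round(r[keep]), round(c[keep]))
}

#' Generate one synthetic OCT-A phantom with its ground-truth FAZ mask
#'
#' The ground-truth mask is the radius-modulated central avascular region;
#' vessels are drawn as random meandering strokes of 1-4 px width plus an
#' explicit perifoveal capillary ring along the FAZ boundary (capillaries
#' terminate at the avascular border, as in real angiograms), then blurred
#' and composed with background noise. Deep style lowers the
#' vessel/background contrast and blurs more. The result is deterministic
#' given the spec seed.
#'
#' @param spec A [phantom_spec()] object.
#' @return A list with `image` (a [gray_image()]), `mask` (logical
#'   ground-truth FAZ), `spec`, and `degenerate` (`TRUE` when
#'   `vessel_density = 0` leaves no vasculature).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "faz_phantom_spec"))
  set.seed(spec$seed)
  n <- spec$size_px
  px_per_mm <- n / spec$field_mm
  r0 <- spec$faz_radius_mm * px_per_mm

  # FAZ contour: low-order Fourier radius modulation
  ks <- 2:6
  amp <- stats::runif(length(ks)) / ks
  amp <- amp / sum(amp)
  phs <- stats::runif(length(ks), 0, 2 * pi)
  sgn <- sample(c(-1, 1), length(ks), replace = TRUE)
  center <- (n + 1) / 2 + stats::runif(2, -0.02, 0.02) * n
  radius_at <- function(theta) {
    mod <- rep(0, length(theta))
    for (i in seq_along(ks)) {
      mod <- mod + sgn[i] * amp[i] * cos(ks[i] * theta + phs[i])
    }
    r0 * (1 + spec$irregularity * mod)
  }
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  dr <- rr - center[1]
  dc <- cc - center[2]
  theta <- atan2(dr, dc)
  rad <- matrix(radius_at(as.numeric(theta)), n, n)
  dist <- sqrt(dr^2 + dc^2)
  gt <- dist <= rad

  deep <- spec$depth_style == "deep"
  base <- if (deep) 0.16 else 0.10
  img <- matrix(base, n, n)
  degenerate <- spec$vessel_density == 0

  if (!degenerate) {
    # meandering capillary strokes, seeded on a jittered grid for even
    # coverage; the stroke count scales with the physical field width (a
    # 6 mm capture shows twice the retina of a 3 mm one) and stroke widths
    # are sampled in physical units (9-40 um calibre) then converted to px
    n_strokes <- max(1L, round(spec$vessel_density * n / 1.7 * spec$field_mm / 3))
    grid_k <- max(2L, ceiling(sqrt(n_strokes)))
    gpos <- expand.grid(
      r = (seq_len(grid_k) - 0.5) / grid_k * n,
      c = (seq_len(grid_k) - 0.5) / grid_k * n
    )
    gpos <- gpos[sample.int(nrow(gpos), n_strokes), , drop = FALSE]
    calibre_mm <- sample(c(0.0094, 0.0188, 0.0281, 0.0375), n_strokes,
                         replace = TRUE, prob = c(0.35, 0.4, 0.2, 0.05))
    widths <- pmin(pmax(round(calibre_mm * px_per_mm), 1L), 4L)
    canv <- lapply(1:4, function(w) matrix(0, n, n))
    for (s in seq_len(n_strokes)) {
      start <- c(gpos$r[s], gpos$c[s]) + stats::runif(2, -n / grid_k, n / grid_k) / 2
      len <- round(stats::runif(1, 0.5, 1.4) * n)
      pts <- stroke_path(start, stats::runif(1, 0, 2 * pi), len,
                         turn_sd = 0.18, n = n)
      if (nrow(pts)) canv[[widths[s]]][pts] <- 1
    }
    # perifoveal capillary ring just outside the FAZ contour
    th <- seq(0, 2 * pi, length.out = max(64L, round(4 * pi * r0)))
    ring_r <- radius_at(th) + 1.5
    rpts <- cbind(
      round(center[1] + ring_r * sin(th)),
      round(center[2] + ring_r * cos(th))
    )
    rpts <- rpts[rpts[, 1] >= 1 & rpts[, 1] <= n &
                   rpts[, 2] >= 1 & rpts[, 2] <= n, , drop = FALSE]
    canv[[2]][rpts] <- 1
    ves <- canv[[1]]
    for (w in 2:4) {
      if (any(canv[[w]] > 0)) {
        dil <- EBImage::dilate(canv[[w]], disc_brush(max(1L, floor(w / 2))))
        ves <- pmax(ves, matrix(as.numeric(dil), n, n))
      }
    }
    inside <- dist <= rad - 0.5
    if (deep) {
      # diffuse edges: vessels vanish inside the FAZ before the blur
      ves[inside] <- 0
      ves <- matrix(as.numeric(EBImage::gblur(ves, sigma = 1.1)), n, n)
    } else {
      ves <- matrix(as.numeric(EBImage::gblur(ves, sigma = 0.5)), n, n)
      ves[inside] <- 0
    }
    contrast <- if (deep) 0.45 else 0.85
    img <- img + contrast * ves
  }

  if (spec$noise_sigma > 0) {
    img <- img + matrix(stats::rnorm(n * n, 0, spec$noise_sigma), n, n)
  }
  if (spec$artifact_band) {
    side <- sample(c("top", "bottom", "left", "right"), 1)
    bw <- max(3L, round(stats::runif(1, 0.05, 0.12) * n))
    sel <- switch(side,
      top = rr <= bw, bottom = rr > n - bw,
      left = cc <= bw, right = cc > n - bw
    )
    img[sel] <- img[sel] * 0.15
  }
  img <- pmin(pmax(img, 0), 1)
  list(
    image = gray_image(img, field_mm = spec$field_mm),
    mask = gt,
    spec = spec,
    degenerate = degenerate
  )
}

#' Generate a reproducible suite of phantoms over the 4 study subgroups
#'
#' Cycles round-robin through the 4 standard en-face configurations
#' (3 and 6 mm fields, superficial and deep plexus styles) while sampling
#' the FAZ area uniformly in `[0.1, 0.6]` mm^2, the contour irregularity
#' uniformly in `[0, 0.6]`, and giving each phantom a 10 percent chance of
#' a border artifact band -- the conditions under which the end-to-end
#' pipeline is validated.
#'
#' @param n Number of phantoms.
#' @param base A [phantom_spec()] giving size, density and noise defaults.
#' @param seed Master RNG seed; per-phantom seeds are drawn from it.
#' @param area_range_mm2 Range the FAZ area is sampled from (mm^2).
#' @param irregularity_range Range the contour irregularity is sampled from.
#' @param artifact_prob Probability of a border artifact band (default 0.1).
#' @return A list of length `n`; each element as in [generate_phantom()]
#'   plus a `subgroup` label (`"3mm-superficial"`, ...).
#' @export
generate_suite <- function(n, base = phantom_spec(), seed = 1L,
                           area_range_mm2 = c(0.1, 0.6),
                           irregularity_range = c(0, 0.6),
                           artifact_prob = 0.1) {
  stopifnot(n >= 1)
  set.seed(seed)
  fields <- rep(c(3, 3, 6, 6), length.out = n)
  depths <- rep(c("superficial", "deep"), length.out = n)
  seeds <- sample.int(2^30, n)
  areas <- stats::runif(n, area_range_mm2[1], area_range_mm2[2])
  irrs <- stats::runif(n, irregularity_range[1], irregularity_range[2])
  bands <- stats::runif(n) < artifact_prob
  lapply(seq_len(n), function(i) {
    sp <- phantom_spec(
      size_px = base$size_px, field_mm = fields[i],
      faz_radius_mm = sqrt(areas[i] / pi),
      irregularity = irrs[i], vessel_density = base$vessel_density,
      depth_style = depths[i], artifact_band = bands[i],
      noise_sigma = base$noise_sigma, seed = seeds[i]
    )
    ph <- generate_phantom(sp)
    ph$subgroup <- sprintf("%dmm-%s", fields[i], depths[i])
    ph
  })
}

#' Write a phantom suite to disk with an evaluation manifest
#'
#' Produces `phantom_###.png` images, `phantom_###_mask.png` ground-truth
#' masks and a `manifest.csv` (columns `image`, `mask`, `field_mm`,
#' `subgroup`) directly consumable by [cmd_evaluate()]. All phantoms are
#' synthetic; none derive from clinical data.
#'
#' @param dir Output directory (created if needed).
#' @param n Number of phantoms.
#' @param base,seed Passed to [generate_suite()].
#' @return The manifest path, invisibly.
#' @export
write_phantom_suite <- function(dir, n, base = phantom_spec(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  suite <- generate_suite(n, base = base, seed = seed)
  rows <- lapply(seq_along(suite), function(i) {
    ip <- file.path(dir, sprintf("phantom_%03d.png", i))
    mp <- file.path(dir, sprintf("phantom_%03d_mask.png", i))
    EBImage::writeImage(
      EBImage::Image(t(suite[[i]]$image$pixels)), ip, type = "png"
    )
    save_mask(suite[[i]]$mask, mp)
    data.frame(
      image = basename(ip), mask = basename(mp),
      field_mm = suite[[i]]$spec$field_mm, subgroup = suite[[i]]$subgroup
    )
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
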