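#' Erode the preliminary FAZ region into a safe seed
#'
#' The preliminary candidate can overshoot the vascular limits, so it is
#' eroded (disc element) before being used as the region-growing seed,
#' guaranteeing the seed sits inside the true avascular region. If the
#' erosion would empty the mask the radius is halved repeatedly (minimum 1);
#' if even radius 1 empties it, the single pixel nearest the mask centroid
#' is used.
#'
#' @param preliminary Non-empty logical mask.
#' @param radius Disc radius in pixels (default 3).
#' @return Non-empty logical mask, always a subset of `preliminary`.
#' @export
erode_seed <- function(preliminary, radius = 3) {
  preliminary <- as_mask(preliminary)
  if (!any(preliminary)) stop("preliminary mask is empty", call. = FALSE)
  radius <- max(1L, as.integer(round(radius)))
  repeat {
    er <- EBImage::erode(preliminary * 1, disc_brush(radius)) > 0.5
    if (any(er)) return(er)
    if (radius == 1L) break
    radius <- max(1L, radius %/% 2L)
  }
  # fallback: single pixel of the mask nearest its centroid
  idx <- which(preliminary, arr.ind = TRUE)
  ctr <- colMeans(idx)
  d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
  out <- matrix(FALSE, nrow(preliminary), ncol(preliminary))
  out[idx[which.min(d2), , drop = FALSE]] <- TRUE
  out
}

#' Region-growing parameters
#'
#' @param tolerance_frac Relative half-width of the intensity acceptance
#'   interval around the average region value (ARV): a pixel is accepted if
#'   its intensity lies in `[ARV - tol x ARV, ARV + tol x ARV]`. Default
#'   0.3, i.e. a 30 percent variation tolerance.
#' @param seed_erosion_radius Disc radius of the seed erosion (default 3).
#' @param max_iterations Sweep cap (default 100).
#' @param abs_floor Absolute widening of the interval (default 0.05, about
#'   twice the typical intensity-noise scale); guards against the
#'   multiplicative interval collapsing when ARV approaches 0 on the dark
#'   avascular plateau of the enhanced image, where a purely relative band
#'   stalls the growth at the seed.
#' @return A list of class `faz_grow_params`.
#' @export
grow_params <- function(tolerance_frac = 0.3, seed_erosion_radius = 3,
                        max_iterations = 100, abs_floor = 0.05) {
  if (!(tolerance_frac > 0 && tolerance_frac < 1)) {
    stop("tolerance_frac must be in (0, 1)", call. = FALSE)
  }
  if (seed_erosion_radius < 1) stop("seed_erosion_radius must be >= 1", call. = FALSE)
  if (max_iterations < 1) stop("max_iterations must be >= 1", call. = FALSE)
  if (abs_floor < 0) stop("abs_floor must be >= 0", call. = FALSE)
  structure(
    list(
      tolerance_frac = tolerance_frac,
      seed_erosion_radius = as.integer(seed_erosion_radius),
      max_iterations = as.integer(max_iterations),
      abs_floor = abs_floor
    ),
    class = "faz_grow_params"
  )
}

# component of `mask` containing (or maximally overlapping) the anchor
keep_anchor_component <- function(mask, anchor) {
  lab <- label_components(mask)
  ctr <- round(colMeans(which(anchor, arr.ind = TRUE)))
  pick <- lab[ctr[1], ctr[2]]
  if (pick == 0L) {
    hits <- tabulate(lab[anchor & mask], max(lab))
    pick <- which.max(hits)
  }
  lab == pick
}

#' Seeded region growing with pixel addition and deletion
#'
#' Extension of classical seeded region growing: each sweep recomputes the
#' average region value (ARV), then simultaneously (1) adds every 8-neighbour
#' of the region whose intensity lies inside the acceptance interval
#' `[ARV - tol x ARV, ARV + tol x ARV]` and (2) deletes every current region
#' pixel whose intensity falls outside that interval. The original seed acts
#' as an anchor that is never deleted (preventing region evaporation) and
#' only the connected component containing the seed centroid is kept after
#' each sweep. The loop stops when a sweep changes no pixel, or at
#' `max_iterations`.
#'
#' Because the ARV is recomputed once per sweep and all additions/deletions
#' of a sweep use that one value, the result is independent of any pixel
#' ordering inside a sweep.
#'
#' @param img A [gray_image()] object -- the top-hat-enhanced working image
#'   of the pipeline, on which the FAZ is a low-intensity plateau.
#' @param seed Non-empty logical seed mask (typically from [erode_seed()]).
#' @param params A [grow_params()] object.
#' @param update_arv Recompute the ARV every sweep (default `TRUE`). With
#'   `FALSE` the interval is frozen at the seed mean.
#' @param allow_delete Enable the deletion rule (default `TRUE`). With
#'   `update_arv = FALSE` and `allow_delete = FALSE` the procedure reduces
#'   to an interval-membership flood fill from the seed.
#' @return A list of class `faz_region_grow`: `mask` (logical), `converged`,
#'   `iterations`, `arv` (final average region value), `evaporated` (`TRUE`
#'   if the region shrank back to the anchor alone).
#' @export
region_grow <- function(img, seed, params = grow_params(),
                        update_arv = TRUE, allow_delete = TRUE) {
  stopifnot(inherits(img, "faz_gray_image"), inherits(params, "faz_grow_params"))
  seed <- as_mask(seed)
  if (!any(seed)) stop("seed is empty", call. = FALSE)
  if (!all(dim(seed) == dim(img$pixels))) {
    stop("seed shape must match image shape", call. = FALSE)
  }
  x <- img$pixels
  anchor <- seed
  region <- seed
  box <- EBImage::makeBrush(3L, shape = "box")
  arv <- mean(x[region])
  converged <- FALSE
  it <- 0L
  deleted_any <- FALSE
  while (it < params$max_iterations) {
    it <- it + 1L
    if (update_arv || it == 1L) arv <- mean(x[region])
    lo <- arv - params$tolerance_frac * arv - params$abs_floor
    hi <- arv + params$tolerance_frac * arv + params$abs_floor
    inband <- x >= lo & x <= hi
    nb <- (EBImage::dilate(region * 1, box) > 0.5) & !region
    add <- nb & inband
    if (allow_delete) {
      kept <- (region & inband) | anchor
      deleted <- any(region & !kept)
      deleted_any <- deleted_any || deleted
    } else {
      kept <- region
      deleted <- FALSE
    }
    new_region <- kept | add
    if (deleted) new_region <- keep_anchor_component(new_region, anchor)
    if (identical(new_region, region)) {
      converged <- TRUE
      break
    }
    region <- new_region
  }
  if (update_arv) arv <- mean(x[region])
  structure(
    list(
      mask = region, converged = converged, iterations = it, arv = arv,
      evaporated = deleted_any && sum(region) <= sum(anchor)
    ),
    class = "faz_region_grow"
  )
}

#' FAZ area in square millimeters
#'
#' `area = a * field_mm^2 / (height * width)` with `a` the foreground pixel
#' count: each pixel covers `(field_mm / width) * (field_mm / height)` of
#' the retina, so a full-frame mask equals the field area exactly.
#'
#' @param mask Logical matrix.
#' @param field_mm Physical field width in millimeters.
#' @return Area in mm^2.
#' @examples
#' compute_area_mm2(matrix(TRUE, 320, 320), 3) # 9 mm^2
#' @export
compute_area_mm2 <- function(mask, field_mm) {
  mask <- as_mask(mask)
  if (field_mm <= 0) stop("field_mm must be > 0", call. = FALSE)
  sum(mask) * field_mm^2 / (nrow(mask) * ncol(mask))
}

#' Circularity from area and perimeter
#'
#' `C = 4 * pi * A / P^2`, clipped to `[0, 1]`: 1 for a perfect circle,
#' decreasing with contour irregularity.
#'
#' @param area Region area (pixel or physical units, consistent with
#'   `perimeter`).
#' @param perimeter Region perimeter (same length unit).
#' @return Circularity in `[0, 1]`.
#' @examples
#' circularity(10^2, 4 * 10) # square: pi / 4
#' @export
circularity <- function(area, perimeter) {
  if (perimeter <= 0) stop("perimeter must be > 0", call. = FALSE)
  min(max(4 * pi * area / perimeter^2, 0), 1)
}

#' Circularity of a binary mask
#'
#' Applies [circularity()] with the pixel count as area and
#' [mask_perimeter()] as perimeter -- the same estimator used for candidate
#' selection, so the shape biomarker is internally consistent.
#'
#' @param mask Non-empty logical matrix (one connected region).
#' @return Circularity in `[0, 1]`.
#' @export
compute_circularity <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  circularity(sum(mask), mask_perimeter(mask))
}

#' Full FAZ localization and segmentation pipeline
#'
#' Runs the complete method on one en-face OCT-A image:
#' vascular enhancement by white top-hat, mean-adaptive Canny edge
#' detection, morphological closing, inversion and opening to expose
#' avascular candidates, removal of peripheral/disperse false positives,
#' perimeter-based selection of the FAZ, then erosion-seeded region growing
#' with addition and deletion on the enhanced image, and finally the area
#' (mm^2) and circularity biomarkers.
#'
#' @param img A [gray_image()] object.
#' @param config A [faz_config()] object.
#' @return An object of class `faz_segmentation` with elements `found`
#'   (logical; `FALSE` is a localization failure, not an error), `mask`,
#'   `preliminary` (candidate mask before growing), `centroid` and
#'   `preliminary_centroid` (`(row, col)`), `area_mm2`, `circularity`,
#'   `converged`, `iterations`, `field_mm` and `config`. On localization
#'   failure the masks are empty and the biomarkers `NA`.
#' @export
segment_faz <- function(img, config = faz_config()) {
  stopifnot(inherits(img, "faz_gray_image"), inherits(config, "faz_config"))
  cfg <- resolve_config(config, img$width)
  enhanced <- white_tophat(img, cfg$tophat.selem_radius)
  edges <- adaptive_canny(
    enhanced,
    canny_params(cfg$canny.sigma, cfg$canny.low_frac, cfg$canny.high_frac)
  )
  closed <- close_edges(edges, cfg$morph.close_radius)
  open <- invert_and_open(closed, cfg$morph.open_radius)
  cands <- label_candidates(open)
  kept <- remove_false_positives(
    cands, c(img$height, img$width),
    border_margin_frac = cfg$fp.border_margin_frac,
    max_center_offset_frac = cfg$fp.max_center_offset_frac,
    min_solidity = cfg$fp.min_solidity
  )
  empty <- matrix(FALSE, img$height, img$width)
  if (nrow(kept) == 0L) {
    return(structure(
      list(
        found = FALSE, mask = empty, preliminary = empty,
        centroid = c(NA_real_, NA_real_),
        preliminary_centroid = c(NA_real_, NA_real_),
        area_mm2 = NA_real_, circularity = NA_real_,
        converged = NA, iterations = 0L,
        field_mm = img$field_mm, config = unclass(cfg)
      ),
      class = "faz_segmentation"
    ))
  }
  faz <- select_faz(kept, c(img$height, img$width))
  lab <- label_components(open)
  preliminary <- lab == faz$label
  seed <- erode_seed(preliminary, cfg$grow.seed_erosion_radius)
  grown <- region_grow(
    enhanced, seed,
    grow_params(
      tolerance_frac = cfg$grow.tolerance_frac,
      seed_erosion_radius = cfg$grow.seed_erosion_radius,
      max_iterations = cfg$grow.max_iterations,
      abs_floor = cfg$grow.abs_floor
    )
  )
  ctr <- colMeans(which(grown$mask, arr.ind = TRUE))
  structure(
    list(
      found = TRUE, mask = grown$mask, preliminary = preliminary,
      centroid = as.numeric(ctr),
      preliminary_centroid = c(faz$centroid_row, faz$centroid_col),
      area_mm2 = compute_area_mm2(grown$mask, img$field_mm),
      circularity = compute_circularity(grown$mask),
      converged = grown$converged, iterations = grown$iterations,
      field_mm = img$field_mm, config = unclass(cfg)
    ),
    class = "faz_segmentation"
  )
}

#' @export
print.faz_segmentation <- function(x, ...) {
  if (!x$found) {
    cat("<faz_segmentation> localization failure (no candidate survived)\n")
  } else {
    cat(sprintf(
      paste0(
        "<faz_segmentation> FAZ at (%.1f, %.1f), area %.4f mm^2, ",
        "circularity %.3f (%d sweep%s, %s)\n"
      ),
      x$centroid[1], x$centroid[2], x$area_mm2, x$circularity,
      x$iterations, if (x$iterations == 1L) "" else "s",
      if (isTRUE(x$converged)) "converged" else "iteration cap"
    ))
  }
  invisible(x)
}
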