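#' Seal gaps in the vascular edge network by morphological closing
#'
#' Binary closing (dilation then erosion) with a disc element. Gaps of width
#' up to `2 * selem_radius` between neighbouring edge fragments are sealed,
#' so the avascular holes of the vasculature become isolated dark regions.
#' A closing is used rather than a bare dilation because the erosion restores
#' the vascular band to its original extent, which a dilation alone would
#' inflate.
#'
#' @param edges Logical edge mask.
#' @param selem_radius Disc radius in pixels; default `round(width / 64)`.
#' @return Logical mask.
#' @export
close_edges <- function(edges, selem_radius = NULL) {
  edges <- as_mask(edges)
  if (is.null(selem_radius)) selem_radius <- max(1L, round(ncol(edges) / 64))
  kern <- disc_brush(selem_radius)
  EBImage::closing(edges * 1, kern) > 0.5
}

#' Invert the closed edge map and remove speckle by opening
#'
#' After inversion the foreground marks non-vascular (dark) territory; the
#' opening (erosion then dilation, disc element) deletes speckle smaller
#' than the element so that as few candidates as possible remain.
#'
#' @param closed Logical mask from [close_edges()].
#' @param selem_radius Disc radius in pixels; default `round(width / 53)`.
#' @return Logical mask of avascular candidate territory.
#' @export
invert_and_open <- function(closed, selem_radius = NULL) {
  closed <- as_mask(closed)
  if (is.null(selem_radius)) selem_radius <- max(1L, round(ncol(closed) / 53))
  kern <- disc_brush(selem_radius)
  EBImage::opening((!closed) * 1, kern) > 0.5
}

#' Label 8-connected components
#'
#' EBImage's `bwlabel` is 4-connected; diagonal-touching fragments are
#' merged here with a union-find pass so thin diagonal structures are not
#' split.
#'
#' @param mask Logical matrix.
#' @return Integer matrix of labels (0 = background, 1..n = components,
#'   labelled in raster order of their first pixel).
#' @export
label_components <- function(mask) {
  mask <- as_mask(mask)
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  # union-find over 4-connected labels that touch diagonally
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  nr <- nrow(lab); nc <- ncol(lab)
  diag_pairs <- function(a, b) {
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) unique(cbind(a[sel], b[sel])) else NULL
  }
  p1 <- diag_pairs(lab[-nr, -nc], lab[-1, -1])   # down-right neighbours
  p2 <- diag_pairs(lab[-nr, -1], lab[-1, -nc])   # down-left neighbours
  pairs <- rbind(p1, p2)
  if (!is.null(pairs)) {
    for (i in seq_len(nrow(pairs))) union(pairs[i, 1], pairs[i, 2])
  }
  roots <- vapply(seq_len(n), find, integer(1))
  # compact to consecutive labels ordered by first raster appearance
  relab <- integer(n)
  relab[sort(unique(roots))] <- seq_along(unique(sort(roots)))
  out <- lab
  out[lab > 0L] <- relab[roots[lab[lab > 0L]]]
  out
}

#' Perimeter of the foreground of a binary mask
#'
#' Boundary-length estimator used consistently for candidate selection and
#' for the circularity biomarker. The outer boundary of each 8-connected
#' component is traced (Moore neighbourhood) and the chain of boundary
#' transitions is converted to a length with the corner-corrected weights
#' of Vossepoel-Smeulders (0.980 per axial step, 1.406 per diagonal step,
#' -0.091 per direction change), which is close to unbiased on smooth
#' digital contours. An isolated pixel counts `pi` (the perimeter of its
#' inscribed unit-diameter disc); interior holes do not contribute.
#'
#' @param mask Logical matrix (any number of components).
#' @return Perimeter estimate in pixel units (0 for an empty mask).
#' @export
mask_perimeter <- function(mask) {
  mask <- as_mask(mask)
  if (!any(mask)) return(0)
  lab <- label_components(mask)
  total <- 0
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    # crop to bounding box with a 1-px pad so tracing never leaves bounds
    r0 <- min(idx[, 1]); c0 <- min(idx[, 2])
    sub <- matrix(FALSE, max(idx[, 1]) - r0 + 3L, max(idx[, 2]) - c0 + 3L)
    sub[cbind(idx[, 1] - r0 + 2L, idx[, 2] - c0 + 2L)] <- TRUE
    total <- total + trace_perimeter(sub)
  }
  total
}

# Moore-neighbour boundary tracing of a single padded component;
# returns the corner-corrected chain-code length of the outer boundary
trace_perimeter <- function(sub) {
  npix <- sum(sub)
  if (npix == 1L) return(pi)
  # neighbour offsets clockwise starting east (chain codes 0..7)
  dr <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dc <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  next_move <- function(cur, backdir) {
    for (s in 1:8) {
      d <- (backdir + s) %% 8L
      if (sub[cur[1] + dr[d + 1L], cur[2] + dc[d + 1L]]) return(d)
    }
    NA_integer_
  }
  start <- which(sub, arr.ind = TRUE)
  start <- start[order(start[, 1], start[, 2]), , drop = FALSE][1, ]
  # the topmost-leftmost pixel is virtually entered from the west
  d1 <- next_move(start, 4L)
  if (is.na(d1)) return(pi)
  codes <- d1
  cur <- c(start[1] + dr[d1 + 1L], start[2] + dc[d1 + 1L])
  second <- cur
  cap <- 8L * npix + 8L
  repeat {
    d <- next_move(cur, (codes[length(codes)] + 4L) %% 8L)
    nxt <- c(cur[1] + dr[d + 1L], cur[2] + dc[d + 1L])
    # Jacob's criterion: the walk is about to repeat its first move
    if (all(cur == start) && all(nxt == second) && d == d1) break
    codes <- c(codes, d)
    cur <- nxt
    if (length(codes) > cap) break  # safety cap; cannot occur on valid input
  }
  n_diag <- sum(codes %% 2L == 1L)
  n_axial <- length(codes) - n_diag
  n_corner <- sum(diff(c(codes, codes[1])) != 0L)
  max(0.980 * n_axial + 1.406 * n_diag - 0.091 * n_corner, 1)
}

#' Measure all connected candidate regions of a mask
#'
#' Each 8-connected component becomes one FAZ candidate with its pixel
#' count, perimeter, centroid, bounding box and border contact recorded.
#'
#' @param mask Logical matrix (the avascular candidate territory).
#' @return A data.frame with one row per candidate: `label`, `pixel_count`,
#'   `perimeter`, `centroid_row`, `centroid_col`, `min_row`, `min_col`,
#'   `max_row`, `max_col`, `touches_border`. Empty mask gives zero rows.
#' @export
label_candidates <- function(mask) {
  mask <- as_mask(mask)
  lab <- label_components(mask)
  n <- max(lab)
  empty <- data.frame(
    label = integer(0), pixel_count = integer(0), perimeter = numeric(0),
    centroid_row = numeric(0), centroid_col = numeric(0),
    min_row = integer(0), min_col = integer(0),
    max_row = integer(0), max_col = integer(0),
    touches_border = logical(0)
  )
  if (n == 0L) return(empty)
  idx <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[lab > 0L]
  cnt <- tabulate(lv, n)
  crow <- vapply(split(idx[, 1], lv), mean, numeric(1))
  ccol <- vapply(split(idx[, 2], lv), mean, numeric(1))
  rmin <- vapply(split(idx[, 1], lv), min, numeric(1))
  rmax <- vapply(split(idx[, 1], lv), max, numeric(1))
  cmin <- vapply(split(idx[, 2], lv), min, numeric(1))
  cmax <- vapply(split(idx[, 2], lv), max, numeric(1))
  peri <- vapply(seq_len(n), function(k) mask_perimeter(lab == k), numeric(1))
  data.frame(
    label = seq_len(n), pixel_count = as.integer(cnt), perimeter = peri,
    centroid_row = crow, centroid_col = ccol,
    min_row = as.integer(rmin), min_col = as.integer(cmin),
    max_row = as.integer(rmax), max_col = as.integer(cmax),
    touches_border = rmin == 1 | cmin == 1 |
      rmax == nrow(mask) | cmax == ncol(mask)
  )
}

#' Discard peripheral and disperse FAZ candidates
#'
#' Three rules remove candidates that cannot be the FAZ:
#' \itemize{
#'   \item peripheral -- the candidate touches the image border or its
#'     bounding box comes within `border_margin_frac * min(rows, cols)` of
#'     any border (capture-artifact bands and the inverted background live
#'     there);
#'   \item eccentric -- the centroid lies farther than
#'     `max_center_offset_frac * min(rows, cols) / 2` from the image center
#'     (en-face captures are macula-centered, so the FAZ is not);
#'   \item disperse -- solidity `pixel_count / bbox_area` below
#'     `min_solidity` (scattered residue of the edge network, not a compact
#'     avascular region).
#' }
#'
#' @param cands Candidate table from [label_candidates()].
#' @param img_shape Integer vector `c(rows, cols)`.
#' @param border_margin_frac,max_center_offset_frac,min_solidity Rule
#'   thresholds (defaults 0.05, 0.8, 0.3).
#' @return The retained subset of `cands` (possibly zero rows).
#' @export
remove_false_positives <- function(cands, img_shape,
                                   border_margin_frac = 0.05,
                                   max_center_offset_frac = 0.8,
                                   min_solidity = 0.3) {
  stopifnot(is.data.frame(cands), length(img_shape) == 2L)
  if (nrow(cands) == 0L) return(cands)
  rows <- img_shape[1]; cols <- img_shape[2]
  margin <- border_margin_frac * min(rows, cols)
  peripheral <- cands$touches_border |
    (cands$min_row - 1) < margin | (cands$min_col - 1) < margin |
    (rows - cands$max_row) < margin | (cols - cands$max_col) < margin
  center <- c((rows + 1) / 2, (cols + 1) / 2)
  offset <- sqrt((cands$centroid_row - center[1])^2 +
                   (cands$centroid_col - center[2])^2)
  eccentric <- offset > max_center_offset_frac * min(rows, cols) / 2
  bbox_area <- (cands$max_row - cands$min_row + 1) *
    (cands$max_col - cands$min_col + 1)
  disperse <- cands$pixel_count / bbox_area < min_solidity
  out <- cands[!(peripheral | eccentric | disperse), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the FAZ among the surviving candidates
#'
#' The largest remaining candidate is taken as the FAZ, measured by its
#' perimeter. Ties break deterministically: larger pixel count first, then
#' the centroid closest to the image center.
#'
#' @param cands Candidate table (after false-positive removal).
#' @param img_shape Integer vector `c(rows, cols)` (used only for the final
#'   tie-break).
#' @return The single selected candidate row.
#' @export
select_faz <- function(cands, img_shape = NULL) {
  stopifnot(is.data.frame(cands))
  if (nrow(cands) == 0L) {
    stop("no FAZ candidate found (localization failure)", call. = FALSE)
  }
  ord <- order(-cands$perimeter, -cands$pixel_count)
  if (!is.null(img_shape)) {
    center <- c((img_shape[1] + 1) / 2, (img_shape[2] + 1) / 2)
    offset <- sqrt((cands$centroid_row - center[1])^2 +
                     (cands$centroid_col - center[2])^2)
    ord <- order(-cands$perimeter, -cands$pixel_count, offset)
  }
  cands[ord[1], , drop = FALSE]
}
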