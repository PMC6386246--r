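#' Centroid-in-mask localization criterion
#'
#' A FAZ localization counts as successful when the integer-rounded
#' centroid of the predicted (preliminary) extraction falls on a foreground
#' pixel of the reference segmentation. An empty prediction is a failure,
#' not an error.
#'
#' @param pred Predicted logical mask (the preliminary extraction).
#' @param reference Reference logical mask, same shape.
#' @return `TRUE`/`FALSE`.
#' @export
localization_success <- function(pred, reference) {
  pred <- as_mask(pred)
  reference <- as_mask(reference)
  if (!all(dim(pred) == dim(reference))) {
    stop("masks must share a shape", call. = FALSE)
  }
  if (!any(pred)) return(FALSE)
  ctr <- round(colMeans(which(pred, arr.ind = TRUE)))
  reference[ctr[1], ctr[2]]
}

#' Jaccard index between two segmentations
#'
#' `|A intersect B| / |A union B|`, in `[0, 1]`; 1 for identical regions,
#' 0 for disjoint ones. Values around 0.7 are conventionally read as good
#' agreement and 0.9 or more as excellent.
#'
#' @param a,b Logical masks of equal shape, not both empty.
#' @return Jaccard index.
#' @export
jaccard_index <- function(a, b) {
  a <- as_mask(a)
  b <- as_mask(b)
  if (!all(dim(a) == dim(b))) stop("masks must share a shape", call. = FALSE)
  uni <- sum(a | b)
  if (uni == 0L) stop("Jaccard undefined: both masks empty", call. = FALSE)
  sum(a & b) / uni
}

#' Pearson correlation between two area series
#'
#' The covariance over the product of standard deviations, used to compare
#' automatic and reference FAZ area measurements across a set of images.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Group evaluation records into circularity tertiles
#'
#' Records are sorted by increasing circularity (stable sort, so ties keep
#' their original order) and split into low / medium / high groups of equal
#' size; when the count is not divisible by 3 the extra records go to the
#' low, then the medium group. Per group, the Pearson correlation between
#' automatic and reference areas and the mean Jaccard index are reported.
#'
#' @param records Data frame with columns `circularity`, `jaccard`,
#'   `area_auto_mm2`, `area_ref_mm2` (at least 3 rows).
#' @return A list with `groups` (the input split into a named list
#'   `low`/`medium`/`high`, each with a `circularity_level` column added)
#'   and `summary` (one row per group: `n`, `correlation`, `mean_jaccard`;
#'   the correlation is `NA` for groups of fewer than 3 records).
#' @export
circularity_tertiles <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("circularity", "jaccard", "area_auto_mm2", "area_ref_mm2")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("records lack column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 records", call. = FALSE)
  ord <- order(records$circularity)   # stable in R
  base <- n %/% 3L
  rem <- n %% 3L
  sizes <- base + c(rem >= 1L, rem >= 2L, FALSE)
  lev <- rep(c("low", "medium", "high"), times = sizes)
  sorted <- records[ord, , drop = FALSE]
  sorted$circularity_level <- lev
  groups <- split(sorted, factor(lev, levels = c("low", "medium", "high")))
  summary <- do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    r <- if (nrow(d) >= 3L && stats::sd(d$area_auto_mm2) > 0 &&
               stats::sd(d$area_ref_mm2) > 0) {
      pearson_correlation(d$area_auto_mm2, d$area_ref_mm2)
    } else {
      NA_real_
    }
    data.frame(
      circularity_level = g, n = nrow(d), correlation = r,
      mean_jaccard = mean(d$jaccard)
    )
  }))
  rownames(summary) <- NULL
  list(groups = groups, summary = summary)
}

#' Evaluate the pipeline on an image/reference-mask collection
#'
#' Runs [segment_faz()] on every image and compares against its reference
#' mask, producing one evaluation record per image plus per-subgroup
#' summary tables (localization rate, area correlation, mean Jaccard) in
#' the conventional 4-subgroup layout (3/6 mm x superficial/deep).
#'
#' @param images List of [gray_image()] objects.
#' @param references List of logical reference masks, parallel to `images`.
#' @param subgroup Character vector of subgroup labels per image (e.g.
#'   `"3mm-superficial"`); defaults to a single `"all"` group.
#' @param config A [faz_config()] object.
#' @param ids Optional character image identifiers.
#' @return A list with `records` (one data.frame row per image: `image_id`,
#'   `subgroup`, `localized`, `jaccard`, `area_auto_mm2`, `area_ref_mm2`,
#'   `circularity`; Jaccard and biomarkers are `NA` when localization
#'   failed) and `summary` (per subgroup: `n`, `localization_rate`,
#'   `correlation`, `mean_jaccard`, computed over localized records).
#' @export
evaluate_batch <- function(images, references, subgroup = NULL,
                           config = faz_config(), ids = NULL) {
  stopifnot(length(images) == length(references))
  n <- length(images)
  if (is.null(subgroup)) subgroup <- rep("all", n)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_len(n))
  stopifnot(length(subgroup) == n, length(ids) == n)
  rows <- lapply(seq_len(n), function(i) {
    res <- segment_faz(images[[i]], config)
    ref <- as_mask(references[[i]])
    loc <- res$found && localization_success(res$preliminary, ref)
    data.frame(
      image_id = ids[i],
      subgroup = subgroup[i],
      localized = loc,
      jaccard = if (loc) jaccard_index(res$mask, ref) else NA_real_,
      area_auto_mm2 = if (loc) res$area_mm2 else NA_real_,
      area_ref_mm2 = compute_area_mm2(ref, images[[i]]$field_mm),
      circularity = if (loc) res$circularity else NA_real_
    )
  })
  records <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(records, records$subgroup), function(d) {
    ok <- d[d$localized, , drop = FALSE]
    r <- if (nrow(ok) >= 3L && stats::sd(ok$area_auto_mm2) > 0 &&
               stats::sd(ok$area_ref_mm2) > 0) {
      pearson_correlation(ok$area_auto_mm2, ok$area_ref_mm2)
    } else {
      NA_real_
    }
    data.frame(
      subgroup = d$subgroup[1], n = nrow(d),
      localization_rate = mean(d$localized),
      correlation = r,
      mean_jaccard = if (nrow(ok)) mean(ok$jaccard) else NA_real_
    )
  }))
  rownames(summary) <- NULL
  list(records = records, summary = summary)
}
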