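test_that("centroid-in-mask localization handles identity, misses and crescents", {
  ref <- matrix(FALSE, 30, 30)
  ref[10:20, 10:20] <- TRUE
  expect_true(localization_success(ref, ref))

  corner <- matrix(FALSE, 30, 30)
  corner[1:4, 1:4] <- TRUE
  expect_false(localization_success(corner, ref))

  expect_false(localization_success(matrix(FALSE, 30, 30), ref))

  # crescent whose own centroid falls outside itself but inside the reference
  n <- 41
  rr <- matrix(1:n, n, n); cc <- t(rr)
  douter <- sqrt((rr - 21)^2 + (cc - 21)^2)
  dinner <- sqrt((rr - 21)^2 + (cc - 14)^2)
  crescent <- douter <= 18 & dinner > 14
  ctr <- colMeans(which(crescent, arr.ind = TRUE))  # first-moment oracle
  expect_false(crescent[round(ctr[1]), round(ctr[2])])
  reference <- douter <= 18
  expect_true(localization_success(crescent, reference))
})

test_that("Jaccard matches set arithmetic and its algebraic properties", {
  a <- matrix(FALSE, 20, 20); a[3:12, 3:12] <- TRUE
  b <- matrix(FALSE, 20, 20); b[3:12, 8:17] <- TRUE   # 5-px shift
  expect_equal(jaccard_index(a, b), 1 / 3)
  expect_equal(jaccard_index(a, a), 1)
  disj <- matrix(FALSE, 20, 20); disj[15:18, 15:18] <- TRUE
  expect_equal(jaccard_index(a, disj), 0)
  expect_error(jaccard_index(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)), "empty")

  set.seed(81)
  for (i in 1:10) {
    x <- random_mask(15, 15); y <- random_mask(15, 15)
    if (!any(x | y)) next
    j <- jaccard_index(x, y)
    expect_identical(j, jaccard_index(y, x))
    expect_gte(j, 0); expect_lte(j, 1)
  }
})

test_that("Pearson correlation equals the covariance/sd formula", {
  x <- c(0.21, 0.35, 0.48, 0.52, 0.77)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  set.seed(91)
  y <- x + rnorm(5, 0, 0.1)
  direct <- mean((x - mean(x)) * (y - mean(y))) /
    (sqrt(mean((x - mean(x))^2)) * sqrt(mean((y - mean(y))^2)))
  expect_equal(pearson_correlation(x, y), direct, tolerance = 1e-12)
  # invariance under positive affine rescaling
  expect_equal(pearson_correlation(3 * x + 2, y), pearson_correlation(x, y),
               tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), x), "zero variance")
  expect_error(pearson_correlation(x[1:2], x[1:2]), "at least 3")
})

test_that("circularity tertiles partition records with the remainder rule", {
  mk <- function(circ) data.frame(
    circularity = circ, jaccard = circ / 2 + 0.3,
    area_auto_mm2 = circ + 0.1, area_ref_mm2 = circ * 1.05 + 0.1
  )
  nine <- mk(seq(0.1, 0.9, by = 0.1))
  t9 <- circularity_tertiles(nine)
  expect_equal(vapply(t9$groups, nrow, integer(1)),
               c(low = 3L, medium = 3L, high = 3L))
  expect_equal(t9$groups$low$circularity, c(0.1, 0.2, 0.3))

  ten <- mk(seq(0.05, 0.95, by = 0.1))
  t10 <- circularity_tertiles(ten)
  expect_equal(unname(vapply(t10$groups, nrow, integer(1))), c(4L, 3L, 3L))

  # partition: disjoint and exhaustive; pooled mean equals overall mean
  all_rows <- do.call(rbind, t10$groups)
  expect_equal(sort(all_rows$circularity), sort(ten$circularity))
  pooled <- sum(t10$summary$n * t10$summary$mean_jaccard) / sum(t10$summary$n)
  expect_equal(pooled, mean(ten$jaccard), tolerance = 1e-12)

  expect_error(circularity_tertiles(mk(c(0.2, 0.4))), "at least 3")
})
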