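test_that("seed erosion shrinks correctly and falls back gracefully", {
  sq <- matrix(FALSE, 13, 13)
  sq[3:11, 3:11] <- TRUE  # 9x9 solid square
  er <- erode_seed(sq, 2)
  expect_identical(er, oracle_erode(sq * 1, disc_brush(2)) >= 1)
  expected <- matrix(FALSE, 13, 13)
  expected[5:9, 5:9] <- TRUE  # 5x5 centred square
  expect_identical(er, expected)

  tiny <- matrix(FALSE, 10, 10)
  tiny[5:6, 5:6] <- TRUE
  fb <- erode_seed(tiny, 3)
  expect_equal(sum(fb), 1L)
  expect_true(all(fb <= tiny))

  set.seed(51)
  for (i in 1:8) {
    m <- EBImage::dilate(random_mask(20, 20, 0.1) * 1, disc_brush(2)) > 0.5
    if (!any(m)) next
    expect_true(all(erode_seed(m, 2) <= m))
  }
  expect_error(erode_seed(matrix(FALSE, 5, 5), 2), "empty")
})

test_that("region growing fills a dark plateau up to its bright boundary", {
  n <- 40
  rr <- matrix(1:n, n, n); cc <- t(rr)
  d <- sqrt((rr - 20.5)^2 + (cc - 20.5)^2)
  px <- ifelse(d <= 10, 0.1, ifelse(d <= 14, 0.9, 0.1))
  img <- gray_image(px, 3, normalize = FALSE)
  seed <- matrix(FALSE, n, n)
  seed[18:23, 18:23] <- TRUE
  g <- region_grow(img, seed, grow_params())
  expect_identical(g$mask, d <= 10)
  expect_true(g$converged)

  # fixed point: a seed already spanning the uniform region stays put
  g2 <- region_grow(img, d <= 10, grow_params())
  expect_identical(g2$mask, d <= 10)
  expect_lte(g2$iterations, 2L)
})

test_that("a near-degenerate tolerance only admits the uniform plateau", {
  px <- matrix(0.9, 12, 12)
  px[4:9, 4:9] <- 0.4
  px[6, 6] <- 0.41  # off-plateau by more than the tiny tolerance
  img <- gray_image(px, 3, normalize = FALSE)
  seed <- matrix(FALSE, 12, 12)
  seed[5, 5] <- TRUE
  g <- region_grow(img, seed, grow_params(tolerance_frac = 1e-9, abs_floor = 0))
  expected <- px == 0.4
  expected[5, 5] <- TRUE
  expect_identical(g$mask, expected)
})

test_that("seed pixels are anchored and the loop always terminates", {
  set.seed(61)
  for (i in 1:6) {
    ph <- generate_phantom(phantom_spec(size_px = 96, seed = 600 + i))
    enh <- white_tophat(ph$image)
    seed <- erode_seed(ph$mask, 2)
    g <- region_grow(enh, seed, grow_params(max_iterations = 60))
    expect_true(all(g$mask[seed]))
    expect_lte(g$iterations, 60L)
    expect_true(g$converged)
    expect_lt(g$iterations, 50L)
  }
})

test_that("area formula is exact rational arithmetic", {
  expect_equal(compute_area_mm2(matrix(TRUE, 320, 320), 3), 9, tolerance = 1e-12)
  expect_equal(compute_area_mm2(matrix(FALSE, 320, 320), 3), 0)
  m <- matrix(FALSE, 320, 320)
  m[seq_len(11378)] <- TRUE
  expect_equal(compute_area_mm2(m, 3), 11378 * 9 / 102400, tolerance = 1e-12)
})

test_that("circularity closed forms hold", {
  expect_equal(circularity(10^2, 4 * 10), pi / 4, tolerance = 1e-12)
  expect_gte(compute_circularity(disc_mask(50)), 0.95)
  expect_error(compute_circularity(matrix(FALSE, 4, 4)), "empty")
})

test_that("the full pipeline segments phantoms and reports failures honestly", {
  ph <- generate_phantom(phantom_spec(seed = 71, irregularity = 0.25))
  res <- segment_faz(ph$image)
  expect_true(res$found)
  expect_gte(jaccard_index(res$mask, ph$mask), 0.8)
  expect_true(localization_success(res$preliminary, ph$mask))

  # artifact band: FAZ still found, band rejected
  phb <- generate_phantom(phantom_spec(seed = 72, artifact_band = TRUE))
  resb <- segment_faz(phb$image)
  expect_true(resb$found)
  expect_true(localization_success(resb$preliminary, phb$mask))

  # bright featureless field with no avascular zone: localization failure,
  # not a spurious region
  bright <- gray_image(matrix(seq(0, 1, length.out = 160), 160, 160), 3,
                       normalize = FALSE)
  resf <- segment_faz(bright)
  expect_false(resf$found)
  expect_true(is.na(resf$area_mm2))
})
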