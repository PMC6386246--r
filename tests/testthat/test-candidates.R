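test_that("closing seals gaps between nearby edge fragments", {
  m <- matrix(FALSE, 20, 20)
  m[5, 3:17] <- TRUE
  m[9, 3:17] <- TRUE   # parallel lines 3 px apart
  cl <- close_edges(m, 2)
  expect_identical(cl, oracle_close(m * 1, disc_brush(2)) > 0.5)
  expect_true(all(cl[5:9, 5:15]))

  empty <- matrix(FALSE, 12, 12)
  expect_identical(close_edges(empty, 2), empty)

  blob <- disc_mask(5, n = 20)
  expect_identical(close_edges(blob, 2), blob)
})

test_that("inversion plus opening keeps only substantial dark regions", {
  full <- matrix(TRUE, 10, 10)
  expect_false(any(invert_and_open(full, 2)))

  # closed-edge map whose complement holds a 20-px-wide blob and a speck
  closed <- matrix(TRUE, 40, 40)
  closed[10:29, 10:29] <- FALSE  # blob survives opening
  closed[35, 35] <- FALSE        # speck does not
  op <- invert_and_open(closed, 3)
  expect_identical(op, oracle_open((!closed) * 1, disc_brush(3)) > 0.5)
  expect_true(all(op[12:27, 12:27]))
  expect_false(op[35, 35])

  # idempotence of the opening
  again <- EBImage::opening(op * 1, disc_brush(3)) > 0.5
  expect_identical(again, op)
})

test_that("8-connected labelling matches a BFS oracle", {
  diag2 <- matrix(FALSE, 4, 4)
  diag2[2, 2] <- diag2[3, 3] <- TRUE
  expect_equal(max(label_components(diag2)), 1L)

  set.seed(41)
  for (i in 1:12) {
    m <- random_mask(16, 16, runif(1, 0.2, 0.6))
    lab <- label_components(m)
    ref <- oracle_label_bfs(m)
    expect_identical(lab > 0L, m)
    expect_equal(max(lab), max(ref))
    # same partition: every package label maps to exactly one BFS label
    for (k in seq_len(max(lab))) {
      expect_length(unique(ref[lab == k]), 1L)
    }
  }
})

test_that("candidate measurement reports count, centroid and border contact", {
  m <- matrix(FALSE, 10, 10)
  m[4:6, 4:6] <- TRUE
  cands <- label_candidates(m)
  expect_equal(nrow(cands), 1L)
  expect_equal(cands$pixel_count, 9L)
  expect_equal(c(cands$centroid_row, cands$centroid_col), c(5, 5))
  expect_false(cands$touches_border)

  expect_equal(nrow(label_candidates(matrix(FALSE, 5, 5))), 0L)

  m2 <- matrix(FALSE, 8, 8)
  m2[1, 3] <- TRUE
  expect_true(label_candidates(m2)$touches_border)
})

test_that("perimeter estimator is accurate on discs and penalizes thin shapes", {
  d <- disc_mask(50)
  expect_equal(mask_perimeter(d), 2 * pi * 50, tolerance = 0.02)
  bar <- matrix(FALSE, 10, 60)
  bar[5, 6:55] <- TRUE
  expect_lt(compute_circularity(bar), 0.2)
  expect_equal(mask_perimeter(matrix(FALSE, 5, 5)), 0)
})

test_that("peripheral, eccentric and disperse candidates are discarded", {
  img_shape <- c(100, 100)
  m <- matrix(FALSE, 100, 100)
  m[40:60, 40:60] <- TRUE              # central compact blob: retained
  m[2:30, 1:6] <- TRUE                 # artifact-style band on the border
  m[cbind(20:49, 61:90)] <- TRUE       # sparse diagonal chain (disperse)
  cands <- label_candidates(m)
  kept <- remove_false_positives(cands, img_shape)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pixel_count, 21L * 21L)
  # monotonicity: output labels are a subset of input labels
  expect_true(all(kept$label %in% cands$label))
})

test_that("FAZ selection maximizes perimeter with documented tie-breaks", {
  two <- data.frame(
    label = 1:2, pixel_count = c(30L, 200L), perimeter = c(12, 40),
    centroid_row = c(10, 50), centroid_col = c(10, 50),
    min_row = c(8L, 40L), min_col = c(8L, 40L),
    max_row = c(12L, 60L), max_col = c(12L, 60L),
    touches_border = FALSE
  )
  expect_equal(select_faz(two, c(100, 100))$label, 2L)

  tie <- two
  tie$perimeter <- c(40, 40)
  tie$pixel_count <- c(50L, 30L)
  expect_equal(select_faz(tie, c(100, 100))$label, 1L)

  expect_error(select_faz(two[0, ], c(100, 100)), "localization failure")
})
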