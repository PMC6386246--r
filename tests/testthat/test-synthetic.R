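test_that("phantoms are deterministic under a fixed seed", {
  a <- generate_phantom(phantom_spec(size_px = 128, seed = 7))
  b <- generate_phantom(phantom_spec(size_px = 128, seed = 7))
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$mask, b$mask)
  c <- generate_phantom(phantom_spec(size_px = 128, seed = 8))
  expect_false(identical(a$image$pixels, c$image$pixels))
})

test_that("the ground-truth region is avascular (darker than its surround)", {
  for (s in 1:5) {
    style <- if (s %% 2 == 0) "deep" else "superficial"
    ph <- generate_phantom(phantom_spec(size_px = 160, seed = s,
                                        depth_style = style))
    expect_lt(mean(ph$image$pixels[ph$mask]), mean(ph$image$pixels[!ph$mask]))
  }
})

test_that("contour irregularity lowers ground-truth circularity", {
  circ_at <- function(irr) {
    mean(vapply(1:4, function(s) {
      ph <- generate_phantom(phantom_spec(size_px = 160, irregularity = irr,
                                          seed = 300 + s))
      compute_circularity(ph$mask)
    }, numeric(1)))
  }
  ramp <- vapply(c(0, 0.3, 0.6), circ_at, numeric(1))
  expect_gte(ramp[1], 0.95)            # circle limit
  expect_true(all(diff(ramp) < 0))     # monotone decrease
})

test_that("degenerate avascular phantoms are flagged", {
  ph <- generate_phantom(phantom_spec(size_px = 96, vessel_density = 0, seed = 2))
  expect_true(ph$degenerate)
  expect_error(phantom_spec(faz_radius_mm = 2, field_mm = 3), "too large")
})

test_that("suites span both fields with correct physical scaling", {
  suite <- generate_suite(8, base = phantom_spec(size_px = 96), seed = 5)
  expect_length(suite, 8L)
  fields <- vapply(suite, function(p) p$spec$field_mm, numeric(1))
  expect_setequal(unique(fields), c(3, 6))
  subgroups <- vapply(suite, `[[`, "", "subgroup")
  expect_setequal(
    unique(subgroups),
    c("3mm-superficial", "3mm-deep", "6mm-superficial", "6mm-deep")
  )
  # full-frame area equals the physical field area for both zooms
  full <- matrix(TRUE, 96, 96)
  expect_equal(compute_area_mm2(full, 3), 9)
  expect_equal(compute_area_mm2(full, 6), 36)
  # reproducibility of the whole suite
  again <- generate_suite(8, base = phantom_spec(size_px = 96), seed = 5)
  expect_identical(suite[[4]]$image$pixels, again[[4]]$image$pixels)
})
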