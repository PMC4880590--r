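test_that("normalization maps the standards to 0/255 and is idempotent", {
  scan <- small_scan(dpi = 60)
  norm <- normalize_scan(scan)
  for (ch in 1:3) {
    b <- norm$standards$black
    w <- norm$standards$white
    expect_lt(abs(mean(norm$raster[b[1]:b[2], b[3]:b[4], ch]) - 0), 1)
    expect_lt(abs(mean(norm$raster[w[1]:w[2], w[3]:w[4], ch]) - 255), 1)
  }
  twice <- normalize_scan(norm)
  expect_true(max(abs(twice$raster - norm$raster)) <= 1)
})

test_that("normalization applies the documented linear map", {
  # build a raster whose red standards average 50 / 200 and probe DN 125
  r <- array(255, dim = c(40, 60, 3))
  r[1:10, 1:10, ] <- 50
  r[1:10, 20:29, ] <- 200
  r[30, 30, ] <- 125
  scan <- leaf_scan(r, dpi = 50,
                    standards = list(black = c(1, 10, 1, 10),
                                     white = c(1, 10, 20, 29)))
  norm <- normalize_scan(scan)
  expect_equal(norm$raster[30, 30, 1], round(255 * (125 - 50) / (200 - 50)))
  expect_equal(norm$raster[30, 30, 1], 128)
})

test_that("degenerate standards are rejected", {
  r <- array(120, dim = c(40, 60, 3))
  r[1:10, 20:29, ] <- 180
  scan <- leaf_scan(r, dpi = 50,
                    standards = list(black = c(1, 10, 1, 10),
                                     white = c(1, 10, 20, 29)))
  # equalize the standards after construction to hit the error path
  scan$raster[1:10, 20:29, ] <- 120
  expect_error(normalize_scan(scan), class = "leafspad_degenerate_standards")
})

test_that("segmentation recovers the true silhouette and excludes standards", {
  scan <- normalize_scan(small_scan(dpi = 100))
  mask <- segment_leaf(scan)
  truth <- attr(scan, "ground_truth")$mask
  jaccard <- sum(mask & truth) / sum(mask | truth)
  expect_gte(jaccard, 0.98)
  for (rect in scan$standards) {
    expect_false(any(mask[rect[1]:rect[2], rect[3]:rect[4]]))
  }
})

test_that("segmentation of an empty scene errors", {
  r <- array(255, dim = c(50, 80, 3))
  r[1:10, 1:10, ] <- 0
  scan <- leaf_scan(r, dpi = 50,
                    standards = list(black = c(1, 10, 1, 10),
                                     white = c(1, 10, 20, 29)))
  expect_error(segment_leaf(scan), class = "leafspad_empty_segmentation")
})

test_that("width extraction matches ground truth on synthetic renders", {
  dpi <- 100
  scan <- normalize_scan(small_scan(dpi = dpi))
  mask <- segment_leaf(scan)
  shape <- extract_width_profile(mask, dpi)
  px_cm <- 2.54 / dpi
  expect_lt(abs(max(shape$width_cm) - 1.2), 2 * px_cm)
  expect_lt(abs(attr(shape, "length_cm") - 25), 2 * px_cm)
})

test_that("width extraction on a rectangle gives a constant profile", {
  mask <- rectangle_mask()
  shape <- extract_width_profile(mask, dpi = 100, n_stations = 25)
  interior <- shape$width_cm[2:(nrow(shape) - 1)]
  expect_lt(diff(range(interior)), 2.54 / 100 + 1e-9)
  expect_error(extract_width_profile(matrix(FALSE, 5, 5), 100),
               class = "leafspad_empty_segmentation")
})

test_that("slicing partitions the mask into equal axial intervals", {
  mask <- rectangle_mask()
  parts <- slice_segments(mask, 10)
  counts <- tabulate(parts$labels[parts$labels > 0], 10)
  # uniform slab: every part within one transect row of total/10
  rows_per_transect <- sum(mask[, 200])
  expect_true(all(abs(counts - sum(mask) / 10) <= rows_per_transect))
  # partition property
  expect_equal(sum(counts), sum(mask))
  expect_equal(sort(unique(as.vector(parts$labels))), 0:10)

  one <- slice_segments(mask, 1)
  expect_equal(one$labels > 0, mask)
  expect_error(slice_segments(mask, 10000),
               class = "leafspad_invalid_parameter")
})

test_that("slicing a linear-width triangle splits areas 1:3", {
  mask <- triangle_mask()
  # orient the axis so the base is the narrow end: width grows toward the tip
  parts <- slice_segments(mask, 2, base_end = "min_t")
  counts <- tabulate(parts$labels[parts$labels > 0], 2)
  expect_equal(counts[2] / counts[1], 3, tolerance = 0.05)
})

test_that("partition property holds on random blob masks", {
  withr::with_seed(33, {
    for (i in 1:5) {
      sh <- make_leaf_shape(runif(1, 8, 15), runif(1, 0.8, 1.6),
                            runif(1, 0.35, 0.65))
      pf <- make_profile(attr(sh, "length_cm"), 30, 40, 0.5)
      scan <- normalize_scan(
        render_leaf_scan(sh, pf, config = scan_config(dpi = 60)))
      mask <- segment_leaf(scan)
      k <- sample(2:12, 1)
      parts <- slice_segments(mask, k)
      expect_equal(sum(parts$labels > 0), sum(mask))
      expect_true(all(parts$labels[!mask] == 0))
    }
  })
})

test_that("per-part DN means are exact on a uniform leaf", {
  flat <- chl_profile(0, 0, 27.645, length_cm = 10) # red DN 100 exactly
  sh <- make_leaf_shape(10, 1.0, 0.5)
  scan <- normalize_scan(render_leaf_scan(sh, flat,
                                          config = scan_config(dpi = 100)))
  mask <- segment_leaf(scan)
  parts <- slice_segments(mask, 5)
  segs <- segment_dn(scan, parts)
  expect_equal(segs$dn_r, rep(100, 5))
  expect_equal(nrow(segs), 5)
  expect_true(all(segs$area_cm2 > 0))
  # areas from full part pixel counts sum to the mask area
  expect_equal(sum(segs$area_cm2), sum(mask) * (2.54 / 100)^2)
  # over-aggressive exclusion empties a part
  expect_error(segment_dn(scan, parts, erosion_px = 60),
               class = "leafspad_empty_part")
})

test_that("render -> process -> calibrate recovers per-part SPAD within 0.5", {
  sh <- make_leaf_shape(25, 1.2, 0.5)
  pf <- published_profile()
  scan <- normalize_scan(small_scan(dpi = 100, shape = sh, profile = pf))
  mask <- segment_leaf(scan)
  parts <- slice_segments(mask, 10)
  segs <- calibrate_segments(segment_dn(scan, parts))
  truth <- profile_part_means(pf, 10, shape = sh)
  expect_lt(max(abs(segs$spad - truth$spad)), 0.5)
})
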