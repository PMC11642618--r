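test_that("box and cylinder ROIs rasterize by voxel-center inclusion", {
  g <- voxel_grid(array(0, c(5, 5, 5)), 10)
  full <- make_roi(roi_spec("box", box = list(lo = c(0, 0, 0),
                                              hi = c(40, 40, 40))), g)
  expect_true(all(full$mask))
  # cylinder of radius 0.4 voxel centered on a voxel: single column
  cyl <- make_roi(roi_spec("cylinder", cylinder = list(
    axis = 1, center = c(20, 20, 20), radius_um = 4, span_um = 100)), g)
  expect_equal(sum(cyl$mask), 5L)
  expect_true(all(which(cyl$mask, arr.ind = TRUE)[, 2:3] == 3L))
  # out-of-grid box -> empty
  expect_error(make_roi(roi_spec("box", box = list(lo = c(1000, 0, 0),
                                                   hi = c(2000, 40, 40))), g),
               "empty")
})

test_that("contour ROIs fill simple polygons by the even-odd rule", {
  g <- voxel_grid(array(0, c(4, 10, 10)), 10)
  # square spanning voxel centers 20..50 in both plane axes: 4x4 voxels,
  # on 2 slices -> 32 voxels
  sq <- rbind(c(15, 15), c(55, 15), c(55, 55), c(15, 55))
  roi <- make_roi(roi_spec("contours", contours = list(
    list(slice = 1, polygon = sq), list(slice = 3, polygon = sq))), g)
  expect_equal(sum(roi$mask), 32L)
  expect_equal(sum(roi$mask[c(1, 3), , ]), 32L)
  bad <- rbind(c(0, 0), c(40, 40), c(40, 0), c(0, 40))  # bow-tie
  expect_error(make_roi(roi_spec("contours", contours = list(
    list(slice = 1, polygon = bad))), g), "self-intersecting")
})

test_that("threshold_bone applies the inclusive rule in mg HA/cm3", {
  vals <- array(0, c(1, 1, 3)); vals[1, 1, ] <- c(100, 300, 500)
  g <- voxel_grid(vals, 10, calibrated = TRUE)
  roi <- voxel_mask(array(TRUE, c(1, 1, 3)))
  bone <- threshold_bone(g, roi, threshold_spec("global", 300))
  expect_equal(as.vector(bone$mask), c(FALSE, TRUE, TRUE))
  expect_equal(attr(bone, "threshold_mgHA_cm3"), 300)
  # threshold at the ROI minimum saturates to the whole ROI
  bone_all <- threshold_bone(g, roi, threshold_spec("global", 100))
  expect_identical(bone_all$mask, roi$mask)
  raw <- voxel_grid(vals, 10)
  expect_error(threshold_bone(raw, roi, threshold_spec("global", 300)),
               "calibrated")
  expect_warning(threshold_bone(g, roi, threshold_spec("global", 1e6)),
                 "empty bone")
})

test_that("Otsu auto threshold splits a bimodal ROI and is logged", {
  set.seed(21)
  vals <- array(c(rnorm(500, 150, 10), rnorm(500, 600, 10)), c(10, 10, 10))
  g <- voxel_grid(vals, 10, calibrated = TRUE)
  roi <- voxel_mask(array(TRUE, c(10, 10, 10)))
  expect_message(bone <- threshold_bone(g, roi, threshold_spec("auto")),
                 "Otsu.*mg HA/cm3")
  thr <- attr(bone, "threshold_mgHA_cm3")
  expect_gt(thr, 200); expect_lt(thr, 550)
})

test_that("bone masks are nested and anti-tone in the threshold", {
  set.seed(22)
  g <- voxel_grid(array(runif(8 * 8 * 8, 0, 1000), c(8, 8, 8)), 10,
                  calibrated = TRUE)
  roi <- voxel_mask(array(runif(512) > 0.3, c(8, 8, 8)))
  prev <- NULL
  for (t in c(100, 300, 500, 700)) {
    bone <- suppressWarnings(threshold_bone(g, roi,
                                            threshold_spec("global", t)))
    expect_true(all(bone$mask <= roi$mask))        # bone subset of ROI
    if (!is.null(prev)) expect_true(all(bone$mask <= prev))
    prev <- bone$mask
  }
})

test_that("separate_specimens finds, orders and filters components", {
  mp <- generate_multiplex(4, spacing_um = 3500, voxel_size_um = 100)
  masks <- separate_specimens(mp, envelope_threshold = 50)
  expect_length(masks, 4L)
  expect_equal(attr(masks, "n"), 4L)
  # union of masks equals the thresholded support
  un <- Reduce(`|`, lapply(masks, function(m) m$mask))
  expect_identical(un, mp$values >= 50)
  # ordered by left-right position
  zpos <- vapply(masks, function(m) mean(which(m$mask, arr.ind = TRUE)[, 3]),
                 numeric(1))
  expect_false(is.unsorted(zpos))

  single <- generate_multiplex(1, voxel_size_um = 100)
  m1 <- separate_specimens(single, 50)
  expect_length(m1, 1L)
  expect_identical(m1[[1]]$mask, single$values >= 50)

  expect_error(separate_specimens(single, 1e9), "no components")
  # min-volume filter drops the small vertebral spheres if run on bone only
  expect_error(separate_specimens(single, 50, min_volume_um3 = 1e18), "below")
})

test_that("touching bodies merge into one component with a warning", {
  vals <- array(0, c(4, 4, 9))
  vals[2:3, 2:3, 2:4] <- 100   # body A
  vals[2:3, 2:3, 5:7] <- 100   # body B, sharing a face with A
  g <- voxel_grid(vals, 10)
  expect_warning(masks <- separate_specimens(g, 50, n_expected = 2),
                 "merged")
  expect_length(masks, 1L)
})

test_that("qc_cupping: uniform ratio 1, synthetic cupping recovered", {
  fix <- uniform_cylinder_grid(value = 500, radius_um = 200, h = 10)
  rep0 <- qc_cupping(fix$grid, fix$roi)
  expect_lt(abs(rep0$ratio - 1), 1e-6)
  expect_false(rep0$flagged)

  cupped <- add_cupping(fix$grid, gamma = 0.2, axis = 1,
                        center_um = fix$roi$cylinder$center[2:3],
                        radius_um = 200)
  rep1 <- qc_cupping(cupped, fix$roi)
  expect_lt(abs(rep1$ratio - 0.8), 0.02)
  expect_true(rep1$flagged)
  # a loose tolerance suppresses the flag on the same data
  expect_false(qc_cupping(cupped, fix$roi, tolerance = 0.5)$flagged)
  # too-thin cylinder
  thin <- roi_spec("cylinder", cylinder = list(
    axis = 1, center = fix$roi$cylinder$center, radius_um = 5,
    span_um = fix$roi$cylinder$span_um))
  expect_error(qc_cupping(fix$grid, thin), "annuli")
})

test_that("voxel-size adequacy uses the inclusive minimum ratio of two", {
  r <- qc_voxel_ratio(50, 21)
  expect_equal(r$ratio, 50 / 21, tolerance = 1e-12)
  expect_true(r$adequate)
  expect_false(qc_voxel_ratio(20, 20)$adequate)
  expect_true(qc_voxel_ratio(40, 20)$adequate)      # boundary inclusive
  expect_error(qc_voxel_ratio(-1, 10), "positive")
  expect_error(qc_voxel_ratio(10, 0), "positive")
})
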