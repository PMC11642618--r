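test_that("landmark distances and centrum radius", {
  expect_equal(landmark_distance(c(0, 0, 0), c(300, 0, 0)), 300)
  expect_equal(landmark_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(landmark_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(landmark_distance(c(0, 0, NA), c(1, 1, 1)), "finite")
  cr <- centrum_radius(ch_um = 500)
  expect_equal(as.numeric(cr), 250)
  expect_identical(attr(cr, "method"), "approximated")
  crl <- centrum_radius(center = c(0, 0, 0), endplate_point = c(0, 260, 0))
  expect_equal(as.numeric(crl), 260)
  expect_identical(attr(crl, "method"), "landmark")
  expect_error(centrum_radius(ch_um = 0), "positive")
})

test_that("arch angles: canonical cases and degeneracies", {
  ep_c <- c(0, 0, 0); ep_d <- c(100, 0, 0)
  expect_equal(arch_angle(c(0, 0, 0), c(0, -50, 0), ep_c, ep_d), 90)
  expect_equal(arch_angle(c(0, 0, 0), c(50, -50, 0), ep_c, ep_d), 45,
               tolerance = 1e-9)
  expect_warning(a0 <- arch_angle(c(0, 0, 0), c(10, 0, 0), ep_c, ep_d),
                 "degenerate")
  expect_equal(a0, 0)
  expect_error(arch_angle(c(0, 0, 0), c(0, 0, 0), ep_c, ep_d), "zero-length")
})

test_that("arch angle is invariant under rigid rotation", {
  set.seed(41)
  pts <- list(base = c(10, 20, 30), tip = c(200, -150, 60),
              c1 = c(0, 0, 0), c2 = c(400, 30, -20))
  a0 <- arch_angle(pts$base, pts$tip, pts$c1, pts$c2)
  for (i in 1:10) {
    M <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(M) < 0) M[, 1] <- -M[, 1]
    shift <- rnorm(3, 0, 100)
    rot <- lapply(pts, function(p) as.numeric(M %*% p + shift))
    expect_equal(arch_angle(rot$base, rot$tip, rot$c1, rot$c2), a0,
                 tolerance = 1e-6)
  }
})

test_that("canal area: shoelace on the best-fit plane", {
  sq <- rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0), c(0, 100, 0))
  expect_equal(canal_area(sq), 10000)
  expect_equal(canal_area(sq[4:1, ]), 10000)       # orientation-independent
  tri <- rbind(c(0, 0), c(300, 0), c(0, 400))
  expect_equal(canal_area(tri), 60000)
  # same square embedded in a tilted plane
  M <- qr.Q(qr(matrix(c(1, 2, 0.5, -1, 0.3, 2, 0.1, 1, -1), 3)))
  sq3 <- sq %*% t(M) + 50
  expect_equal(canal_area(sq3), 10000, tolerance = 1e-6)
  # non-coplanar and self-intersecting polygons are rejected
  bent <- rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 40), c(0, 100, 0))
  expect_error(canal_area(bent), "coplanar")
  bow <- rbind(c(0, 0, 0), c(100, 100, 0), c(100, 0, 0), c(0, 100, 0))
  expect_error(canal_area(bow), "self-intersecting")
  expect_error(canal_area(sq[1:2, ]), "3 vertices")
})

test_that("landmark scaling: lengths double, areas quadruple, angles fixed", {
  set.seed(42)
  a <- rnorm(3); b <- rnorm(3)
  expect_equal(landmark_distance(2 * a, 2 * b),
               2 * landmark_distance(a, b), tolerance = 1e-12)
  poly <- rbind(c(0, 0, 0), c(120, 0, 0), c(140, 90, 0), c(10, 80, 0))
  expect_equal(canal_area(2 * poly), 4 * canal_area(poly), tolerance = 1e-9)
  ang1 <- arch_angle(c(0, 0, 0), c(30, -40, 10), c(0, 0, 0), c(50, 5, 0))
  ang2 <- arch_angle(c(0, 0, 0), c(60, -80, 20), c(0, 0, 0), c(100, 10, 0))
  expect_equal(ang1, ang2, tolerance = 1e-12)
})

test_that("local thickness equals the exhaustive sphere-fitting oracle", {
  set.seed(43)
  for (i in 1:50) {
    m <- random_blob_mask(sample(6:12, 1), sample(1:4, 1))
    if (!any(m)) next
    fast <- local_thickness(m, 1)
    slow <- oracle_thickness(m, 1)
    expect_equal(fast$thickness_map, slow$thickness_map, tolerance = 1e-9)
    expect_equal(fast$mean_um, slow$mean_um, tolerance = 1e-9)
  }
})

test_that("digital ball thickness is within 5% of its diameter", {
  for (D in c(11, 15, 21)) {
    m <- digital_ball(D)
    mt <- local_thickness(m, 10)$mean_um
    expect_rel_equal(mt, 10 * D, 0.05)
  }
})

test_that("one-voxel plate reports the documented two-voxel thickness", {
  # the distance-to-center model carries a +1 voxel bias at the thinnest
  # scale; the half-voxel diameter correction leaves a uniform 1.5-voxel
  # map on an isolated 1-voxel plate (see the methods vignette)
  pl <- array(FALSE, c(30, 3, 30)); pl[, 2, ] <- TRUE
  lt <- local_thickness(pl, 4)
  inner <- lt$thickness_map[5:26, 2, 5:26]
  expect_true(all(inner == inner[1]))            # no interior edge effects
  expect_equal(inner[1], 1.5 * 4)
  expect_error(local_thickness(array(FALSE, c(2, 2, 2)), 1), "empty")
})

test_that("structure volume: counting, additivity, translation invariance", {
  # 1000 voxels at h = 10 um -> 1.0e6 um^3
  expect_equal(structure_volume(array(TRUE, c(10, 10, 10)), 10), 1e6)
  expect_equal(structure_volume(array(TRUE, c(10, 10, 10)), 1), 1000)
  expect_equal(structure_volume(array(FALSE, c(3, 3, 3)), 10), 0)
  set.seed(44)
  a <- array(runif(512) > 0.5, c(8, 8, 8))
  b <- array(runif(512) > 0.5, c(8, 8, 8)) & !a
  expect_equal(structure_volume(a | b, 7),
               structure_volume(a, 7) + structure_volume(b, 7))
  shifted <- array(FALSE, c(8, 8, 8))
  shifted[2:8, , ] <- a[1:7, , ]
  expect_equal(structure_volume(shifted, 7),
               structure_volume(a[1:7, , , drop = FALSE], 7))
})

test_that("vertebra_summary assembles records and tags methods", {
  lm <- list(endplate_cranial = c(0, 0, 0), endplate_caudal = c(500, 0, 0),
             centrum_dorsal = c(250, -200, 0), centrum_ventral = c(250, 200, 0),
             neural_arch_base = c(250, -200, 0),
             neural_spine_tip = c(250, -600, 0),
             snout_tip = c(0, 0, 0), caudal_fin_base = c(30000, 0, 0))
  g <- voxel_grid(array(0, c(2, 2, 2)), 10)
  vm <- suppressMessages(vertebra_summary(g, landmarks = lm))
  expect_equal(unname(vm$measures["CL"]), 500)
  expect_equal(unname(vm$measures["CH"]), 400)
  expect_equal(unname(vm$measures["CR"]), 200)
  expect_equal(unname(vm$measures["Na.L"]), 400)
  expect_equal(unname(vm$measures["Na.Ang"]), 90)
  expect_equal(unname(vm$measures["SL"]), 30)      # mm
  expect_true(all(vm$methods == "landmark"))
  # segmentation-based fields absent without masks
  expect_false(any(c("CV", "C.Th", "VV") %in% names(vm$measures)))
  # disjoint element masks: VV additive
  d <- c(12, 12, 12)
  mc <- array(FALSE, d); mc[2:5, 2:5, 2:5] <- TRUE
  mn <- array(FALSE, d); mn[8:11, 2:5, 2:5] <- TRUE
  mh <- array(FALSE, d); mh[2:5, 8:11, 8:11] <- TRUE
  vm2 <- suppressMessages(vertebra_summary(
    voxel_grid(array(0, d), 10),
    masks = list(centrum = mc, neural_arch = mn, haemal_arch = mh)))
  expect_equal(unname(vm2$measures["VV"]),
               unname(sum(vm2$measures[c("CV", "Na.V", "Ha.V")])))
  expect_true(all(vm2$methods[c("CV", "V.Th")] == "segmentation"))
})

test_that("landmark CSV round-trips into vertebra_summary input", {
  df <- data.frame(
    name = c("endplate_cranial", "endplate_caudal", rep("neural_canal_polygon", 4)),
    x_um = c(0, 500, 0, 100, 100, 0),
    y_um = c(0, 0, 0, 0, 100, 100),
    z_um = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE)
  lm <- read_landmarks_csv(path)
  expect_equal(as.numeric(lm$endplate_caudal), c(500, 0, 0))
  expect_equal(canal_area(lm$neural_canal_polygon), 10000)
})
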