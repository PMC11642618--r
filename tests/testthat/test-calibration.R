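test_that("two-phantom calibration interpolates exactly", {
  # the conventional 0.25/0.75 g.cm^-3 pair; solving the 2x2 system by hand:
  # slope = (750-250)/(3000-1000) = 0.25, intercept = 250 - 0.25*1000 = 0
  cal <- fit_density_calibration(list(phantom_measurement(250, 1000),
                                      phantom_measurement(750, 3000)))
  expect_equal(cal$slope, 0.25, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-9)
  expect_equal(cal$fit_r2, 1.0)
  expect_equal(cal$n_phantoms, 2L)
  # identity map
  cal2 <- fit_density_calibration(list(phantom_measurement(0, 0),
                                       phantom_measurement(1000, 1000)))
  expect_equal(cal2$slope, 1, tolerance = 1e-12)
  expect_equal(cal2$intercept, 0, tolerance = 1e-9)
})

test_that("calibration fit errors on degenerate input", {
  expect_error(fit_density_calibration(list(phantom_measurement(250, 1000))),
               "two phantoms")
  expect_error(fit_density_calibration(list(phantom_measurement(250, 1000),
                                            phantom_measurement(250, 2000))),
               "distinct")
  expect_error(fit_density_calibration(list(phantom_measurement(250, 1000),
                                            phantom_measurement(750, 1000))),
               "spread")
})

test_that("multi-phantom fit matches the closed-form OLS solution", {
  raw <- c(500, 1500, 2600, 3900)
  dens <- c(120, 390, 660, 980)
  cal <- fit_density_calibration(Map(phantom_measurement, dens, raw))
  # independent closed form
  slope <- sum((raw - mean(raw)) * (dens - mean(dens))) /
    sum((raw - mean(raw))^2)
  intercept <- mean(dens) - slope * mean(raw)
  expect_equal(cal$slope, slope, tolerance = 1e-12)
  expect_equal(cal$intercept, intercept, tolerance = 1e-9)
  expect_gt(cal$fit_r2, 0.999)
})

test_that("apply_calibration is affine, preserves negatives, flags state", {
  cal <- fit_density_calibration(list(phantom_measurement(250, 1000),
                                      phantom_measurement(750, 3000)))
  g <- voxel_grid(array(1000, c(2, 2, 2)), 10)
  out <- apply_calibration(g, cal)
  expect_true(out$calibrated)
  expect_true(all(out$values == 250))
  expect_error(apply_calibration(out, cal), "already calibrated")
  # negative values retained, with a message
  cal_neg <- fit_density_calibration(list(phantom_measurement(0, 1000),
                                          phantom_measurement(500, 2000)))
  g2 <- voxel_grid(array(c(500, 1500), c(1, 1, 2)), 10)
  expect_message(out2 <- apply_calibration(g2, cal_neg), "negative")
  expect_equal(as.vector(out2$values), c(-250, 250))
})

test_that("identity calibration leaves values unchanged", {
  cal <- fit_density_calibration(list(phantom_measurement(0, 0),
                                      phantom_measurement(1000, 1000)))
  set.seed(5)
  g <- voxel_grid(array(runif(27, 0, 800), c(3, 3, 3)), 10)
  expect_equal(apply_calibration(g, cal)$values, g$values)
})

test_that("wedge calibration: interpolation, collinearity, degeneracy", {
  w <- fit_wedge_calibration(data.frame(thickness_mm_al = c(1, 3),
                                        mean_gray = c(100, 300)))
  expect_equal(w$slope * 200 + w$intercept, 2, tolerance = 1e-12)
  w3 <- fit_wedge_calibration(data.frame(t = c(1, 2, 3), g = c(100, 200, 300)))
  expect_equal(w3$fit_r2, 1.0, tolerance = 1e-12)
  expect_error(fit_wedge_calibration(data.frame(t = c(1, 1), g = c(100, 200))),
               "distinct")
  expect_error(fit_wedge_calibration(data.frame(t = 1, g = 100)), "two")
})

test_that("relative aBMD maps ROI means through the wedge line", {
  w <- fit_wedge_calibration(data.frame(t = c(1, 3), g = c(100, 300)))
  img <- radiograph2d(matrix(200, 4, 4), 6)
  roi <- matrix(TRUE, 4, 4)
  v <- relative_abmd(img, roi, w)
  expect_equal(as.numeric(v), 2, tolerance = 1e-12)
  expect_identical(attr(v, "unit"), "mm Al")
  expect_true(attr(v, "relative"))
  # mixed ROI: half at 1 mm-equivalent gray, half at 3 -> mean-then-map = 2
  img2 <- radiograph2d(matrix(c(100, 300), 2, 4), 6)
  expect_equal(as.numeric(relative_abmd(img2, matrix(TRUE, 2, 4), w)), 2,
               tolerance = 1e-12)
  # zeros with identity wedge
  w_id <- fit_wedge_calibration(data.frame(t = c(0, 1), g = c(0, 1)))
  img0 <- radiograph2d(matrix(0, 2, 2), 6)
  expect_equal(as.numeric(relative_abmd(img0, matrix(TRUE, 2, 2), w_id)), 0)
  expect_error(relative_abmd(img, matrix(FALSE, 4, 4), w), "empty")
})

test_that("noisy phantom fits recover the line within 3 standard errors", {
  # noise sigma is a known simulation input, so the standard errors are the
  # exact Gaussian ones (raw noise of sd sigma maps to density residuals of
  # sd slope*sigma); 3 SE then carries its nominal ~99.7% coverage
  true_slope <- 0.25; true_int <- -40
  dens <- c(100, 250, 400, 550, 750)
  sigma <- 30
  hits_slope <- 0L; hits_int <- 0L
  n_sim <- 100L
  set.seed(314)
  for (s in seq_len(n_sim)) {
    raw <- (dens - true_int) / true_slope + rnorm(length(dens), 0, sigma)
    cal <- fit_density_calibration(Map(phantom_measurement, dens, raw))
    sxx <- sum((raw - mean(raw))^2)
    se_slope <- true_slope * sigma / sqrt(sxx)
    se_int <- true_slope * sigma *
      sqrt(1 / length(raw) + mean(raw)^2 / sxx)
    if (abs(cal$slope - true_slope) <= 3 * se_slope)
      hits_slope <- hits_slope + 1L
    if (abs(cal$intercept - true_int) <= 3 * se_int)
      hits_int <- hits_int + 1L
  }
  expect_gte(hits_slope, 97L)
  expect_gte(hits_int, 97L)
})

test_that("calibration JSON round-trips", {
  cal <- fit_density_calibration(list(phantom_measurement(250, 1000),
                                      phantom_measurement(750, 3000)))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_json(cal, path,
                         phantoms = list(phantom_measurement(250, 1000),
                                         phantom_measurement(750, 3000)))
  cal2 <- read_calibration_json(path)
  expect_equal(cal2$slope, cal$slope, tolerance = 1e-12)
  expect_equal(cal2$intercept, cal$intercept, tolerance = 1e-9)
})
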