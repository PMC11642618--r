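test_that("golden manifests pass with completeness 1", {
  for (m in list(example_acquisition_manifest(), example_analysis_manifest())) {
    rep <- check_manifest(m)
    expect_true(rep$passed)
    expect_equal(rep$completeness, 1.0)
    expect_equal(nrow(rep$violations), 0L)
  }
})

test_that("deleting any required field yields exactly one violation naming its row", {
  m <- example_acquisition_manifest()
  # fields whose absence also disables dependent conditionals are skipped in
  # the dependency direction: removing filter_used removes the filter_type
  # requirement too, so drop conditional parents from the single-deletion loop
  parents <- c("multiplexed", "filter_used", "modality")
  for (f in setdiff(names(m), parents)) {
    rep <- check_manifest(m[names(m) != f])
    expect_equal(nrow(rep$violations), 1L, info = f)
    expect_equal(rep$violations$field, f)
    expect_true(nzchar(rep$violations$row))
    expect_false(rep$passed)
    expect_lt(rep$completeness, 1.0)
  }
  # a conditional that is switched off is simply not required
  m2 <- m; m2$multiplexed <- FALSE; m2$n_multiplexed <- NULL
  expect_true(check_manifest(m2)$passed)
  a <- example_analysis_manifest()
  for (f in setdiff(names(a), c("density_measures", "morphometry_mode"))) {
    rep <- check_manifest(a[names(a) != f])
    expect_equal(nrow(rep$violations), 1L, info = f)
    expect_equal(rep$violations$field, f)
  }
  # dropping BMD from the measures removes the ROI-description requirement
  a2 <- a; a2$density_measures <- list("TMD"); a2$bmd_roi_description <- NULL
  expect_true(check_manifest(a2)$passed)
})

test_that("type violations are reported as ill-typed", {
  m <- example_acquisition_manifest()
  m$tube_potential_kv <- "fifty-five"
  rep <- check_manifest(m)
  expect_equal(rep$violations$problem, "ill-typed")
  expect_match(rep$violations$row, "tube potential")
  a <- example_analysis_manifest()
  a$sex <- "unknown"
  expect_equal(check_manifest(a)$violations$field, "sex")
})

test_that("lenient mode demotes strain/sex/controls to warnings", {
  a <- example_analysis_manifest()
  a$strain <- NULL; a$sex <- NULL; a$controls <- NULL
  strict <- check_manifest(a)
  expect_equal(nrow(strict$violations), 3L)
  lenient <- check_manifest(a, lenient = TRUE)
  expect_true(lenient$passed)
  expect_equal(nrow(lenient$warnings), 3L)
  expect_equal(lenient$completeness, 1.0)
})

test_that("manifest checking is idempotent and order-independent", {
  m <- example_acquisition_manifest()
  r1 <- check_manifest(m)
  r2 <- check_manifest(m[sample(names(m))])
  expect_equal(r1$completeness, r2$completeness)
  expect_equal(r1$n_required, r2$n_required)
  # from JSON file, identically
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(m, path, auto_unbox = TRUE)
  expect_true(check_manifest(path)$passed)
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad)
  expect_error(check_manifest(bad), "malformed JSON")
})

test_that("modality selects the applicable schema rows", {
  x <- list(modality = "xray2d",
            sample_preparation = "freshly euthanized", in_vivo = TRUE,
            whole_animal = TRUE, medium = "air",
            tube_potential_kv = 45, tube_current_ua = 400,
            filter_used = FALSE, exposure_s = 10, frames_averaged = 1L,
            source_distance_cm = 30, pixel_or_voxel_size_um = 6,
            detector_description = "100 mm, 12 MP",
            calibration_method = "aluminum step wedge",
            machine_make_model = "cabinet system")
  rep <- check_manifest(x)
  expect_true(rep$passed)
  # 3D-only rows must not be demanded of a 2D manifest
  expect_false(any(grepl("integration", rep$violations$row)))
})

test_that("unit normalization converts to canonical reporting units", {
  expect_equal(as.numeric(normalize_units("tube_potential_kv", "45 kV")), 45)
  expect_equal(as.numeric(normalize_units("tube_current_ua", "0.2 mA")), 200)
  expect_equal(as.numeric(normalize_units("integration_ms", "10 s")), 10000)
  expect_equal(as.numeric(normalize_units("density_mgHA_cm3", "0.75 g.cm^-3")),
               750)
  expect_equal(as.numeric(normalize_units("pixel_or_voxel_size_um", "0.021 mm")),
               21)
  expect_equal(as.numeric(normalize_units("standard_length_mm", "3 cm")), 30)
  expect_identical(attr(normalize_units("exposure_s", "4 s"), "unit"), "s")
  expect_error(normalize_units("tube_potential_kv", "45 mA"), "not valid")
  expect_error(normalize_units("no_such_field", "1 s"), "unknown field")
})

test_that("unit normalization round-trips through formatting", {
  set.seed(71)
  for (field in c("tube_potential_kv", "tube_current_ua", "integration_ms",
                  "exposure_s", "pixel_or_voxel_size_um",
                  "standard_length_mm", "density_mgHA_cm3")) {
    v <- round(runif(1, 0.1, 900), 6)
    expect_equal(as.numeric(normalize_units(field, format_units(field, v))),
                 v, tolerance = 1e-12)
  }
})

test_that("schema row sets mirror the reporting tables bijectively", {
  acq <- finmorph:::report_schema("acquisition")
  ana <- finmorph:::report_schema("analysis")
  acq_fields <- vapply(acq$fields, `[[`, "", "field")
  ana_fields <- vapply(ana$fields, `[[`, "", "field")
  expect_false(anyDuplicated(acq_fields) > 0)
  expect_false(anyDuplicated(ana_fields) > 0)
  acq_rows <- vapply(acq$fields, `[[`, "", "row")
  ana_rows <- vapply(ana$fields, `[[`, "", "row")
  expect_false(anyDuplicated(acq_rows) > 0)
  expect_false(anyDuplicated(ana_rows) > 0)
  # one schema entry per reporting-table row for the declared scope:
  # 19 acquisition rows (+ the modality selector) and 16 analysis rows
  expect_length(acq_fields, 20L)
  expect_length(ana_fields, 16L)
})
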