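# Density calibration: raw attenuation values -> attenuation-equivalent
# hydroxyapatite concentration. Routine practice uses two CaHA rods
# (recommended densities 250 and 750 mg HA/cm3, 2-4 mm diameter) scanned
# with the same parameters as the specimens; the mapping is affine and two
# phantoms determine it exactly. 2D radiographs are calibrated against an
# aluminum step wedge and yield only relative areal density, in mm of
# aluminum equivalent thickness.

#' Phantom measurement
#'
#' One calibration rod: its known hydroxyapatite density and the mean raw
#' value observed inside its ROI.
#'
#' @param known_density_mgHA_cm3 known density, mg HA/cm3 (>= 0).
#' @param mean_raw_value mean raw attenuation value in the phantom ROI.
#' @return An object of class `phantom_measurement`.
#' @export
phantom_measurement <- function(known_density_mgHA_cm3, mean_raw_value) {
  if (!is.finite(known_density_mgHA_cm3) || known_density_mgHA_cm3 < 0)
    stop("known density must be a non-negative scalar", call. = FALSE)
  if (!is.finite(mean_raw_value)) stop("mean raw value must be finite", call. = FALSE)
  structure(list(known_density_mgHA_cm3 = known_density_mgHA_cm3,
                 mean_raw_value = mean_raw_value),
            class = "phantom_measurement")
}

#' Fit a density calibration line from CaHA phantoms
#'
#' Ordinary least squares of known density on mean raw value:
#' density = slope * raw + intercept. With exactly two phantoms the line
#' interpolates both points; r-squared is 1 by construction then.
#'
#' @param phantoms list of [phantom_measurement()] (or 2-element lists with
#'   the same field names); at least two, with distinct known densities and
#'   non-degenerate raw-value spread.
#' @return An object of class `density_calibration` with fields `slope`
#'   (mg HA/cm3 per raw unit), `intercept` (mg HA/cm3), `n_phantoms`,
#'   `fit_r2`.
#' @export
fit_density_calibration <- function(phantoms) {
  if (length(phantoms) < 2L)
    stop("at least two phantoms are required", call. = FALSE)
  dens <- vapply(phantoms, function(p) p$known_density_mgHA_cm3, numeric(1))
  raw <- vapply(phantoms, function(p) p$mean_raw_value, numeric(1))
  if (anyDuplicated(dens))
    stop("phantom densities must be distinct", call. = FALSE)
  if (diff(range(raw)) == 0)
    stop("zero raw-value spread across phantoms", call. = FALSE)
  fit <- stats::lm(dens ~ raw)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  r2 <- if (length(raw) == 2L) 1.0 else summary(fit)$r.squared
  if (slope == 0) stop("degenerate calibration: zero slope", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 n_phantoms = length(phantoms), fit_r2 = r2),
            class = "density_calibration")
}

#' @export
print.density_calibration <- function(x, ...) {
  cat(sprintf(
    "<density_calibration> density = %.6g * raw + %.6g mg HA/cm3 (n = %d, r2 = %.4f)\n",
    x$slope, x$intercept, x$n_phantoms, x$fit_r2))
  invisible(x)
}

#' Apply a density calibration to a raw volume
#'
#' Voxelwise affine transform into mg HA/cm3. Negative outputs are kept,
#' not clamped: dehydrated soft tissue or air in the ROI legitimately yields
#' values below zero, and hiding them would mask a QC problem. A message is
#' emitted when negatives are produced.
#'
#' @param grid an uncalibrated [voxel_grid()].
#' @param cal a `density_calibration`.
#' @return A calibrated [voxel_grid()] in mg HA/cm3.
#' @export
apply_calibration <- function(grid, cal) {
  stopifnot_grid(grid)
  if (grid$calibrated)
    stop("grid is already calibrated", call. = FALSE)
  if (!inherits(cal, "density_calibration"))
    stop("expected a density_calibration", call. = FALSE)
  vals <- cal$slope * grid$values + cal$intercept
  if (any(vals < 0))
    message(sprintf("apply_calibration: %d voxels map to negative density (retained)",
                    sum(vals < 0)))
  voxel_grid(vals, grid$voxel_size_um, calibrated = TRUE)
}

#' Fit an aluminum wedge calibration for 2D radiographs
#'
#' Least-squares line mapping gray value to aluminum-equivalent thickness
#' (mm Al). Exact through two steps; r-squared 1 for collinear steps.
#'
#' @param steps a data.frame or matrix with columns `thickness_mm_al` and
#'   `mean_gray` (or a 2-column numeric object in that order); at least two
#'   distinct thicknesses.
#' @return An object of class `wedge_calibration` with `slope` (mm Al per
#'   gray unit), `intercept` (mm Al), `steps`, `fit_r2`.
#' @export
fit_wedge_calibration <- function(steps) {
  steps <- as.data.frame(steps)
  if (ncol(steps) < 2) stop("steps need thickness and gray columns", call. = FALSE)
  names(steps)[1:2] <- c("thickness_mm_al", "mean_gray")
  if (nrow(steps) < 2L) stop("at least two wedge steps required", call. = FALSE)
  if (anyDuplicated(steps$thickness_mm_al))
    stop("wedge thicknesses must be distinct", call. = FALSE)
  if (diff(range(steps$mean_gray)) == 0)
    stop("zero gray-value spread across wedge steps", call. = FALSE)
  fit <- stats::lm(thickness_mm_al ~ mean_gray, data = steps)
  # collinear step wedges are a legitimate (indeed ideal) input; silence the
  # perfect-fit warning from summary()
  r2 <- if (nrow(steps) == 2L) 1.0 else
    suppressWarnings(summary(fit)$r.squared)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 steps = steps, fit_r2 = r2),
            class = "wedge_calibration")
}

#' Relative areal BMD of a radiograph ROI, in mm Al equivalent
#'
#' Mean gray value in the ROI mapped through the wedge line. 2D projections
#' integrate attenuation along the beam, so the result is a relative measure
#' only and is labeled as such; it is never expressed in mg HA/cm3.
#'
#' @param image a [radiograph2d()].
#' @param roi_mask logical matrix congruent with `image`.
#' @param wedge a `wedge_calibration`.
#' @return Scalar mm-Al-equivalent thickness with attributes `unit`
#'   (`"mm Al"`) and `relative = TRUE`.
#' @export
relative_abmd <- function(image, roi_mask, wedge) {
  if (!inherits(image, "radiograph2d")) stop("expected a radiograph2d", call. = FALSE)
  if (!inherits(wedge, "wedge_calibration"))
    stop("expected a wedge_calibration", call. = FALSE)
  if (!is.logical(roi_mask)) storage.mode(roi_mask) <- "logical"
  if (!identical(dim(image$values), dim(roi_mask)))
    stop("ROI mask shape does not match image", call. = FALSE)
  if (!any(roi_mask)) stop("empty ROI", call. = FALSE)
  g <- mean(image$values[roi_mask])
  structure(wedge$slope * g + wedge$intercept, unit = "mm Al", relative = TRUE)
}

#' Read/write calibration JSON
#'
#' The interchange format stores the phantom list alongside the fitted line:
#' `{"phantoms":[{"density_mgHA_cm3":..,"mean_raw":..}],"slope":..,"intercept":..}`.
#'
#' @param cal a `density_calibration`.
#' @param phantoms optional list of [phantom_measurement()] to embed.
#' @param path JSON file path.
#' @return `write_calibration_json`: `path` invisibly;
#'   `read_calibration_json`: a `density_calibration`.
#' @export
write_calibration_json <- function(cal, path, phantoms = NULL) {
  obj <- list(slope = cal$slope, intercept = cal$intercept,
              n_phantoms = cal$n_phantoms, fit_r2 = cal$fit_r2)
  if (!is.null(phantoms))
    obj$phantoms <- lapply(phantoms, function(p)
      list(density_mgHA_cm3 = p$known_density_mgHA_cm3,
           mean_raw = p$mean_raw_value))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$slope) || is.null(obj$intercept)) {
    phantoms <- lapply(seq_len(nrow(obj$phantoms)), function(i)
      phantom_measurement(obj$phantoms$density_mgHA_cm3[i],
                          obj$phantoms$mean_raw[i]))
    return(fit_density_calibration(phantoms))
  }
  structure(list(slope = obj$slope, intercept = obj$intercept,
                 n_phantoms = if (is.null(obj$n_phantoms)) 2L else obj$n_phantoms,
                 fit_r2 = if (is.null(obj$fit_r2)) 1.0 else obj$fit_r2),
            class = "density_calibration")
}
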