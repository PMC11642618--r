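#' Voxel grid container
#'
#' The shared 3D data model for uCT volumes. Values are either raw detector
#' units or calibrated attenuation-equivalent hydroxyapatite concentration
#' (mg HA/cm3). Voxels are isotropic cubes; anisotropic spacing is rejected
#' because the thickness and volume definitions used throughout assume one
#' edge length.
#'
#' Axis convention (fixed, documented rather than stored in files):
#' array dimension 1 runs cranial to caudal, dimension 2 dorsal to ventral,
#' dimension 3 left to right. Coordinates are voxel-center based and
#' zero-based: physical coordinate (um) = index0 * voxel_size_um.
#'
#' @param values numeric 3D array.
#' @param voxel_size_um isotropic voxel edge length in micrometres (> 0).
#' @param calibrated logical; `TRUE` once values are in mg HA/cm3.
#' @param units_label `"raw"` or `"mgHA/cm3"`; must agree with `calibrated`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, voxel_size_um, calibrated = FALSE,
                       units_label = if (calibrated) "mgHA/cm3" else "raw") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("all three extents must be positive", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar", call. = FALSE)
  if (isTRUE(calibrated) && units_label != "mgHA/cm3")
    stop("calibrated grids must carry units_label \"mgHA/cm3\"", call. = FALSE)
  if (!units_label %in% c("raw", "mgHA/cm3"))
    stop("units_label must be \"raw\" or \"mgHA/cm3\"", call. = FALSE)
  structure(
    list(values = values, voxel_size_um = as.numeric(voxel_size_um),
         calibrated = isTRUE(calibrated), units_label = units_label),
    class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d voxels @ %g um [%s]\n",
              d[1], d[2], d[3], x$voxel_size_um, x$units_label))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$values)

is_voxel_grid <- function(x) inherits(x, "voxel_grid")

stopifnot_grid <- function(grid) {
  if (!is_voxel_grid(grid)) stop("expected a voxel_grid", call. = FALSE)
  invisible(grid)
}

#' Voxel mask
#'
#' A boolean mask congruent with a [voxel_grid()], used either as an ROI
#' (the denominator of BMD and BV/TV) or as a bone mask (thresholded voxels).
#'
#' @param mask logical 3D array.
#' @param kind `"roi"` or `"bone"`.
#' @return An object of class `voxel_mask`.
#' @export
voxel_mask <- function(mask, kind = c("roi", "bone")) {
  kind <- match.arg(kind)
  if (is.numeric(mask)) {
    storage.mode(mask) <- "logical"
  }
  if (!is.array(mask) || length(dim(mask)) != 3L || !is.logical(mask))
    stop("`mask` must be a logical 3D array", call. = FALSE)
  structure(list(mask = mask, kind = kind), class = "voxel_mask")
}

#' @export
print.voxel_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("<voxel_mask:%s> %d x %d x %d, %d voxels set\n",
              x$kind, d[1], d[2], d[3], sum(x$mask)))
  invisible(x)
}

as_mask_array <- function(mask) {
  if (inherits(mask, "voxel_mask")) return(mask$mask)
  if (is.array(mask) && length(dim(mask)) == 3L) {
    storage.mode(mask) <- "logical"
    return(mask)
  }
  stop("expected a voxel_mask or logical 3D array", call. = FALSE)
}

check_congruent <- function(grid, mask) {
  m <- as_mask_array(mask)
  if (!identical(dim(grid$values), dim(m)))
    stop("mask shape does not match grid shape", call. = FALSE)
  m
}

#' 2D radiograph container
#'
#' Holds a 2D gray-value image (X-ray radiograph or an intensity projection
#' of a volume) with its pixel size. By the display convention used for fish
#' imaging, column 1 is the anterior end and row 1 is dorsal.
#'
#' @param values numeric matrix.
#' @param pixel_size_um positive scalar pixel edge (um).
#' @return An object of class `radiograph2d`.
#' @export
radiograph2d <- function(values, pixel_size_um) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a positive scalar", call. = FALSE)
  structure(list(values = values, pixel_size_um = as.numeric(pixel_size_um)),
            class = "radiograph2d")
}

#' @export
print.radiograph2d <- function(x, ...) {
  cat(sprintf("<radiograph2d> %d x %d px @ %g um\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um))
  invisible(x)
}

#' Intensity projection of a volume
#'
#' Collapses a volume along the left-right axis (lateral view) or the
#' dorsal-ventral axis (dorsal view). `mode = "max"` gives the maximum
#' intensity projection (shows peak TMD along each ray); `mode = "mean"`
#' resembles a conventional radiograph. Output follows the presentation
#' convention: anterior end on the left, dorsal side up.
#'
#' @param grid a [voxel_grid()].
#' @param mode `"max"` or `"mean"`.
#' @param view `"lateral"` (project along axis 3) or `"dorsal"` (axis 2).
#' @return A [radiograph2d()] whose pixel size equals the voxel size.
#' @export
export_projection <- function(grid, mode = c("max", "mean"),
                              view = c("lateral", "dorsal")) {
  stopifnot_grid(grid)
  mode <- match.arg(mode)
  view <- match.arg(view)
  axis <- if (view == "lateral") 3L else 2L
  fun <- if (mode == "max") max else mean
  keep <- setdiff(1:3, axis)
  proj <- apply(grid$values, keep, fun)
  # proj rows = cranial->caudal, cols = dorsal->ventral (lateral) or
  # left->right (dorsal). Display wants anterior left (columns) and, for the
  # lateral view, dorsal on top (rows): transpose so rows run down the fish.
  radiograph2d(t(proj), pixel_size_um = grid$voxel_size_um)
}
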