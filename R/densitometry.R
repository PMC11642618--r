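# Volumetric densitometry. Two distinct density measures:
#   BMD — mean attenuation-equivalent hydroxyapatite concentration over ALL
#         voxels of an ROI (bone + soft tissue); depends on the ROI, whose
#         volume is the denominator.
#   TMD — the same mean restricted to bone voxels; invariant under ROI
#         enlargement that adds only non-bone voxels.
# BV/TV is the bone volume fraction of the ROI. The three satisfy the exact
# decomposition BMD = BVTV*TMD + (1-BVTV)*mean(non-bone), which
# density_report() asserts on every call.

#' Volumetric BMD of an ROI
#'
#' Arithmetic mean of all calibrated voxel values inside the ROI, bone and
#' non-bone alike. No thresholding is involved. Negative results are
#' possible (dehydrated soft tissue, trapped air) and are returned as-is.
#'
#' @param grid a calibrated [voxel_grid()].
#' @param roi a non-empty [voxel_mask()].
#' @return Scalar BMD in mg HA/cm3.
#' @export
compute_bmd <- function(grid, roi) {
  stopifnot_grid(grid)
  if (!grid$calibrated) stop("BMD requires a calibrated grid", call. = FALSE)
  m <- check_congruent(grid, roi)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  mean(grid$values[m])
}

#' TMD of a bone mask
#'
#' Mean calibrated value over bone voxels only.
#'
#' @param grid a calibrated [voxel_grid()].
#' @param bone a non-empty bone [voxel_mask()].
#' @return Scalar TMD in mg HA/cm3.
#' @export
compute_tmd <- function(grid, bone) {
  stopifnot_grid(grid)
  if (!grid$calibrated) stop("TMD requires a calibrated grid", call. = FALSE)
  m <- check_congruent(grid, bone)
  if (!any(m)) stop("empty bone mask", call. = FALSE)
  mean(grid$values[m])
}

#' Bone volume fraction
#'
#' BV = n_bone * h^3, TV = n_roi * h^3 (total ROI volume), BVTV = BV/TV.
#'
#' @param bone bone [voxel_mask()], subset of `roi`.
#' @param roi non-empty ROI [voxel_mask()].
#' @param voxel_size_um isotropic voxel size (um).
#' @return List with `bv_um3`, `tv_um3`, `bvtv`.
#' @export
compute_bvtv <- function(bone, roi, voxel_size_um) {
  b <- as_mask_array(bone)
  r <- as_mask_array(roi)
  if (!identical(dim(b), dim(r))) stop("mask shapes differ", call. = FALSE)
  if (!any(r)) stop("empty ROI", call. = FALSE)
  if (any(b & !r)) stop("bone mask is not a subset of the ROI", call. = FALSE)
  h3 <- voxel_size_um^3
  nb <- sum(b); nr <- sum(r)
  list(bv_um3 = nb * h3, tv_um3 = nr * h3, bvtv = nb / nr)
}

#' Full density report for one ROI
#'
#' Thresholds the ROI, computes BMD, TMD and BV/TV, and verifies the exact
#' decomposition BMD = BVTV*TMD + (1-BVTV)*mean(non-bone ROI voxels) to 1e-9
#' relative as an internal consistency check. Flags negative BMD (suspect
#' dehydration or air) and empty bone masks.
#'
#' @param grid a calibrated [voxel_grid()].
#' @param roi a non-empty [voxel_mask()].
#' @param spec a [threshold_spec()].
#' @return A `density_result` list: `bmd_mgHA_cm3`, `tmd_mgHA_cm3`,
#'   `bv_um3`, `tv_um3`, `bvtv`, `n_roi_voxels`, `n_bone_voxels`,
#'   `threshold_used_mgHA_cm3`, `flags`.
#' @export
density_report <- function(grid, roi, spec) {
  stopifnot_grid(grid)
  m <- check_congruent(grid, roi)
  bone <- suppressWarnings(threshold_bone(grid, roi, spec))
  thr <- attr(bone, "threshold_mgHA_cm3")
  b <- bone$mask
  flags <- character(0)
  bmd <- compute_bmd(grid, roi)
  nb <- sum(b); nr <- sum(m)
  h <- grid$voxel_size_um
  vol <- compute_bvtv(b, m, h)
  if (nb > 0) {
    tmd <- compute_tmd(grid, bone)
    nonbone_mean <- if (nb < nr) mean(grid$values[m & !b]) else 0
    recomposed <- vol$bvtv * tmd + (1 - vol$bvtv) * nonbone_mean
    if (abs(recomposed - bmd) > 1e-9 * max(1, abs(bmd)))
      stop("internal decomposition check failed", call. = FALSE)
  } else {
    tmd <- NA_real_
    flags <- c(flags, "empty bone mask at this threshold")
  }
  if (bmd < 0) flags <- c(flags, "negative BMD - suspect dehydration/air")
  structure(
    list(bmd_mgHA_cm3 = bmd, tmd_mgHA_cm3 = tmd,
         bv_um3 = vol$bv_um3, tv_um3 = vol$tv_um3, bvtv = vol$bvtv,
         n_roi_voxels = nr, n_bone_voxels = nb,
         threshold_used_mgHA_cm3 = thr, flags = flags),
    class = "density_result")
}

#' @export
print.density_result <- function(x, ...) {
  cat(sprintf(
    "<density_result> BMD %.4g, TMD %.4g mg HA/cm3 | BV/TV %.4g (threshold %.4g)\n",
    x$bmd_mgHA_cm3, x$tmd_mgHA_cm3, x$bvtv, x$threshold_used_mgHA_cm3))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' One-row data frame for tidy result tables
#'
#' @param x a `density_result`.
#' @param ... unused.
#' @return data.frame with columns BMD, TMD, BV, TV, BVTV, threshold, flags.
#' @export
as.data.frame.density_result <- function(x, ...) {
  data.frame(BMD = x$bmd_mgHA_cm3, TMD = x$tmd_mgHA_cm3, BV = x$bv_um3,
             TV = x$tv_um3, BVTV = x$bvtv,
             threshold = x$threshold_used_mgHA_cm3,
             flags = paste(x$flags, collapse = "; "),
             stringsAsFactors = FALSE)
}
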