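# The standard vertebral measurement suite: landmark-based lengths, angles
# and canal areas, plus segmentation-based thickness and volume. Measure
# abbreviations follow the conventional spine nomenclature (CL, CH, CR,
# C.Th, CV, CTV, Na.*, Ha.*, Nc.A, V.Th, VV, SL). All thicknesses are
# lengths in um (the occasional um^2 seen in print for centrum thickness is
# a typo; a thickness is a length).

#' Euclidean distance between two landmarks
#'
#' @param a,b numeric 3-vectors (um).
#' @return Distance in um.
#' @export
landmark_distance <- function(a, b) {
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("landmarks must be finite", call. = FALSE)
  sqrt(sum((as.numeric(a) - as.numeric(b))^2))
}

#' Centrum radius
#'
#' Either approximated as half the centrum height or measured directly as
#' the distance from the notochord-canal center to the endplate.
#'
#' @param ch_um centrum height (um, > 0); used when `center`/`endplate_point`
#'   are absent.
#' @param center,endplate_point optional landmark pair for the direct
#'   variant.
#' @return Radius in um with attribute `method` (`"approximated"` or
#'   `"landmark"`).
#' @export
centrum_radius <- function(ch_um = NULL, center = NULL, endplate_point = NULL) {
  if (!is.null(center) && !is.null(endplate_point)) {
    return(structure(landmark_distance(center, endplate_point),
                     method = "landmark"))
  }
  if (is.null(ch_um) || !is.finite(ch_um) || ch_um <= 0)
    stop("centrum height must be positive", call. = FALSE)
  structure(ch_um / 2, method = "approximated")
}

#' Arch angle against the cranial-caudal axis
#'
#' Undirected angle between the arch-base-to-spine-tip segment and the
#' endplate-to-endplate segment, via the arccosine of the normalized dot
#' product; reported in (0, 180] degrees. Parallel segments give 0 with a
#' degeneracy warning rather than an error.
#'
#' @param arch_base,spine_tip,endplate_cranial,endplate_caudal numeric
#'   3-vectors (um).
#' @return Angle in degrees.
#' @export
arch_angle <- function(arch_base, spine_tip, endplate_cranial, endplate_caudal) {
  u <- as.numeric(spine_tip) - as.numeric(arch_base)
  v <- as.numeric(endplate_caudal) - as.numeric(endplate_cranial)
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("zero-length segment", call. = FALSE)
  cosang <- sum(u * v) / (nu * nv)
  cosang <- min(1, max(-1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (ang == 0) warning("degenerate (parallel) segments: angle 0", call. = FALSE)
  ang
}

#' Area of a planar canal polygon
#'
#' Projects the (nearly) coplanar vertices onto their best-fit plane and
#' applies the shoelace formula; orientation-independent absolute area.
#'
#' @param polygon n x 3 (or n x 2) matrix of ordered vertices (um); n >= 3,
#'   simple, coplanar within `tol` relative to the polygon extent.
#' @param tol coplanarity tolerance as a fraction of the bounding size.
#' @return Area in um^2.
#' @export
canal_area <- function(polygon, tol = 1e-6) {
  poly <- as.matrix(polygon)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices", call. = FALSE)
  if (ncol(poly) == 2) poly <- cbind(poly, 0)
  ctr <- colMeans(poly)
  x <- sweep(poly, 2, ctr)
  sv <- svd(x)
  extent <- max(sv$d)
  if (extent == 0) stop("degenerate polygon", call. = FALSE)
  if (sv$d[3] > tol * extent)
    stop("polygon vertices are not coplanar", call. = FALSE)
  p2 <- x %*% sv$v[, 1:2]
  if (!polygon_is_simple(p2))
    stop("polygon is self-intersecting", call. = FALSE)
  n <- nrow(p2)
  j <- c(2:n, 1)
  abs(sum(p2[, 1] * p2[j, 2] - p2[j, 1] * p2[, 2])) / 2
}

#' Local thickness by maximal inscribed spheres
#'
#' Model thickness of a binary structure: each voxel is assigned the
#' diameter of the largest sphere that both fits inside the structure and
#' contains the voxel, and the structure thickness is the unweighted mean of
#' this map over bone voxels. Implemented as an exact Euclidean distance
#' transform (distance to the nearest background voxel center, with the
#' volume padded by one background layer so structures touching the grid
#' edge stay finite) followed by sphere painting. Radii run center-to-center
#' (the canonical uncorrected model), which carries a known upward bias of
#' about one voxel at the thinnest scale: a one-voxel plate reports a
#' thickness of two voxels. Keep features at three voxels and above (the
#' voxel-adequacy rule) for accurate means.
#'
#' @param bone a non-empty [voxel_mask()] or logical 3D array.
#' @param voxel_size_um isotropic voxel size (um).
#' @return List with `thickness_map` (um; 0 outside bone) and `mean_um`.
#' @export
local_thickness <- function(bone, voxel_size_um) {
  m <- as_mask_array(bone)
  if (!any(m)) stop("empty mask", call. = FALSE)
  d <- dim(m)
  th <- local_thickness_cpp(as.logical(m), d) * voxel_size_um
  th <- array(th, dim = d)
  list(thickness_map = th, mean_um = mean(th[m]))
}

#' Structure volume from a bone mask
#'
#' Voxel count times the voxel volume.
#'
#' @param bone a [voxel_mask()] or logical 3D array.
#' @param voxel_size_um isotropic voxel size (um).
#' @return Volume in um^3.
#' @export
structure_volume <- function(bone, voxel_size_um) {
  m <- as_mask_array(bone)
  sum(m) * voxel_size_um^3
}

MEASURE_UNITS <- c(
  SL = "mm", CL = "um", CH = "um", CR = "um", C.Th = "um", CV = "um3",
  CTV = "um3", Na.L = "um", Na.Th = "um", Na.V = "um3", Na.Ang = "deg",
  Nc.A = "um2", Ha.L = "um", Ha.Th = "um", Ha.V = "um3", Ha.Ang = "deg",
  Ha.A = "um2", V.Th = "um", VV = "um3")

#' Assemble a per-vertebra measurement record
#'
#' Fills every computable field of the standard suite from whatever inputs
#' are present; missing inputs leave fields absent (with a log message), not
#' an error. Landmark-based fields come from `landmarks`, a named list of
#' 3-vectors (um) with names among: `endplate_cranial`, `endplate_caudal`,
#' `centrum_dorsal`, `centrum_ventral`, `neural_arch_base`,
#' `neural_spine_tip`, `haemal_arch_base`, `haemal_spine_tip`,
#' `neural_canal_polygon` (n x 3 matrix), `haemal_canal_polygon`,
#' `snout_tip`, `caudal_fin_base`. Segmentation-based fields come from
#' `masks`, a named list with any of `centrum`, `neural_arch`,
#' `haemal_arch`. V.Th and VV are computed on the union mask; CTV is the
#' volume of `ctv_roi` (centrum plus surrounding soft tissue).
#'
#' @param grid a [voxel_grid()] (used for the voxel size).
#' @param masks named list of element masks, or `NULL`.
#' @param landmarks named list of landmark points, or `NULL`.
#' @param ctv_roi optional [voxel_mask()] for centrum total volume.
#' @return A `vertebra_measures` list: `measures` (named numeric),
#'   `units`, `methods` (named character: `"landmark"`/`"segmentation"`).
#' @export
vertebra_summary <- function(grid, masks = NULL, landmarks = NULL,
                             ctv_roi = NULL) {
  stopifnot_grid(grid)
  h <- grid$voxel_size_um
  meas <- c(); meth <- c()
  put <- function(name, value, method) {
    meas[[name]] <<- as.numeric(value)
    meth[[name]] <<- method
  }
  lm <- landmarks
  has <- function(...) all(c(...) %in% names(lm))
  if (!is.null(lm)) {
    if (has("endplate_cranial", "endplate_caudal"))
      put("CL", landmark_distance(lm$endplate_cranial, lm$endplate_caudal),
          "landmark")
    if (has("centrum_dorsal", "centrum_ventral")) {
      ch <- landmark_distance(lm$centrum_dorsal, lm$centrum_ventral)
      put("CH", ch, "landmark")
      put("CR", centrum_radius(ch_um = ch), "landmark")
    }
    if (has("neural_arch_base", "neural_spine_tip")) {
      put("Na.L", landmark_distance(lm$neural_arch_base, lm$neural_spine_tip),
          "landmark")
      if (has("endplate_cranial", "endplate_caudal"))
        put("Na.Ang", arch_angle(lm$neural_arch_base, lm$neural_spine_tip,
                                 lm$endplate_cranial, lm$endplate_caudal),
            "landmark")
    }
    if (has("haemal_arch_base", "haemal_spine_tip")) {
      put("Ha.L", landmark_distance(lm$haemal_arch_base, lm$haemal_spine_tip),
          "landmark")
      if (has("endplate_cranial", "endplate_caudal"))
        put("Ha.Ang", arch_angle(lm$haemal_arch_base, lm$haemal_spine_tip,
                                 lm$endplate_cranial, lm$endplate_caudal),
            "landmark")
    }
    if ("neural_canal_polygon" %in% names(lm))
      put("Nc.A", canal_area(lm$neural_canal_polygon), "landmark")
    if ("haemal_canal_polygon" %in% names(lm))
      put("Ha.A", canal_area(lm$haemal_canal_polygon), "landmark")
    if (has("snout_tip", "caudal_fin_base"))
      put("SL", landmark_distance(lm$snout_tip, lm$caudal_fin_base) / 1000,
          "landmark")
  }
  if (!is.null(masks)) {
    el <- list(centrum = c("CV", "C.Th"), neural_arch = c("Na.V", "Na.Th"),
               haemal_arch = c("Ha.V", "Ha.Th"))
    union_mask <- NULL
    for (nm in names(el)) {
      if (is.null(masks[[nm]])) next
      m <- as_mask_array(masks[[nm]])
      put(el[[nm]][1], structure_volume(m, h), "segmentation")
      put(el[[nm]][2], local_thickness(m, h)$mean_um, "segmentation")
      union_mask <- if (is.null(union_mask)) m else union_mask | m
    }
    if (!is.null(union_mask)) {
      put("VV", structure_volume(union_mask, h), "segmentation")
      put("V.Th", local_thickness(union_mask, h)$mean_um, "segmentation")
    }
  }
  if (!is.null(ctv_roi))
    put("CTV", structure_volume(as_mask_array(ctv_roi), h), "segmentation")
  absent <- setdiff(names(MEASURE_UNITS), names(meas))
  if (length(absent))
    message("vertebra_summary: fields absent for lack of inputs: ",
            paste(absent, collapse = ", "))
  structure(list(measures = unlist(meas),
                 units = MEASURE_UNITS[names(meas)],
                 methods = unlist(meth)),
            class = "vertebra_measures")
}

#' @export
print.vertebra_measures <- function(x, ...) {
  cat("<vertebra_measures>\n")
  for (nm in names(x$measures))
    cat(sprintf("  %-7s %12.4g %-4s [%s]\n", nm, x$measures[[nm]],
                x$units[[nm]], x$methods[[nm]]))
  invisible(x)
}

#' Read a landmark table
#'
#' CSV with columns `name,x_um,y_um,z_um`; polygon vertices use repeated
#' names like `neural_canal_polygon` and are assembled in file order.
#'
#' @param path CSV path.
#' @return Named list of 3-vectors / polygon matrices for
#'   [vertebra_summary()].
#' @export
read_landmarks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_um", "y_um", "z_um")
  if (!all(need %in% names(df)))
    stop("landmark CSV needs columns name,x_um,y_um,z_um", call. = FALSE)
  out <- list()
  for (nm in unique(df$name)) {
    rows <- df[df$name == nm, c("x_um", "y_um", "z_um")]
    out[[nm]] <- if (nrow(rows) == 1) as.numeric(rows) else as.matrix(rows)
  }
  out
}

#' One-row data frame of a measurement record
#'
#' @param x a `vertebra_measures`.
#' @param ... unused.
#' @return data.frame with one column per available measure.
#' @export
as.data.frame.vertebra_measures <- function(x, ...) {
  as.data.frame(as.list(x$measures), check.names = FALSE)
}
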