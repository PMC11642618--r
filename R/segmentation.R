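# ROI construction, bone thresholding, multiplex specimen separation and
# scan-quality checks. ROIs rasterize by voxel-center inclusion; thresholds
# are inclusive (>=) and, for calibrated volumes, expressed in mg HA/cm3 so
# they can be reported directly.

#' Region-of-interest specification
#'
#' Geometric ROI descriptions in physical units (um), rasterized onto a
#' grid by [make_roi()]. Three kinds are supported, mirroring common
#' practice: an axis-aligned box, a cylinder, and per-slice closed contours.
#'
#' @param kind `"box"`, `"cylinder"` or `"contours"`.
#' @param box list with `lo` and `hi`, 3-vectors of corner coordinates (um).
#' @param cylinder list with `axis` (1, 2 or 3), `center` (3-vector um; the
#'   component along `axis` is the cylinder midpoint), `radius_um`, `span_um`
#'   (full length along the axis).
#' @param contours list of lists with `slice` (1-based index along axis 1)
#'   and `polygon` (n x 2 matrix of um coordinates in the axis-2/axis-3
#'   plane); polygons must be simple and are filled by the even-odd rule.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(kind = c("box", "cylinder", "contours"), box = NULL,
                     cylinder = NULL, contours = NULL) {
  kind <- match.arg(kind)
  spec <- structure(list(kind = kind, box = box, cylinder = cylinder,
                         contours = contours), class = "roi_spec")
  if (kind == "box" && (is.null(box$lo) || is.null(box$hi)))
    stop("box ROI needs lo and hi corners", call. = FALSE)
  if (kind == "cylinder" &&
      (is.null(cylinder$axis) || is.null(cylinder$center) ||
       is.null(cylinder$radius_um) || is.null(cylinder$span_um)))
    stop("cylinder ROI needs axis, center, radius_um, span_um", call. = FALSE)
  if (kind == "contours" && !length(contours))
    stop("contours ROI needs at least one polygon", call. = FALSE)
  spec
}

# even-odd point-in-polygon test for voxel centers; px/py vectors, poly n x 2
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (abs(i - j) <= 1 || (i == 1 && j == n) || (j == 1 && i == n)) next
      if (segments_intersect(poly[i, ], poly[i %% n + 1, ],
                             poly[j, ], poly[j %% n + 1, ])) return(FALSE)
    }
  }
  TRUE
}

#' Rasterize an ROI specification onto a grid
#'
#' Box and cylinder ROIs include a voxel when its center lies inside the
#' geometry (boundary inclusive); contour ROIs fill each listed slice by the
#' even-odd rule at voxel centers and stack the slices.
#'
#' @param spec a [roi_spec()].
#' @param grid a [voxel_grid()].
#' @return A [voxel_mask()] of kind `"roi"`.
#' @export
make_roi <- function(spec, grid) {
  stopifnot_grid(grid)
  if (!inherits(spec, "roi_spec")) stop("expected a roi_spec", call. = FALSE)
  d <- dim(grid$values)
  h <- grid$voxel_size_um
  coords <- lapply(d, function(n) (seq_len(n) - 1) * h)
  m <- array(FALSE, dim = d)
  if (spec$kind == "box") {
    lo <- pmin(spec$box$lo, spec$box$hi)
    hi <- pmax(spec$box$lo, spec$box$hi)
    sel <- lapply(1:3, function(a) coords[[a]] >= lo[a] & coords[[a]] <= hi[a])
    m[sel[[1]], sel[[2]], sel[[3]]] <- TRUE
  } else if (spec$kind == "cylinder") {
    cyl <- spec$cylinder
    ax <- as.integer(cyl$axis)
    if (!ax %in% 1:3) stop("cylinder axis must be 1, 2 or 3", call. = FALSE)
    perp <- setdiff(1:3, ax)
    along_ok <- abs(coords[[ax]] - cyl$center[ax]) <= cyl$span_um / 2
    u <- coords[[perp[1]]] - cyl$center[perp[1]]
    v <- coords[[perp[2]]] - cyl$center[perp[2]]
    r2 <- outer(u^2, v^2, `+`)
    disc <- r2 <= cyl$radius_um^2
    idx <- list(NULL, NULL, NULL)
    for (k in which(along_ok)) {
      slc <- array(FALSE, d[perp])
      slc[disc] <- TRUE
      if (ax == 1) m[k, , ] <- slc else if (ax == 2) m[, k, ] <- slc
      else m[, , k] <- slc
    }
  } else {
    for (ct in spec$contours) {
      poly <- as.matrix(ct$polygon)
      if (!polygon_is_simple(poly))
        stop("contour polygon is self-intersecting", call. = FALSE)
      k <- as.integer(ct$slice)
      if (k < 1 || k > d[1]) stop("contour slice out of bounds", call. = FALSE)
      pts <- expand.grid(y = coords[[2]], z = coords[[3]])
      inside <- points_in_polygon(pts$y, pts$z, poly)
      m[k, , ] <- m[k, , ] | array(inside, d[2:3])
    }
  }
  if (!any(m)) stop("ROI rasterizes to an empty mask", call. = FALSE)
  voxel_mask(m, "roi")
}

#' Otsu threshold of a value vector
#'
#' Canonical parameter-free between-class-variance maximizer over a 256-bin
#' histogram; used for specimen-specific ("auto") thresholds where a global
#' threshold is inappropriate (growth series, mineralization mutants).
#'
#' @param values numeric vector (ROI voxel values).
#' @param n_bins histogram bins (default 256).
#' @return Threshold on the value scale (bin upper edge maximizing
#'   between-class variance).
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  counts <- tabulate(findInterval(values, breaks, rightmost.closed = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  # empty-gap histograms give a plateau of maximal between-class variance;
  # take its middle bin so the threshold falls centrally between the modes
  k <- which(sigma_b == max(sigma_b))
  k <- k[ceiling(length(k) / 2)]
  breaks[k + 1L]
}

#' Threshold specification
#'
#' @param mode `"global"` (manually selected threshold, mg HA/cm3) or
#'   `"auto"` (specimen-specific Otsu threshold over the ROI histogram).
#' @param global_mgHA_cm3 threshold value for `mode = "global"`.
#' @param auto_algorithm name of the automatic algorithm (only `"otsu"`).
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(mode = c("global", "auto"), global_mgHA_cm3 = NULL,
                           auto_algorithm = "otsu") {
  mode <- match.arg(mode)
  if (mode == "global" &&
      (is.null(global_mgHA_cm3) || !is.finite(global_mgHA_cm3)))
    stop("global mode needs a finite global_mgHA_cm3", call. = FALSE)
  if (mode == "auto" && !identical(auto_algorithm, "otsu"))
    stop("only the 'otsu' auto algorithm is implemented", call. = FALSE)
  structure(list(mode = mode, global_mgHA_cm3 = global_mgHA_cm3,
                 auto_algorithm = auto_algorithm), class = "threshold_spec")
}

#' Identify bone voxels within an ROI
#'
#' Bone = ROI voxels whose calibrated value is >= the threshold (inclusive,
#' a fixed convention for reproducibility). With `mode = "auto"` the Otsu
#' threshold of the ROI histogram is computed and reported via a message so
#' it can be logged in mg HA/cm3, as the reporting standard requires.
#'
#' @param grid a calibrated [voxel_grid()].
#' @param roi a [voxel_mask()] (non-empty).
#' @param spec a [threshold_spec()].
#' @return A [voxel_mask()] of kind `"bone"` with attribute
#'   `threshold_mgHA_cm3`. An empty result is a warning, not an error.
#' @export
threshold_bone <- function(grid, roi, spec) {
  stopifnot_grid(grid)
  if (!grid$calibrated)
    stop("thresholding requires a calibrated grid (mg HA/cm3)", call. = FALSE)
  m <- check_congruent(grid, roi)
  if (!any(m)) stop("empty ROI", call. = FALSE)
  if (!inherits(spec, "threshold_spec")) stop("expected a threshold_spec", call. = FALSE)
  thr <- if (spec$mode == "global") {
    spec$global_mgHA_cm3
  } else {
    t0 <- otsu_threshold(grid$values[m])
    message(sprintf("auto threshold (Otsu): %.6g mg HA/cm3", t0))
    t0
  }
  bone <- m & (grid$values >= thr)
  if (!any(bone)) warning("threshold yields an empty bone mask", call. = FALSE)
  out <- voxel_mask(bone, "bone")
  attr(out, "threshold_mgHA_cm3") <- thr
  out
}

#' Separate specimens in a multiplexed (bulk) scan
#'
#' For scans acquired in air: thresholds the tissue envelope, labels
#' 26-connected components, drops components smaller than `min_volume_um3`,
#' and returns one mask per animal ordered by left-right position. When the
#' expected animal count is supplied and fewer components are found, bodies
#' have probably merged and a warning is raised.
#'
#' @param grid a [voxel_grid()] (raw or calibrated) scanned against an
#'   air (~0) background.
#' @param envelope_threshold value separating tissue from air.
#' @param min_volume_um3 minimum component volume retained.
#' @param n_expected optional expected number of animals (1-8 typical).
#' @return List of [voxel_mask()], one per specimen, with attribute `n`.
#' @export
separate_specimens <- function(grid, envelope_threshold, min_volume_um3 = 0,
                               n_expected = NULL) {
  stopifnot_grid(grid)
  fg <- grid$values >= envelope_threshold
  d <- dim(grid$values)
  labs <- label_components_cpp(as.logical(fg), d)
  labs <- array(labs, dim = d)
  if (max(labs) == 0L) stop("no components above the envelope threshold", call. = FALSE)
  h3 <- grid$voxel_size_um^3
  keep <- which(tabulate(labs[labs > 0]) * h3 >= min_volume_um3)
  if (!length(keep)) stop("all components below min_volume_um3", call. = FALSE)
  # order by mean left-right (axis 3) position
  zpos <- vapply(keep, function(l) {
    idx <- which(labs == l, arr.ind = TRUE)
    mean(idx[, 3])
  }, numeric(1))
  keep <- keep[order(zpos)]
  masks <- lapply(keep, function(l) voxel_mask(labs == l, "roi"))
  if (!is.null(n_expected) && length(masks) < n_expected)
    warning("components merged; check spacing", call. = FALSE)
  attr(masks, "n") <- length(masks)
  masks
}

#' Beam-hardening (cupping) check on a uniform cylinder
#'
#' Cupping produces a radial attenuation gradient across a nominally uniform
#' cylinder. The check averages values in 10 equal-width radial annuli, fits
#' value ~ (r/R)^2, and reports the fitted center/edge ratio. Either
#' polarity shows up: a ratio below 1 means the center is depressed (the
#' pattern seen after pre-hardening loss), above 1 means it is elevated.
#'
#' @param grid a calibrated [voxel_grid()].
#' @param cylinder_roi a cylinder [roi_spec()] covering uniform material.
#' @param tolerance flag when `|1 - ratio|` exceeds this (default 0.05).
#' @param n_annuli number of radial annuli (default 10).
#' @return List with `ratio` (center/edge), `flagged`, `annulus_mean`,
#'   `annulus_r_mid`, `fit` coefficients.
#' @export
qc_cupping <- function(grid, cylinder_roi, tolerance = 0.05, n_annuli = 10L) {
  stopifnot_grid(grid)
  if (!inherits(cylinder_roi, "roi_spec") || cylinder_roi$kind != "cylinder")
    stop("qc_cupping needs a cylinder roi_spec", call. = FALSE)
  cyl <- cylinder_roi$cylinder
  mask <- make_roi(cylinder_roi, grid)$mask
  d <- dim(grid$values)
  h <- grid$voxel_size_um
  ax <- as.integer(cyl$axis)
  perp <- setdiff(1:3, ax)
  idx <- which(mask, arr.ind = TRUE)
  u <- (idx[, perp[1]] - 1) * h - cyl$center[perp[1]]
  v <- (idx[, perp[2]] - 1) * h - cyl$center[perp[2]]
  r <- sqrt(u^2 + v^2)
  R <- cyl$radius_um
  band <- pmin(floor(r / (R / n_annuli)) + 1L, n_annuli)
  vals <- grid$values[mask]
  pops <- tabulate(band, nbins = n_annuli)
  if (sum(pops > 0) < 3L)
    stop("cylinder too thin: fewer than 3 annuli populated", call. = FALSE)
  ann_mean <- vapply(seq_len(n_annuli), function(b)
    if (pops[b]) mean(vals[band == b]) else NA_real_, numeric(1))
  r_mid <- (seq_len(n_annuli) - 0.5) * (R / n_annuli)
  x <- (r / R)^2
  fit <- stats::lm(vals ~ x)
  center <- unname(stats::coef(fit)[1])
  edge <- center + unname(stats::coef(fit)[2])
  ratio <- center / edge
  list(ratio = ratio, flagged = abs(1 - ratio) > tolerance,
       annulus_mean = ann_mean, annulus_r_mid = r_mid,
       fit = stats::coef(fit))
}

#' Feature-size to voxel-size adequacy check
#'
#' The minimum recommended ratio of analyzed-object size to voxel size is
#' two; below that, tissue-boundary identification errors dominate.
#' The boundary is inclusive: a ratio of exactly 2 is adequate.
#'
#' @param feature_size_um size of the structure being measured (um).
#' @param voxel_size_um isotropic voxel size (um).
#' @return List with `ratio` and `adequate`.
#' @export
qc_voxel_ratio <- function(feature_size_um, voxel_size_um) {
  if (!is.finite(feature_size_um) || feature_size_um <= 0 ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("sizes must be positive scalars", call. = FALSE)
  ratio <- feature_size_um / voxel_size_um
  list(ratio = ratio, adequate = ratio >= 2)
}
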