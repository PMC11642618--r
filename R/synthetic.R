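# Ground-truth-known synthetic inputs. The vertebra phantom idealizes an
# amphicoelous vertebra as a hollow tube (centrum) with flared endplate
# rings and capsule struts for the neural/haemal arches; every measure the
# package computes on it has a closed-form truth. Density phantoms,
# multiplexed fish arrays, beam-hardening cupping and the small worked
# -example grids used by the densitometry tests are generated here too.
# Every generator is a pure function of its spec and seed.

#' Vertebra phantom specification
#'
#' Geometry and densities of the synthetic vertebra. The centrum is a
#' hollow tube along the cranial-caudal axis: outer radius `ch_um/2`, inner
#' radius `ch_um/2 - wall_um`. Endplate flare shifts BOTH radii outward by
#' a linear taper reaching `(flare_factor - 1) * ch_um/2` at each end over
#' `flare_len_um`, so the radial wall stays `wall_um` and the normal wall
#' in the taper is `wall_um * cos(taper angle)` — the analytic thickness
#' truth accounts for this. Arches are pairs of capsule struts meeting at a spine
#' tip placed to realize the requested angle against the cranial-caudal
#' axis. Densities follow adult zebrafish practice: bone TMD in the
#' 400-600 mg HA/cm3 range, wall thickness 50-80 um.
#'
#' @param cl_um centrum length (default 500).
#' @param ch_um centrum height of the unflared tube (default 400).
#' @param wall_um centrum wall thickness (default 60; must be < ch_um/2).
#' @param flare_factor endplate flare (default 1.15; 1 = no flare).
#' @param flare_len_um flared length at each end (default cl_um/10).
#' @param na_l_um,ha_l_um neural/haemal arch lengths (default 400).
#' @param strut_um arch strut thickness = capsule diameter (default 60).
#' @param na_ang_deg,ha_ang_deg arch angles in degrees (default 110).
#' @param bone_density_mgHA_cm3 bone density (default 500).
#' @param soft_density_mgHA_cm3 background soft tissue (default 80).
#' @param voxel_size_um voxel size (default 10).
#' @param supersampling per-axis subsamples for partial-volume averaging
#'   (default 2).
#' @param include_haemal caudal-type vertebra with haemal arch (default
#'   TRUE); FALSE gives the abdominal type.
#' @param noise_sd additive Gaussian noise on the calibrated values
#'   (default 0).
#' @param seed RNG seed for the noise (default 1).
#' @return An object of class `vertebra_phantom_spec`.
#' @export
vertebra_phantom_spec <- function(cl_um = 500, ch_um = 400, wall_um = 60,
                                  flare_factor = 1.15,
                                  flare_len_um = cl_um / 10,
                                  na_l_um = 400, ha_l_um = 400, strut_um = 60,
                                  na_ang_deg = 110, ha_ang_deg = 110,
                                  bone_density_mgHA_cm3 = 500,
                                  soft_density_mgHA_cm3 = 80,
                                  voxel_size_um = 10, supersampling = 2L,
                                  include_haemal = TRUE, noise_sd = 0,
                                  seed = 1L) {
  if (wall_um <= 0 || wall_um >= ch_um / 2)
    stop("wall thickness must be in (0, ch_um/2)", call. = FALSE)
  if (cl_um <= 0 || ch_um <= 0 || na_l_um <= 0 || strut_um <= 0)
    stop("geometry must be positive", call. = FALSE)
  if (flare_factor < 1) stop("flare_factor must be >= 1", call. = FALSE)
  if (bone_density_mgHA_cm3 < 0 || soft_density_mgHA_cm3 < 0)
    stop("densities must be >= 0", call. = FALSE)
  structure(as.list(environment()), class = "vertebra_phantom_spec")
}

arch_geometry <- function(spec, side = c("neural", "haemal"), center, r_out) {
  side <- match.arg(side)
  sgn <- if (side == "neural") -1 else 1       # dorsal = decreasing axis 2
  len <- if (side == "neural") spec$na_l_um else spec$ha_l_um
  ang <- (if (side == "neural") spec$na_ang_deg else spec$ha_ang_deg) * pi / 180
  base <- c(center[1], center[2] + sgn * r_out, center[3])
  tip <- base + c(cos(ang), sgn * sin(ang), 0) * len
  w <- 0.4 * r_out                              # lateral base half-spacing
  b1 <- base + c(0, 0, -w)
  b2 <- base + c(0, 0, w)
  list(base = base, tip = tip, b1 = b1, b2 = b2, len = len,
       strut_len = sqrt(sum((tip - b1)^2)))
}

#' Generate a synthetic vertebra with analytic ground truth
#'
#' Rasterizes the phantom with supersampled partial-volume averaging: the
#' calibrated voxel value is `occ * bone + (1 - occ) * soft` where `occ` is
#' the occupied sub-sample fraction. Returns per-element bone masks
#' (occupancy >= 0.5), a `core` mask of fully-interior voxels (occupancy of
#' exactly 1 at the used supersampling, on which TMD equals the nominal bone
#' density), landmark ground truth, and the analytic measure truth.
#'
#' @param spec a [vertebra_phantom_spec()].
#' @return List with `grid` (calibrated [voxel_grid()]), `masks` (named
#'   list: centrum, neural_arch, haemal_arch, bone = union, core),
#'   `truth` (list: `measures` named numeric, `landmarks`, densities).
#' @export
generate_vertebra <- function(spec) {
  if (!inherits(spec, "vertebra_phantom_spec"))
    stop("expected a vertebra_phantom_spec", call. = FALSE)
  h <- spec$voxel_size_um
  r_out <- spec$ch_um / 2
  r_in <- r_out - spec$wall_um
  delta <- (spec$flare_factor - 1) * r_out
  margin <- 4 * h
  na_ang <- spec$na_ang_deg * pi / 180
  ha_ang <- spec$ha_ang_deg * pi / 180
  dorsal_reach <- spec$na_l_um * sin(na_ang)
  ventral_reach <- if (spec$include_haemal) spec$ha_l_um * sin(ha_ang) else 0
  x_reach <- max(abs(cos(na_ang)) * spec$na_l_um,
                 if (spec$include_haemal) abs(cos(ha_ang)) * spec$ha_l_um else 0)
  ex_x <- spec$cl_um + 2 * (margin + x_reach)
  ex_y <- 2 * (r_out + delta) + dorsal_reach + ventral_reach + 2 * margin
  ex_z <- 2 * (r_out + delta) + 2 * margin
  dims <- as.integer(ceiling(c(ex_x, ex_y, ex_z) / h)) + 1L
  center <- c(ex_x / 2,
              margin + dorsal_reach + r_out + delta,
              ex_z / 2)
  tube <- c(center, spec$cl_um / 2, r_out, r_in, delta, spec$flare_len_um)
  no_tube <- c(0, 0, 0, -1, 0, 0, 0, 0)
  rad <- spec$strut_um / 2
  na <- arch_geometry(spec, "neural", center, r_out)
  caps_n <- rbind(c(na$b1, na$tip, rad), c(na$b2, na$tip, rad))
  caps <- caps_n
  ha <- NULL
  if (spec$include_haemal) {
    ha <- arch_geometry(spec, "haemal", center, r_out)
    caps_h <- rbind(c(ha$b1, ha$tip, rad), c(ha$b2, ha$tip, rad))
    caps <- rbind(caps_n, caps_h)
  }
  ss <- as.integer(spec$supersampling)
  none <- matrix(numeric(0), ncol = 7)
  occ_all <- array(rasterize_vertebra_cpp(dims, h, ss, tube, caps), dim = dims)
  occ_c <- array(rasterize_vertebra_cpp(dims, h, ss, tube, none), dim = dims)
  occ_n <- array(rasterize_vertebra_cpp(dims, h, ss, no_tube, caps_n), dim = dims)
  occ_h <- if (spec$include_haemal)
    array(rasterize_vertebra_cpp(dims, h, ss, no_tube, caps_h), dim = dims)
  else array(0, dim = dims)
  vals <- occ_all * spec$bone_density_mgHA_cm3 +
    (1 - occ_all) * spec$soft_density_mgHA_cm3
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    vals <- vals + array(stats::rnorm(length(vals), 0, spec$noise_sd),
                         dim = dims)
  }
  grid <- voxel_grid(vals, h, calibrated = TRUE)
  masks <- list(centrum = voxel_mask(occ_c >= 0.5, "bone"),
                neural_arch = voxel_mask(occ_n >= 0.5, "bone"),
                haemal_arch = voxel_mask(occ_h >= 0.5, "bone"),
                bone = voxel_mask(occ_all >= 0.5, "bone"),
                core = voxel_mask(occ_all >= 1, "bone"))
  # analytic truths; the flare taper adds pi*delta*(r_out-r_in)*flare_len
  # per end and thins the normal wall by cos(taper angle) there
  Lf <- spec$flare_len_um
  Lmid <- spec$cl_um - 2 * Lf
  cv <- pi * (r_out^2 - r_in^2) * spec$cl_um +
    2 * pi * delta * (r_out - r_in) * Lf
  cos_taper <- if (Lf > 0) cos(atan2(delta, Lf)) else 1
  cth_true <- spec$wall_um * (Lmid + 2 * Lf * cos_taper) / spec$cl_um
  capsule_vol <- function(len) pi * rad^2 * len + 4 / 3 * pi * rad^3
  nav <- 2 * capsule_vol(na$strut_len)
  hav <- if (spec$include_haemal) 2 * capsule_vol(ha$strut_len) else NA_real_
  landmarks <- list(
    endplate_cranial = center - c(spec$cl_um / 2, 0, 0),
    endplate_caudal = center + c(spec$cl_um / 2, 0, 0),
    centrum_dorsal = center - c(0, r_out + delta, 0),
    centrum_ventral = center + c(0, r_out + delta, 0),
    neural_arch_base = na$base, neural_spine_tip = na$tip)
  if (spec$include_haemal) {
    landmarks$haemal_arch_base <- ha$base
    landmarks$haemal_spine_tip <- ha$tip
  }
  measures <- c(CL = spec$cl_um, CH = 2 * (r_out + delta), CR = r_out + delta,
                C.Th = cth_true, CV = cv, Na.L = spec$na_l_um,
                Na.Th = spec$strut_um, Na.V = nav, Na.Ang = spec$na_ang_deg,
                Ha.L = if (spec$include_haemal) spec$ha_l_um else NA_real_,
                Ha.Th = if (spec$include_haemal) spec$strut_um else NA_real_,
                Ha.V = hav,
                Ha.Ang = if (spec$include_haemal) spec$ha_ang_deg else NA_real_)
  measures["VV"] <- sum(measures[c("CV", "Na.V", "Ha.V")], na.rm = TRUE)
  truth <- list(measures = measures, landmarks = landmarks,
                bone_density = spec$bone_density_mgHA_cm3,
                soft_density = spec$soft_density_mgHA_cm3)
  list(grid = grid, masks = masks, truth = truth)
}

#' Estimate arch landmarks from a segmented arch mask
#'
#' Data-driven counterpart of the analytic landmark truth: the spine tip is
#' the centroid of the most extreme voxels of the arch in the dorsal (or
#' ventral) direction and the base the centroid of the voxels nearest the
#' centrum, each taken over one strut-thickness of depth.
#'
#' @param arch_mask arch [voxel_mask()].
#' @param voxel_size_um voxel size (um).
#' @param side `"neural"` (tip is dorsal) or `"haemal"`.
#' @param depth_um slab depth over which centroids are taken (default 30).
#' @return List with `base` and `tip` coordinates (um).
#' @export
estimate_arch_landmarks <- function(arch_mask, voxel_size_um,
                                    side = c("neural", "haemal"),
                                    depth_um = 30) {
  side <- match.arg(side)
  m <- as_mask_array(arch_mask)
  idx <- which(m, arr.ind = TRUE)
  if (!nrow(idx)) stop("empty arch mask", call. = FALSE)
  pos <- (idx - 1) * voxel_size_um
  y <- pos[, 2]
  if (side == "neural") {
    tip_sel <- y <= min(y) + depth_um
    base_sel <- y >= max(y) - depth_um
  } else {
    tip_sel <- y >= max(y) - depth_um
    base_sel <- y <= min(y) + depth_um
  }
  list(base = colMeans(pos[base_sel, , drop = FALSE]),
       tip = colMeans(pos[tip_sel, , drop = FALSE]))
}

#' Generate CaHA density calibration phantoms
#'
#' Cylindrical rods of the requested densities, voxelized against an air
#' background at the raw values implied by inverting the target calibration
#' (`raw = (density - intercept) / slope`), with optional additive Gaussian
#' detector noise. Rod interiors are uniform (no partial-volume model), so
#' with zero noise the rod means are exactly the inverse-affine raws and a
#' two-phantom fit recovers slope and intercept to machine precision.
#'
#' @param densities_mgHA_cm3 at least two known densities (the conventional
#'   pair is 250 and 750).
#' @param slope,intercept target calibration (density = slope * raw +
#'   intercept); slope must be nonzero.
#' @param noise_sd raw-value noise standard deviation (default 0).
#' @param seed RNG seed.
#' @param rod_diameter_um rod diameter (default 3000, within the 2-4 mm
#'   convention).
#' @param voxel_size_um voxel size (default 50).
#' @return List with `grid` (raw [voxel_grid()]), `phantoms` (list of
#'   [phantom_measurement()] with measured rod means), `rod_masks`.
#' @export
generate_density_phantoms <- function(densities_mgHA_cm3, slope = 0.25,
                                      intercept = 0, noise_sd = 0, seed = 1L,
                                      rod_diameter_um = 3000,
                                      voxel_size_um = 50) {
  if (length(densities_mgHA_cm3) < 2L)
    stop("at least two phantom densities required", call. = FALSE)
  if (!is.finite(slope) || slope == 0)
    stop("invalid affine: slope must be nonzero", call. = FALSE)
  n <- length(densities_mgHA_cm3)
  h <- voxel_size_um
  R <- rod_diameter_um / 2
  pitch <- rod_diameter_um * 1.5
  len_um <- rod_diameter_um
  dims <- as.integer(ceiling(c(len_um + 4 * h, rod_diameter_um + 6 * h,
                               n * pitch + 4 * h) / h))
  vals <- array(0, dim = dims)
  rod_masks <- vector("list", n)
  cx <- (dims[1] - 1) * h / 2
  cy <- (dims[2] - 1) * h / 2
  xs <- (seq_len(dims[1]) - 1) * h
  ys <- (seq_len(dims[2]) - 1) * h
  zs <- (seq_len(dims[3]) - 1) * h
  raws <- (densities_mgHA_cm3 - intercept) / slope
  for (i in seq_len(n)) {
    cz <- (i - 0.5) * pitch + 2 * h
    in_x <- abs(xs - cx) <= len_um / 2
    m <- array(FALSE, dim = dims)
    disc <- outer((ys - cy)^2, (zs - cz)^2, `+`) <= R^2
    for (k in which(in_x)) m[k, , ] <- disc
    vals[m] <- raws[i]
    rod_masks[[i]] <- voxel_mask(m, "roi")
  }
  if (noise_sd > 0) {
    set.seed(seed)
    vals <- vals + array(stats::rnorm(length(vals), 0, noise_sd), dim = dims)
  }
  grid <- voxel_grid(vals, h)
  phantoms <- lapply(seq_len(n), function(i)
    phantom_measurement(densities_mgHA_cm3[i],
                        mean(vals[rod_masks[[i]]$mask])))
  list(grid = grid, phantoms = phantoms, rod_masks = rod_masks)
}

#' Generate a multiplexed fish array scan
#'
#' `n_fish` ellipsoidal soft-tissue bodies, each with an embedded chain of
#' dense "vertebra" spheres, arranged equidistant from the scan center (the
#' mounting recommendation that minimizes differential beam hardening)
#' against an air (zero) background. Adjacent body centers sit `spacing_um`
#' apart.
#'
#' @param n_fish 1 to 8 animals.
#' @param spacing_um center-to-center spacing of adjacent bodies (> 0).
#' @param body list with `a_um` (half-length along the fish axis), `b_um`
#'   (transverse semi-axis), `soft_density`, `bone_density` (raw-value
#'   stand-ins).
#' @param voxel_size_um voxel size (default 100).
#' @param seed RNG seed (jitters nothing by default; kept for API
#'   determinism).
#' @return A raw [voxel_grid()].
#' @export
generate_multiplex <- function(n_fish, spacing_um = 3500,
                               body = list(a_um = 4000, b_um = 1200,
                                           soft_density = 100,
                                           bone_density = 1000),
                               voxel_size_um = 100, seed = 1L) {
  if (n_fish < 1 || n_fish > 8) stop("n_fish must be 1..8", call. = FALSE)
  if (spacing_um <= 0) stop("spacing_um must be positive", call. = FALSE)
  if (n_fish > 1 && spacing_um < body$b_um)
    stop("bodies overlap at requested spacing", call. = FALSE)
  h <- voxel_size_um
  rho <- if (n_fish == 1) 0 else spacing_um / (2 * sin(pi / n_fish))
  margin <- 3 * h
  ex_perp <- 2 * (rho + body$b_um) + 2 * margin
  ex_x <- 2 * body$a_um + 2 * margin
  dims <- as.integer(ceiling(c(ex_x, ex_perp, ex_perp) / h)) + 1L
  cx <- (dims[1] - 1) * h / 2
  cy <- (dims[2] - 1) * h / 2
  cz <- (dims[3] - 1) * h / 2
  xs <- (seq_len(dims[1]) - 1) * h
  ys <- (seq_len(dims[2]) - 1) * h
  zs <- (seq_len(dims[3]) - 1) * h
  vals <- array(0, dim = dims)
  angles <- 2 * pi * (seq_len(n_fish) - 1) / max(n_fish, 1)
  xr2 <- ((xs - cx) / body$a_um)^2
  for (i in seq_len(n_fish)) {
    oy <- cy + rho * cos(angles[i])
    oz <- cz + rho * sin(angles[i])
    perp <- outer(((ys - oy) / body$b_um)^2, ((zs - oz) / body$b_um)^2, `+`)
    for (k in seq_len(dims[1])) {
      inside <- xr2[k] + perp <= 1
      slab <- vals[k, , ]
      slab[inside & slab == 0] <- body$soft_density
      vals[k, , ] <- slab
    }
    # vertebra chain: dense spheres along the body axis
    vr <- body$b_um / 3
    for (s in seq(-0.5, 0.5, length.out = 5)) {
      sx <- cx + s * body$a_um
      ix <- which(abs(xs - sx) <= vr)
      sph_perp <- outer((ys - oy)^2, (zs - oz)^2, `+`)
      for (k in ix) {
        inside <- (xs[k] - sx)^2 + sph_perp <= vr^2
        slab <- vals[k, , ]
        slab[inside] <- body$bone_density
        vals[k, , ] <- slab
      }
    }
  }
  voxel_grid(vals, h)
}

#' Apply a beam-hardening cupping field
#'
#' Multiplies values by `1 - gamma * (1 - (r/R)^2)` radially around the
#' given axis: the center is depressed by the factor `1 - gamma` and the
#' field is unchanged at radius `R` and beyond. [qc_cupping()] on a uniform
#' cylinder of radius `R` then reports a center/edge ratio of `1 - gamma`.
#'
#' @param grid a [voxel_grid()].
#' @param gamma depression fraction in [0, 1).
#' @param axis cylinder axis (1, 2 or 3; default 1).
#' @param center_um optional in-plane center (defaults to the grid center).
#' @param radius_um reference radius `R` (defaults to the largest in-plane
#'   center distance).
#' @return The modified [voxel_grid()].
#' @export
add_cupping <- function(grid, gamma, axis = 1L, center_um = NULL,
                        radius_um = NULL) {
  stopifnot_grid(grid)
  if (!is.finite(gamma) || gamma < 0 || gamma >= 1)
    stop("gamma must be in [0, 1)", call. = FALSE)
  if (gamma == 0) return(grid)
  d <- dim(grid$values)
  h <- grid$voxel_size_um
  perp <- setdiff(1:3, axis)
  u <- (seq_len(d[perp[1]]) - 1) * h
  v <- (seq_len(d[perp[2]]) - 1) * h
  if (is.null(center_um)) center_um <- c(max(u) / 2, max(v) / 2)
  r2 <- outer((u - center_um[1])^2, (v - center_um[2])^2, `+`)
  if (is.null(radius_um)) radius_um <- sqrt(max(r2))
  factor <- 1 - gamma * pmax(0, 1 - r2 / radius_um^2)
  vals <- grid$values
  for (k in seq_len(d[axis])) {
    if (axis == 1) vals[k, , ] <- vals[k, , ] * factor
    else if (axis == 2) vals[, k, ] <- vals[, k, ] * factor
    else vals[, , k] <- vals[, , k] * factor
  }
  voxel_grid(vals, h, calibrated = grid$calibrated,
             units_label = grid$units_label)
}

#' Embed a small density pattern as a one-slice calibrated volume
#'
#' Reproduces the classic worked example used to teach the ROI dependence
#' of BMD: a tiny pixel grid of hydroxyapatite concentrations, plus index
#' ROIs. Used heavily by the densitometry tests.
#'
#' @param pattern numeric matrix of densities (mg HA/cm3).
#' @param rois named list of index ROIs, each `list(rows =, cols =)`.
#' @param voxel_size_um voxel size (default 10).
#' @return List with `grid` (calibrated, dims `nrow x ncol x 1`) and
#'   `rois` (named list of [voxel_mask()]).
#' @export
worked_example_grid <- function(pattern,
                                rois = list(full = list(rows = NULL,
                                                        cols = NULL)),
                                voxel_size_um = 10) {
  pattern <- as.matrix(pattern)
  if (!length(pattern) || !all(is.finite(pattern)))
    stop("pattern must be a non-empty finite matrix", call. = FALSE)
  arr <- array(pattern, dim = c(nrow(pattern), ncol(pattern), 1L))
  grid <- voxel_grid(arr, voxel_size_um, calibrated = TRUE)
  masks <- lapply(rois, function(r) {
    m <- array(FALSE, dim = dim(arr))
    rows <- if (is.null(r$rows)) seq_len(nrow(pattern)) else r$rows
    cols <- if (is.null(r$cols)) seq_len(ncol(pattern)) else r$cols
    m[rows, cols, 1] <- TRUE
    voxel_mask(m, "roi")
  })
  list(grid = grid, rois = masks)
}
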