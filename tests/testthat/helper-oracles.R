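# Independent oracles and fixture builders shared across the suite.

# Exhaustive maximal-inscribed-sphere thickness, same model as the package
# (sphere radius = distance to nearest background voxel center, grid padded
# by one background layer; thickness = 2 * max covering radius - 0.5) but
# computed by brute-force pair enumeration — no distance transform, no
# painting. Only viable for small masks.
oracle_thickness <- function(mask, voxel_size_um = 1) {
  d <- dim(mask)
  bone <- which(mask, arr.ind = TRUE)
  pad <- as.matrix(expand.grid(i = 0:(d[1] + 1), j = 0:(d[2] + 1),
                               k = 0:(d[3] + 1)))
  inb <- pad[, 1] >= 1 & pad[, 1] <= d[1] & pad[, 2] >= 1 &
    pad[, 2] <= d[2] & pad[, 3] >= 1 & pad[, 3] <= d[3]
  isbone <- rep(FALSE, nrow(pad))
  isbone[inb] <- mask[pad[inb, , drop = FALSE]]
  bg <- pad[!isbone, , drop = FALSE]
  # r^2(q): min squared distance to any background center
  cross <- function(a, b) outer(rowSums(a^2), rowSums(b^2), `+`) -
    2 * a %*% t(b)
  r2 <- apply(cross(bone, bg), 1, min)
  # coverage: |p-q|^2 <= r^2(q)
  d2 <- cross(bone, bone)
  covered <- d2 <= matrix(r2, nrow(bone), nrow(bone), byrow = TRUE)
  rmax <- apply(covered * matrix(r2, nrow(bone), nrow(bone), byrow = TRUE),
                1, max)
  th <- array(0, dim = d)
  th[bone] <- pmax(2 * sqrt(rmax) - 0.5, 0) * voxel_size_um
  list(thickness_map = th, mean_um = mean(th[bone]))
}

# random blob mask: union of a few random balls inside an n^3 grid
random_blob_mask <- function(n = 12, n_balls = 3) {
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  m <- rep(FALSE, n^3)
  for (b in seq_len(n_balls)) {
    ctr <- runif(3, 2, n - 1)
    r <- runif(1, 1, n / 3)
    m <- m | (rowSums(sweep(idx, 2, ctr)^2) <= r^2)
  }
  array(m, dim = c(n, n, n))
}

digital_ball <- function(D, margin = 3) {
  n <- D + 2 * margin
  ctr <- (n + 1) / 2
  idx <- as.matrix(expand.grid(1:n, 1:n, 1:n))
  array(sqrt(rowSums(sweep(idx, 2, ctr)^2)) <= D / 2, dim = c(n, n, n))
}

uniform_cylinder_grid <- function(value = 500, radius_um = 200, h = 10,
                                  n_perp = 51, n_len = 12) {
  ctr <- (n_perp - 1) * h / 2
  u <- (seq_len(n_perp) - 1) * h - ctr
  disc <- outer(u^2, u^2, `+`) <= radius_um^2
  vals <- array(0, dim = c(n_len, n_perp, n_perp))
  for (k in seq_len(n_len)) vals[k, , ][disc] <- value
  list(grid = voxel_grid(vals, h, calibrated = TRUE),
       roi = roi_spec("cylinder",
                      cylinder = list(axis = 1, center = c(0, ctr, ctr),
                                      radius_um = radius_um,
                                      span_um = n_len * h * 2)))
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * max(1, abs(expected)))
}
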