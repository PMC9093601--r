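
# Affine conventions used throughout the package:
#   * voxel indices are 0-based (i, j, k)
#   * world space is RAS+ millimetres
#   * world = affine %*% c(i, j, k, 1)
# R arrays are 1-based, so array lookups add 1 to the voxel index.

#' Convert 0-based voxel indices to world coordinates
#'
#' @param vox numeric matrix (n x 3) of 0-based voxel indices (may be
#'   fractional), or a length-3 vector.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(vox, affine) {
  vox <- rbind3(vox)
  t(affine[1:3, 1:3] %*% t(vox) + affine[1:3, 4])
}

#' Convert world coordinates to 0-based voxel indices
#'
#' @param world numeric matrix (n x 3) of world mm coordinates.
#' @param affine 4x4 voxel-to-world matrix.
#' @return n x 3 matrix of fractional 0-based voxel indices.
#' @export
world_to_voxel <- function(world, affine) {
  world <- rbind3(world)
  inv <- solve(affine)
  t(inv[1:3, 1:3] %*% t(world) + inv[1:3, 4])
}

# coerce a 3-vector or n x 3 matrix to n x 3 matrix
rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3L) else as.matrix(x)
}

#' Rotation matrix about an axis (Rodrigues form)
#' @param axis rotation axis (any length-3 vector, normalized internally).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# 4x4 rigid transform from rotation matrix and translation
rigid_matrix <- function(R, t) {
  m <- diag(4)
  m[1:3, 1:3] <- R
  m[1:3, 4] <- t
  m
}

# apply a 4x4 world transform to an n x 3 point matrix
apply_transform <- function(points, matrix4) {
  points <- rbind3(points)
  t(matrix4[1:3, 1:3] %*% t(points) + matrix4[1:3, 4])
}

#' Rotation angle (degrees) of a 3x3 rotation matrix
#' @param R rotation matrix.
#' @return angle in degrees in [0, 180].
#' @export
rotation_angle_deg <- function(R) {
  c <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, c))) * 180 / pi
}

# grid of 0-based voxel centre world coordinates for a 3D array shape
grid_world_coords <- function(shape, affine) {
  idx <- as.matrix(expand.grid(i = 0:(shape[1] - 1L),
                               j = 0:(shape[2] - 1L),
                               k = 0:(shape[3] - 1L)))
  voxel_to_world(idx, affine)
}

#' Trilinearly sample a 3D array at fractional 0-based voxel coordinates
#'
#' Coordinates outside the grid return `NA`.
#'
#' @param arr 3D numeric array.
#' @param vox n x 3 matrix of fractional 0-based voxel coordinates.
#' @return numeric vector of sampled values, `NA` outside the volume.
#' @keywords internal
trilinear_sample <- function(arr, vox) {
  vox <- rbind3(vox)
  d <- dim(arr)
  i0 <- floor(vox)
  f <- vox - i0
  out <- rep(NA_real_, nrow(vox))
  ok <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
        vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
        vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  if (!any(ok)) return(out)
  i0 <- i0[ok, , drop = FALSE]
  f <- f[ok, , drop = FALSE]
  # clamp upper corner so that points exactly on the far face stay in range
  i1 <- pmin(i0 + 1, matrix(rep(d - 1, each = nrow(i0)), ncol = 3))
  v <- 0
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ii <- if (cx) i1[, 1] else i0[, 1]
    jj <- if (cy) i1[, 2] else i0[, 2]
    kk <- if (cz) i1[, 3] else i0[, 3]
    w <- (if (cx) f[, 1] else 1 - f[, 1]) *
         (if (cy) f[, 2] else 1 - f[, 2]) *
         (if (cz) f[, 3] else 1 - f[, 3])
    v <- v + w * arr[cbind(ii + 1, jj + 1, kk + 1)]
  }
  out[ok] <- v
  out
}

# nearest-neighbour sample; outside -> fill (default NA)
nearest_sample <- function(arr, vox, fill = NA_real_) {
  vox <- rbind3(vox)
  d <- dim(arr)
  idx <- round(vox)
  out <- rep(fill, nrow(vox))
  ok <- idx[, 1] >= 0 & idx[, 1] <= d[1] - 1 &
        idx[, 2] >= 0 & idx[, 2] <= d[2] - 1 &
        idx[, 3] >= 0 & idx[, 3] <= d[3] - 1
  ok[is.na(ok)] <- FALSE
  if (any(ok)) {
    out[ok] <- arr[cbind(idx[ok, 1] + 1, idx[ok, 2] + 1, idx[ok, 3] + 1)]
  }
  out
}
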