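# Vectorized eigendecomposition of fields of symmetric 3x3 tensors.
# Eigenvalues use the trigonometric (Cardano) solution; the principal
# eigenvector comes from the rank-one product (D - l2 I)(D - l3 I), which
# equals (l1-l2)(l1-l3) v1 v1^T. Near-degenerate voxels (l1 ~ l2) fall back
# to base eigen(); those voxels are isotropic and never steer tracking.

#' Sorted eigenvalues of packed symmetric tensors
#'
#' @param tensors n x 6 matrix packed (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @return n x 3 matrix of eigenvalues sorted l1 >= l2 >= l3.
#' @export
tensor_eigenvalues <- function(tensors) {
  tensors <- matrix(tensors, ncol = 6L)
  dxx <- tensors[, 1]; dxy <- tensors[, 2]; dxz <- tensors[, 3]
  dyy <- tensors[, 4]; dyz <- tensors[, 5]; dzz <- tensors[, 6]
  q <- (dxx + dyy + dzz) / 3
  p1 <- dxy^2 + dxz^2 + dyz^2
  p2 <- (dxx - q)^2 + (dyy - q)^2 + (dzz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  out <- cbind(q, q, q)
  nz <- p > 0
  if (any(nz)) {
    pp <- p[nz]
    bxx <- (dxx[nz] - q[nz]) / pp; byy <- (dyy[nz] - q[nz]) / pp
    bzz <- (dzz[nz] - q[nz]) / pp
    bxy <- dxy[nz] / pp; bxz <- dxz[nz] / pp; byz <- dyz[nz] / pp
    detB <- bxx * (byy * bzz - byz^2) -
            bxy * (bxy * bzz - byz * bxz) +
            bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    l1 <- q[nz] + 2 * pp * cos(phi)
    l3 <- q[nz] + 2 * pp * cos(phi + 2 * pi / 3)
    l2 <- 3 * q[nz] - l1 - l3
    out[nz, ] <- cbind(l1, l2, l3)
  }
  out
}

#' Principal eigenvectors of packed symmetric tensors
#'
#' @param tensors n x 6 matrix packed (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @param evals optional precomputed n x 3 sorted eigenvalues.
#' @return n x 3 matrix of unit principal eigenvectors (sign arbitrary);
#'   rows of (near-)isotropic tensors default to the +x axis.
#' @export
tensor_principal_axis <- function(tensors, evals = NULL) {
  tensors <- matrix(tensors, ncol = 6L)
  if (is.null(evals)) evals <- tensor_eigenvalues(tensors)
  n <- nrow(tensors)
  out <- matrix(rep(c(1, 0, 0), each = n), n, 3)
  scale <- rowSums(abs(evals)) + .Machine$double.eps
  distinct <- (evals[, 1] - evals[, 2]) / scale > 1e-7
  if (!any(distinct)) return(out)
  idx <- which(distinct)
  dxx <- tensors[idx, 1]; dxy <- tensors[idx, 2]; dxz <- tensors[idx, 3]
  dyy <- tensors[idx, 4]; dyz <- tensors[idx, 5]; dzz <- tensors[idx, 6]
  l2 <- evals[idx, 2]; l3 <- evals[idx, 3]
  # columns of (D - l2 I)(D - l3 I); each non-zero column is parallel to v1
  a11 <- dxx - l2; a22 <- dyy - l2; a33 <- dzz - l2
  b11 <- dxx - l3; b22 <- dyy - l3; b33 <- dzz - l3
  c1 <- cbind(a11 * b11 + dxy * dxy + dxz * dxz,
              dxy * b11 + a22 * dxy + dyz * dxz,
              dxz * b11 + dyz * dxy + a33 * dxz)
  c2 <- cbind(a11 * dxy + dxy * b22 + dxz * dyz,
              dxy * dxy + a22 * b22 + dyz * dyz,
              dxz * dxy + dyz * b22 + a33 * dyz)
  c3 <- cbind(a11 * dxz + dxy * dyz + dxz * b33,
              dxy * dxz + a22 * dyz + dyz * b33,
              dxz * dxz + dyz * dyz + a33 * b33)
  n1 <- rowSums(c1^2); n2 <- rowSums(c2^2); n3 <- rowSums(c3^2)
  best <- cbind(n1, n2, n3)
  pick <- max.col(best, ties.method = "first")
  v <- c1
  v[pick == 2, ] <- c2[pick == 2, , drop = FALSE]
  v[pick == 3, ] <- c3[pick == 3, , drop = FALSE]
  nv <- sqrt(rowSums(v^2))
  good <- nv > 0
  v[good, ] <- v[good, , drop = FALSE] / nv[good]
  # numerically fragile rows: fall back to a dense eigendecomposition
  frag <- which(!good | !is.finite(nv))
  for (r in frag) {
    D <- unpack_tensor(tensors[idx[r], ])
    v[r, ] <- eigen(D, symmetric = TRUE)$vectors[, 1]
  }
  out[idx, ] <- v
  out
}

#' Scalar invariants from eigenvalues
#'
#' MD = (l1+l2+l3)/3, L1 = l1, RD = (l2+l3)/2 and
#' FA = sqrt(3/2) * ||lambda - MD|| / ||lambda||. Negative eigenvalues are
#' clamped to zero first (magnitude-noise artefact), and FA of an all-zero
#' tensor is defined as 0 rather than NaN.
#'
#' @param evals n x 3 matrix of sorted eigenvalues.
#' @return list with vectors `fa`, `md`, `l1`, `rd` and the count
#'   `n_clamped` of voxels that had negative eigenvalues clamped.
#' @export
eigenvalue_metrics <- function(evals) {
  evals <- matrix(evals, ncol = 3L)
  n_clamped <- sum(rowSums(evals < 0) > 0)
  evals[evals < 0] <- 0
  md <- rowMeans(evals)
  l1 <- evals[, 1]
  rd <- (evals[, 2] + evals[, 3]) / 2
  num <- (evals[, 1] - md)^2 + (evals[, 2] - md)^2 + (evals[, 3] - md)^2
  den <- rowSums(evals^2)
  fa <- ifelse(den > 0, sqrt(1.5 * num / den), 0)
  fa <- pmin(pmax(fa, 0), 1)
  list(fa = fa, md = md, l1 = l1, rd = rd, n_clamped = n_clamped)
}

#' Derive FA, MD, L1 and RD maps from a fitted tensor field
#'
#' @param field a `tensor_field` from [fit_tensor()].
#' @return named list of [scalar_map()]s `FA`, `MD`, `L1`, `RD`; the number
#'   of voxels whose negative eigenvalues were clamped is attached as
#'   attribute `n_clamped` and logged.
#' @export
scalar_maps <- function(field) {
  stopifnot(inherits(field, "tensor_field"))
  d <- dim(field$tensors)[1:3]
  tm <- matrix(field$tensors, ncol = 6L)
  mvec <- as.vector(field$mask)
  evals <- tensor_eigenvalues(tm[mvec, , drop = FALSE])
  met <- eigenvalue_metrics(evals)
  if (met$n_clamped > 0) {
    pt_log("scalar_maps: clamped negative eigenvalues in ",
           met$n_clamped, " voxels")
  }
  make <- function(v, kind) {
    a <- array(0, d)
    a[mvec] <- v
    scalar_map(a, field$affine, kind)
  }
  out <- list(FA = make(met$fa, "FA"), MD = make(met$md, "MD"),
              L1 = make(met$l1, "L1"), RD = make(met$rd, "RD"))
  attr(out, "n_clamped") <- met$n_clamped
  out
}

#' Principal-direction field of a fitted tensor
#'
#' Voxels whose FA falls below `fa_floor` get a zero vector so that
#' (near-)isotropic tissue contributes nothing when directions are
#' interpolated at bundle boundaries during tracking.
#'
#' @param field a `tensor_field`.
#' @param fa_floor FA below which a voxel carries no direction.
#' @return x,y,z,3 array of unit principal eigenvectors (zero outside mask
#'   and in isotropic voxels).
#' @export
principal_direction_field <- function(field, fa_floor = 0.1) {
  d <- dim(field$tensors)[1:3]
  tm <- matrix(field$tensors, ncol = 6L)
  mvec <- as.vector(field$mask)
  evals <- tensor_eigenvalues(tm[mvec, , drop = FALSE])
  v <- tensor_principal_axis(tm[mvec, , drop = FALSE], evals)
  fa <- eigenvalue_metrics(evals)$fa
  v[!is.finite(fa) | fa < fa_floor, ] <- 0
  out <- matrix(0, nrow = prod(d), ncol = 3)
  out[mvec, ] <- v
  array(out, c(d, 3L))
}
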