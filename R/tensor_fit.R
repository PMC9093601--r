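#' Fit the diffusion tensor per voxel
#'
#' Ordinary (unweighted) log-linear least squares on
#' \eqn{\ln S_k = \ln S_0 - b_k\, g_k^T D\, g_k}, solved in one QR pass for
#' all voxels. The non-weighted signal S0 is estimated jointly as the
#' intercept, which is exact on noise-free input. Signals at or below zero
#' are floored at a small epsilon before taking logarithms.
#'
#' @param dwi a [dwi_volume()].
#' @param mask optional [scalar_map()] of kind "mask"; voxels outside are
#'   left unfitted (all-zero tensor, excluded from the field mask).
#' @param signal_floor positive floor applied to the signal before the log
#'   transform (default 1e-6 of the volume maximum).
#' @return object of class `tensor_field` with elements `tensors`
#'   (x, y, z, 6 array packed Dxx, Dxy, Dxz, Dyy, Dyz, Dzz in mm^2/s), `s0`,
#'   `mask` (logical array), `affine`.
#' @export
fit_tensor <- function(dwi, mask = NULL, signal_floor = NULL) {
  stopifnot(inherits(dwi, "dwi_volume"))
  gtab <- dwi$gtab
  assert_fit_determined(gtab)
  d <- dim(dwi$data)
  nvox <- prod(d[1:3])
  S <- matrix(dwi$data, nrow = nvox)        # nvox x K
  if (is.null(mask)) {
    mvec <- rep(TRUE, nvox)
  } else {
    if (!all(dim(mask$data) == d[1:3])) stop("mask grid does not match DWI")
    mvec <- as.vector(mask$data != 0)
  }
  if (is.null(signal_floor)) signal_floor <- max(S) * 1e-6
  X <- tensor_design_matrix(gtab)
  qrX <- qr(X)
  Y <- t(log(pmax(S[mvec, , drop = FALSE], signal_floor)))  # K x n
  beta <- qr.coef(qrX, Y)                                   # 7 x n
  tensors <- array(0, c(d[1:3], 6L))
  tm <- matrix(tensors, nrow = nvox)
  tm[mvec, ] <- t(beta[2:7, , drop = FALSE])
  tensors <- array(tm, c(d[1:3], 6L))
  s0 <- array(0, d[1:3])
  s0[mvec] <- exp(beta[1, ])
  structure(list(tensors = tensors,
                 s0 = s0,
                 mask = array(mvec, d[1:3]),
                 affine = dwi$affine,
                 gtab = gtab),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat("Tensor field:", paste(dim(x$tensors)[1:3], collapse = " x "),
      "voxels,", sum(x$mask), "fitted\n")
  invisible(x)
}

#' Predict diffusion-weighted signals from a tensor field
#'
#' Forward Stejskal-Tanner model
#' \eqn{S_k = S_0 \exp(-b_k\, g_k^T D\, g_k)}; the generator behind the
#' digital phantoms and the tensor-fit oracle.
#'
#' @param tensors n x 6 matrix of packed tensors (Dxx, Dxy, Dxz, Dyy, Dyz,
#'   Dzz) in mm^2/s.
#' @param s0 length-n vector of non-weighted signals.
#' @param gtab a [gradient_table()].
#' @return n x K signal matrix.
#' @export
predict_signal <- function(tensors, s0, gtab) {
  tensors <- matrix(tensors, ncol = 6L)
  X <- tensor_design_matrix(gtab)      # K x 7; cols 2:7 already carry -b
  expo <- tensors %*% t(X[, 2:7, drop = FALSE])
  s0 * exp(expo)
}

# pack a symmetric 3x3 matrix to the 6-vector convention
pack_tensor <- function(D) {
  c(D[1, 1], D[1, 2], D[1, 3], D[2, 2], D[2, 3], D[3, 3])
}

# unpack a 6-vector to the symmetric 3x3 matrix
unpack_tensor <- function(v) {
  matrix(c(v[1], v[2], v[3],
           v[2], v[4], v[5],
           v[3], v[5], v[6]), 3, 3)
}

# tensor with eigenvalues evals and principal axis along unit vector e1;
# the two minor axes are any orthonormal completion (isotropic in the
# radial plane whenever evals[2] == evals[3])
tensor_from_axis <- function(evals, e1) {
  e1 <- e1 / sqrt(sum(e1^2))
  ref <- if (abs(e1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e2 <- ref - sum(ref * e1) * e1
  e2 <- e2 / sqrt(sum(e2^2))
  e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
          e1[3] * e2[1] - e1[1] * e2[3],
          e1[1] * e2[2] - e1[2] * e2[1])
  V <- cbind(e1, e2, e3)
  V %*% diag(evals) %*% t(V)
}
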