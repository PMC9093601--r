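#' Diffusion gradient table
#'
#' Bundles b-values (s/mm^2) with unit gradient direction vectors. A valid
#' table for tensor fitting needs at least six non-collinear diffusion-
#' weighted directions plus at least one b = 0 measurement, otherwise the
#' six tensor components and the non-weighted signal cannot be identified.
#'
#' @param bvals numeric vector of b-values in s/mm^2.
#' @param bvecs n x 3 matrix of gradient directions (unit vectors for b > 0;
#'   b = 0 rows may be zero).
#' @param validate check invariants (default TRUE).
#' @return object of class `gradient_table` with elements `bvals`, `bvecs`.
#' @export
gradient_table <- function(bvals, bvecs, validate = TRUE) {
  bvals <- as.numeric(bvals)
  bvecs <- rbind3(bvecs)
  if (length(bvals) != nrow(bvecs)) {
    stop("gradient table length mismatch: ", length(bvals), " b-values vs ",
         nrow(bvecs), " directions")
  }
  dw <- bvals > 0
  norms <- sqrt(rowSums(bvecs^2))
  if (any(dw)) {
    bad <- dw & abs(norms - 1) > 1e-3
    if (any(bad)) {
      stop("diffusion-weighted gradient directions must be unit vectors; ",
           sum(bad), " deviate from norm 1 by more than 1e-3")
    }
    # re-normalize small deviations so downstream code sees exact units
    bvecs[dw, ] <- bvecs[dw, , drop = FALSE] / norms[dw]
  }
  gtab <- structure(list(bvals = bvals, bvecs = bvecs),
                    class = "gradient_table")
  if (validate) assert_fit_determined(gtab)
  gtab
}

# the tensor fit solves for 7 unknowns (6 tensor components + log S0);
# the design matrix must therefore have rank 7
assert_fit_determined <- function(gtab) {
  if (!any(gtab$bvals == 0)) {
    stop("gradient table has no b = 0 measurement; S0 is unidentifiable")
  }
  if (sum(gtab$bvals > 0) < 6) {
    stop("gradient table has fewer than 6 diffusion-weighted directions; ",
         "the tensor fit is underdetermined")
  }
  X <- tensor_design_matrix(gtab)
  if (qr(X)$rank < 7L) {
    stop("gradient directions are collinear/degenerate; the tensor design ",
         "matrix has rank ", qr(X)$rank, " < 7")
  }
  invisible(gtab)
}

# design matrix of ln(S_k) = ln(S0) - b_k g^T D g, with D packed as
# (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz); columns: intercept then -b * quadratic form
tensor_design_matrix <- function(gtab) {
  g <- gtab$bvecs
  b <- gtab$bvals
  cbind(1,
        -b * g[, 1]^2,
        -b * 2 * g[, 1] * g[, 2],
        -b * 2 * g[, 1] * g[, 3],
        -b * g[, 2]^2,
        -b * 2 * g[, 2] * g[, 3],
        -b * g[, 3]^2)
}

#' @export
print.gradient_table <- function(x, ...) {
  cat("Gradient table:", length(x$bvals), "entries (",
      sum(x$bvals > 0), "diffusion-weighted,", sum(x$bvals == 0), "b0 )\n")
  cat("  b-values:", paste(unique(x$bvals), collapse = ", "), "s/mm^2\n")
  invisible(x)
}

#' @export
length.gradient_table <- function(x) length(x$bvals)

#' Deterministic spread of unit directions over the sphere
#'
#' Generates an approximately uniform set of gradient directions using the
#' spherical Fibonacci (golden-angle) lattice over a hemisphere, the usual
#' stand-in for electrostatic-repulsion schemes in simulation work.
#'
#' @param n number of directions.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  # hemisphere (z >= 0): antipodal directions are equivalent for DTI
  z <- i / n
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Default acquisition scheme: 41 directions at b = 1,000 plus 5 b0
#'
#' @param n_dirs number of diffusion-weighted directions (default 41).
#' @param n_b0 number of b = 0 volumes (default 5).
#' @param bvalue diffusion weighting in s/mm^2 (default 1000).
#' @return a [gradient_table()].
#' @export
default_gradient_table <- function(n_dirs = 41L, n_b0 = 5L, bvalue = 1000) {
  bvals <- c(rep(0, n_b0), rep(bvalue, n_dirs))
  bvecs <- rbind(matrix(0, n_b0, 3), fibonacci_directions(n_dirs))
  gradient_table(bvals, bvecs)
}
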