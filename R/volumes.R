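#' 4D diffusion-weighted volume
#'
#' @param data 4D non-negative array (x, y, z, measurement).
#' @param affine 4x4 voxel-to-world matrix (RAS+ mm, 0-based voxel indices).
#' @param gtab a [gradient_table()] whose length matches the 4th dimension.
#' @return object of class `dwi_volume`.
#' @export
dwi_volume <- function(data, affine, gtab) {
  stopifnot(length(dim(data)) == 4L, inherits(gtab, "gradient_table"))
  if (dim(data)[4] != length(gtab$bvals)) {
    stop("4th dimension (", dim(data)[4], ") does not match gradient table ",
         "length (", length(gtab$bvals), ")")
  }
  check_affine(affine)
  if (any(data < 0)) stop("DWI signal must be non-negative")
  structure(list(data = data, affine = affine, gtab = gtab),
            class = "dwi_volume")
}

check_affine <- function(affine) {
  if (!is.matrix(affine) || !all(dim(affine) == c(4, 4))) {
    stop("affine must be a 4x4 matrix")
  }
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < 1e-12) {
    stop("affine is not invertible (det = ", format(det3), ")")
  }
  invisible(affine)
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("DWI volume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "measurements\n")
  print(x$gtab)
  invisible(x)
}

#' 3D scalar map (FA, diffusivity, mask, ...)
#'
#' @param data 3D array.
#' @param affine 4x4 voxel-to-world matrix.
#' @param kind one of "FA", "MD", "L1", "RD", "S0", "T1like", "mask".
#' @return object of class `scalar_map`.
#' @export
scalar_map <- function(data, affine,
                       kind = c("FA", "MD", "L1", "RD", "S0", "T1like",
                                "mask")) {
  kind <- match.arg(kind)
  stopifnot(length(dim(data)) == 3L)
  check_affine(affine)
  fin <- data[is.finite(data)]
  if (kind == "FA" && length(fin) && (min(fin) < -1e-9 || max(fin) > 1 + 1e-9)) {
    stop("FA map values must lie in [0, 1]")
  }
  if (kind %in% c("MD", "L1", "RD") && length(fin) && min(fin) < -1e-15) {
    stop(kind, " map values must be non-negative")
  }
  if (kind == "mask") data <- (data != 0) * 1
  structure(list(data = data, affine = affine, kind = kind),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  fin <- x$data[is.finite(x$data)]
  cat("Scalar map [", x$kind, "]: ",
      paste(dim(x$data), collapse = " x "), " voxels, range ",
      format(min(fin)), " .. ", format(max(fin)), "\n", sep = "")
  invisible(x)
}

#' Sample a scalar map at world coordinates
#'
#' @param map a [scalar_map()].
#' @param world n x 3 matrix of world mm coordinates.
#' @param method "trilinear" or "nearest".
#' @return numeric vector (`NA` outside the volume).
#' @export
sample_map <- function(map, world, method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  vox <- world_to_voxel(world, map$affine)
  if (method == "trilinear") trilinear_sample(map$data, vox)
  else nearest_sample(map$data, vox)
}

#' Streamline tractogram
#'
#' Streamlines are stored as a list of n x 3 matrices of ordered points in
#' world RAS+ millimetres, so tract selection is resolution independent.
#'
#' @param streamlines list of n x 3 numeric matrices (n >= 2).
#' @param provenance named list recording seed parameters and source image.
#' @return object of class `tractogram`.
#' @export
tractogram <- function(streamlines = list(), provenance = list()) {
  for (s in streamlines) {
    if (!is.matrix(s) || ncol(s) != 3L || nrow(s) < 2L) {
      stop("every streamline must be an n x 3 matrix with n >= 2 points")
    }
  }
  structure(list(streamlines = streamlines,
                 space = "world-RAS-mm",
                 provenance = provenance),
            class = "tractogram")
}

#' @export
length.tractogram <- function(x) length(x$streamlines)

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  cat("Tractogram:", n, "streamlines (world RAS+ mm)\n")
  if (n) {
    len <- vapply(x$streamlines, streamline_length, numeric(1))
    cat("  length: mean", round(mean(len), 1), "mm, range",
        round(min(len), 1), "-", round(max(len), 1), "mm\n")
  }
  invisible(x)
}

#' Arc length of one streamline (mm)
#' @param points n x 3 matrix of points.
#' @export
streamline_length <- function(points) {
  if (nrow(points) < 2L) return(0)
  sum(sqrt(rowSums(diff(points)^2)))
}

#' Apply a world-space transform to all streamlines
#' @param tractogram a [tractogram()].
#' @param matrix4 4x4 world-to-world transform.
#' @export
transform_tractogram <- function(tractogram, matrix4) {
  tractogram$streamlines <- lapply(tractogram$streamlines, apply_transform,
                                   matrix4 = matrix4)
  tractogram
}
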