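#' Read a diffusion-weighted dataset (NIfTI + FSL bval/bvec)
#'
#' @param nifti_path path to a 4D NIfTI-1 file.
#' @param bval_path path to a whitespace-delimited b-value text file.
#' @param bvec_path path to the matching gradient-direction file; both the
#'   3 x N and N x 3 layouts are accepted and auto-detected by shape.
#' @return a [dwi_volume()].
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path) {
  for (p in c(nifti_path, bval_path, bvec_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L) {
    stop("expected a 4D volume, got ", length(dim(arr)), " dimensions")
  }
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  gtab <- read_bval_bvec(bval_path, bvec_path)
  dwi_volume(arr, affine, gtab)
}

#' Read FSL-style bval/bvec text files
#'
#' @inheritParams read_dwi
#' @return a [gradient_table()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  raw <- as.matrix(utils::read.table(bvec_path))
  # FSL dialect: 3 rows of N entries; transposed N x 3 also occurs
  if (nrow(raw) == 3L && ncol(raw) != 3L) {
    bvecs <- t(raw)
  } else if (ncol(raw) == 3L && nrow(raw) != 3L) {
    bvecs <- raw
  } else if (all(dim(raw) == 3L)) {
    bvecs <- raw  # ambiguous 3 x 3: treat rows as directions
  } else {
    stop("bvec file must be 3 x N or N x 3, got ",
         nrow(raw), " x ", ncol(raw))
  }
  dimnames(bvecs) <- NULL
  gradient_table(bvals, bvecs)
}

#' Write a gradient table as FSL bval/bvec files
#'
#' @param gtab a [gradient_table()].
#' @param bval_path,bvec_path output paths; bvecs are written 3 x N.
#' @return invisibly, the two paths.
#' @export
write_bval_bvec <- function(gtab, bval_path, bvec_path) {
  writeLines(paste(format(gtab$bvals, trim = TRUE), collapse = " "),
             bval_path)
  m <- t(gtab$bvecs)
  writeLines(apply(m, 1, function(r)
    paste(format(r, trim = TRUE, digits = 17), collapse = " ")), bvec_path)
  invisible(c(bval_path, bvec_path))
}

#' Write a DWI volume as NIfTI + bval/bvec
#'
#' @param dwi a [dwi_volume()].
#' @param nifti_path,bval_path,bvec_path output paths.
#' @return invisibly, `nifti_path`.
#' @export
write_dwi <- function(dwi, nifti_path, bval_path, bvec_path) {
  write_nifti_array(dwi$data, dwi$affine, nifti_path)
  write_bval_bvec(dwi$gtab, bval_path, bvec_path)
  invisible(nifti_path)
}

#' Write a scalar map as a NIfTI-1 file
#'
#' @param map a [scalar_map()].
#' @param path output .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
write_scalar_map <- function(map, path) {
  write_nifti_array(map$data, map$affine, path)
  invisible(path)
}

#' Read a scalar map from a NIfTI-1 file
#'
#' @param path NIfTI file path.
#' @param kind map kind tag (see [scalar_map()]).
#' @return a [scalar_map()].
#' @export
read_scalar_map <- function(path, kind = "FA") {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D volume")
  affine <- unclass(RNifti::xform(img))
  attributes(affine) <- list(dim = c(4L, 4L))
  scalar_map(arr, affine, kind)
}

# shared NIfTI writer: data stored float64, sform/qform from the affine
write_nifti_array <- function(arr, affine, path) {
  img <- RNifti::asNifti(arr)
  pd <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (length(dim(arr)) == 4L) pd <- c(pd, 1)
  RNifti::pixdim(img) <- pd
  xf <- structure(affine, code = 2L)
  RNifti::sform(img) <- xf
  RNifti::qform(img) <- xf
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
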