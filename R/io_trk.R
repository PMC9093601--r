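# TrackVis .trk container (version 2, 1000-byte header). No R package in
# this stack reads TRK, so the binary layout is implemented here directly.
# Points are stored exactly as held in the tractogram (world RAS+ mm) with a
# unit voxel size and an identity vox-to-ras, i.e. the file's coordinate
# frame *is* world mm; float32 storage bounds the round-trip error.

TRK_HEADER_SIZE <- 1000L

#' Write a tractogram to a TrackVis .trk file
#'
#' @param tractogram a [tractogram()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_trk <- function(tractogram, path) {
  stopifnot(inherits(tractogram, "tractogram"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("TRACK", con, nchars = 5, eos = NULL)
  writeBin(as.raw(0L), con)                               # id_string pad
  writeBin(as.integer(c(1L, 1L, 1L)), con, size = 2)      # dim (unused)
  writeBin(c(1, 1, 1), con, size = 4)                     # voxel_size
  writeBin(c(0, 0, 0), con, size = 4)                     # origin
  writeBin(0L, con, size = 2)                             # n_scalars
  writeBin(raw(200), con)                                 # scalar names
  writeBin(0L, con, size = 2)                             # n_properties
  writeBin(raw(200), con)                                 # property names
  writeBin(as.numeric(diag(4)), con, size = 4)            # vox_to_ras
  writeBin(raw(444), con)                                 # reserved
  writeChar("RAS", con, nchars = 3, eos = NULL)           # voxel_order
  writeBin(raw(1), con)
  writeBin(raw(4), con)                                   # pad2
  writeBin(rep(0, 6), con, size = 4)                      # image orientation
  writeBin(raw(2), con)                                   # pad1
  writeBin(raw(6), con)                                   # invert/swap flags
  writeBin(length(tractogram$streamlines), con, size = 4) # n_count
  writeBin(2L, con, size = 4)                             # version
  writeBin(TRK_HEADER_SIZE, con, size = 4)                # hdr_size
  for (s in tractogram$streamlines) {
    writeBin(nrow(s), con, size = 4)
    writeBin(as.numeric(t(s)), con, size = 4)
  }
  invisible(path)
}

#' Read a TrackVis .trk file
#'
#' @param path .trk file path.
#' @return a [tractogram()]; scalars/properties, if present, are skipped.
#' @export
read_trk <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  id <- rawToChar(readBin(con, raw(), 6)[1:5])
  if (id != "TRACK") {
    stop("malformed TRK header: id_string is not 'TRACK'")
  }
  readBin(con, integer(), 3, size = 2)          # dim
  readBin(con, numeric(), 3, size = 4)          # voxel_size
  readBin(con, numeric(), 3, size = 4)          # origin
  n_scalars <- readBin(con, integer(), 1, size = 2)
  readBin(con, raw(), 200)
  n_properties <- readBin(con, integer(), 1, size = 2)
  readBin(con, raw(), 200)
  readBin(con, numeric(), 16, size = 4)         # vox_to_ras
  readBin(con, raw(), 444)
  readBin(con, raw(), 4)                        # voxel_order
  readBin(con, raw(), 4)                        # pad2
  readBin(con, numeric(), 6, size = 4)
  readBin(con, raw(), 2)
  readBin(con, raw(), 6)
  n_count <- readBin(con, integer(), 1, size = 4)
  readBin(con, integer(), 1, size = 4)          # version
  hdr_size <- readBin(con, integer(), 1, size = 4)
  if (!identical(hdr_size, TRK_HEADER_SIZE)) {
    stop("malformed TRK header: hdr_size is ", hdr_size, ", expected 1000")
  }
  if (n_scalars < 0 || n_scalars > 10) {
    stop("malformed TRK header: n_scalars is ", n_scalars)
  }
  if (n_properties < 0 || n_properties > 10) {
    stop("malformed TRK header: n_properties is ", n_properties)
  }
  streamlines <- list()
  repeat {
    m <- readBin(con, integer(), 1, size = 4)
    if (length(m) == 0L) break
    if (m < 0) stop("malformed TRK body: negative point count")
    vals <- readBin(con, numeric(), m * (3L + n_scalars), size = 4)
    if (n_properties > 0) readBin(con, numeric(), n_properties, size = 4)
    pts <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3,
                                                             drop = FALSE]
    streamlines[[length(streamlines) + 1L]] <- pts
  }
  if (n_count > 0 && length(streamlines) != n_count) {
    warning("TRK n_count (", n_count, ") disagrees with streamlines read (",
            length(streamlines), ")")
  }
  tractogram(streamlines, provenance = list(source = path))
}

#' Write a tractogram as JSON (debugging fallback)
#'
#' @param tractogram a [tractogram()].
#' @param path output .json path.
#' @return the path, invisibly.
#' @export
write_tractogram_json <- function(tractogram, path) {
  obj <- list(space = tractogram$space,
              provenance = tractogram$provenance,
              streamlines = lapply(tractogram$streamlines, function(s)
                unname(as.data.frame(s))))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
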