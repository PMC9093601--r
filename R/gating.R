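# Resolution of declarative gates to voxel masks, and streamline selection
# by AND/NOT set logic.

#' Reference geometry for gate resolution
#'
#' @param shape grid dimensions.
#' @param affine 4x4 voxel-to-world matrix.
#' @param structures named list of logical arrays (landmark masks) on the
#'   grid; placement rules cite structures by these names.
#' @return object of class `reference_geometry`.
#' @export
reference_geometry <- function(shape, affine, structures) {
  stopifnot(is.list(structures), length(names(structures)) ==
              length(structures))
  structure(list(shape = as.integer(shape), affine = affine,
                 structures = structures),
            class = "reference_geometry")
}

#' Reference geometry of a phantom subject
#' @param truth subject truth list from [generate_subject()].
#' @export
phantom_reference <- function(truth) {
  reference_geometry(dim(truth$skull_mask), truth$affine, truth$structures)
}

# world-extent (min, max) of a structure mask along axis 1..3, padded by
# half a voxel pitch on each side
structure_extent <- function(ref, name, axis) {
  m <- ref$structures[[name]]
  if (is.null(m)) {
    stop("reference geometry has no structure named '", name, "'")
  }
  if (!any(m)) stop("structure '", name, "' is empty")
  idx <- which(m, arr.ind = TRUE) - 1L
  w <- voxel_to_world(idx, ref$affine)[, axis]
  pitch <- sqrt(sum(ref$affine[1:3, axis]^2))
  c(min(w) - pitch / 2, max(w) + pitch / 2)
}

plane_normal_axis <- function(plane) {
  switch(plane, axial = 3L, coronal = 2L, sagittal = 1L, parasagittal = 1L)
}

#' Resolve a recipe's gates to voxel masks on a reference grid
#'
#' Fractional placements are measured along the anterior-posterior world
#' axis (+y = anterior in RAS+) of the named structure's bounding extent;
#' "entire" gates span the full in-plane extent of the resolved slab.
#' Expanding a bilateral recipe for one side intersects its AND gates with
#' that hemisphere (x < 0 = left, x > 0 = right); NOT gates stay global.
#'
#' @param recipe a [tract_recipe()].
#' @param reference a [reference_geometry()].
#' @param side "n/a" for midline recipes, else "left" or "right".
#' @param slab_mm slab thickness used for single-slice rules (default one
#'   voxel pitch, with a 3 mm floor).
#' @return list of resolved gates, each `list(polarity, mask)` where `mask`
#'   is a logical array on the reference grid.
#' @export
resolve_gates <- function(recipe, reference, side = "n/a", slab_mm = NULL) {
  stopifnot(inherits(recipe, "tract_recipe"),
            inherits(reference, "reference_geometry"))
  if (recipe$laterality == "bilateral" && !side %in% c("left", "right")) {
    stop("bilateral recipe '", recipe$tract,
         "' must be resolved for side 'left' or 'right'")
  }
  W <- grid_world_coords(reference$shape, reference$affine)
  if (is.null(slab_mm)) {
    slab_mm <- max(3, max(sqrt(colSums(reference$affine[1:3, 1:3]^2))))
  }
  lapply(recipe$gates, function(g) {
    mask <- resolve_one_gate(g, reference, W, slab_mm)
    if (g$polarity == "AND" && recipe$laterality == "bilateral") {
      hemi <- if (side == "left") W[, 1] < 0 else W[, 1] > 0
      mask <- mask & hemi
    }
    list(polarity = g$polarity, mask = array(mask, reference$shape),
         affine = reference$affine)
  })
}

resolve_one_gate <- function(g, ref, W, slab_mm) {
  p <- g$placement
  ax <- plane_normal_axis(g$plane)
  n <- nrow(W)
  keep <- rep(TRUE, n)
  inplane_axes <- setdiff(1:3, ax)

  interval_on <- function(axis, lo, hi) W[, axis] >= lo & W[, axis] <= hi

  if (p$type == "fraction") {
    # slab over a fraction of the structure's anterior-posterior extent
    ext_y <- structure_extent(ref, p$structure, 2L)
    L <- diff(ext_y)
    edge <- if (is.null(p$edge)) "anterior" else p$edge
    fr <- as.numeric(p$from); to <- as.numeric(p$to)
    if (edge == "anterior") {
      lo <- ext_y[2] - to * L; hi <- ext_y[2] - fr * L
    } else {
      lo <- ext_y[1] + fr * L; hi <- ext_y[1] + to * L
    }
    keep <- keep & interval_on(2L, lo, hi)
    if (ax != 2L) {
      # the drawing plane covers the structure's extent along its normal
      exn <- structure_extent(ref, p$structure, ax)
      keep <- keep & interval_on(ax, exn[1], exn[2])
    }
  } else if (p$type == "slice") {
    edge <- p$edge
    axis <- switch(edge,
                   anterior = 2L, posterior = 2L,
                   superior = 3L, inferior = 3L,
                   lateral = 1L,
                   stop("unknown slice edge '", edge, "'"))
    exn <- structure_extent(ref, p$structure, axis)
    off <- if (is.null(p$offset_mm)) 0 else as.numeric(p$offset_mm)
    if (edge == "lateral") {
      # one slab at each lateral face; side filtering happens via hemisphere
      keep <- keep & (interval_on(1L, exn[1] + off - slab_mm, exn[1] + off) |
                      interval_on(1L, exn[2] - off, exn[2] - off + slab_mm))
    } else {
      pos <- if (edge %in% c("anterior", "superior")) exn[2] else exn[1]
      pos <- pos + off
      keep <- keep & interval_on(axis, pos - slab_mm / 2, pos + slab_mm / 2)
    }
  } else if (p$type == "at_center") {
    exn <- structure_extent(ref, p$structure, ax)
    cen <- mean(exn)
    keep <- keep & interval_on(ax, cen - slab_mm / 2, cen + slab_mm / 2)
  } else if (p$type == "midline") {
    keep <- keep & interval_on(1L, -slab_mm / 2, slab_mm / 2)
  } else if (p$type == "lateral_of") {
    gap <- if (is.null(p$gap_mm)) 1 else as.numeric(p$gap_mm)
    exn <- structure_extent(ref, p$structure, 1L)
    left_reg <- W[, 1] <= exn[1] - gap
    right_reg <- W[, 1] >= exn[2] + gap
    keep <- keep & switch(g$side,
                          left = left_reg,
                          right = right_reg,
                          both = left_reg | right_reg)
  } else {
    stop("unknown placement type '", p$type, "'")
  }

  if (g$extent != "entire") {
    sname <- g$extent_structure
    box <- rep(TRUE, n)
    for (a in inplane_axes) {
      exs <- structure_extent(ref, sname, a)
      box <- box & interval_on(a, exs[1], exs[2])
    }
    if (g$extent == "structure") keep <- keep & box
    else keep <- keep & !box
  }
  keep
}

#' Select streamlines with resolved AND/NOT gates
#'
#' A streamline is kept iff at least one of its vertices falls inside every
#' AND mask and none falls inside any NOT mask (vertex-based intersection;
#' at the default half-voxel step no segment can tunnel through a slab).
#'
#' @param tractogram a [tractogram()].
#' @param gates resolved gates from [resolve_gates()] (or any list of
#'   `list(polarity, mask)`), with masks on `affine`'s grid.
#' @param affine voxel-to-world matrix of the gate masks.
#' @return list with `streamlines` (the selected [tractogram()]),
#'   `generated` (TRUE iff at least one streamline was kept) and `kept`
#'   (logical index into the input).
#' @export
select_tract <- function(tractogram, gates, affine) {
  n <- length(tractogram$streamlines)
  if (n == 0L) {
    return(list(streamlines = tractogram, generated = FALSE,
                kept = logical(0)))
  }
  counts <- vapply(tractogram$streamlines, nrow, integer(1))
  sl_id <- rep.int(seq_len(n), counts)
  verts <- do.call(rbind, tractogram$streamlines)
  vox <- round(world_to_voxel(verts, affine))
  keep <- rep(TRUE, n)
  for (g in gates) {
    d <- dim(g$mask)
    inb <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
           vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
           vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
    hit_v <- rep(FALSE, nrow(vox))
    if (any(inb)) {
      hit_v[inb] <- g$mask[cbind(vox[inb, 1] + 1, vox[inb, 2] + 1,
                                 vox[inb, 3] + 1)]
    }
    hit_sl <- as.logical(rowsum(hit_v * 1, sl_id, reorder = TRUE) > 0)
    keep <- keep & (if (g$polarity == "AND") hit_sl else !hit_sl)
  }
  sel <- tractogram
  sel$streamlines <- tractogram$streamlines[keep]
  if (!is.null(tractogram$provenance$seed_points)) {
    sel$provenance$seed_points <-
      tractogram$provenance$seed_points[keep, , drop = FALSE]
  }
  list(streamlines = sel, generated = any(keep), kept = keep)
}
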