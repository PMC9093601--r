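# ACPC landmark alignment, affine FA-map registration, gate propagation and
# atlas-label metric extraction.

#' Construct a rigid or affine world-to-world transform
#'
#' @param matrix 4x4 transform acting on world mm coordinates.
#' @param kind "rigid" or "affine".
#' @param provenance named list (fixed/moving ids, cost, ...).
#' @return object of class `spatial_transform`.
#' @export
spatial_transform <- function(matrix, kind = c("rigid", "affine"),
                              provenance = list()) {
  kind <- match.arg(kind)
  check_affine(matrix)
  if (kind == "rigid") {
    R <- matrix[1:3, 1:3]
    if (max(abs(t(R) %*% R - diag(3))) > 1e-6 || det(R) < 0) {
      stop("rigid transform must have an orthonormal rotation block with ",
           "det = +1")
    }
  }
  structure(list(matrix = matrix, kind = kind, provenance = provenance),
            class = "spatial_transform")
}

#' @export
print.spatial_transform <- function(x, ...) {
  cat("Spatial transform (", x$kind, "):\n", sep = "")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Compose two transforms (apply `a` after `b`)
#' @param a,b `spatial_transform`s.
#' @export
compose_transform <- function(a, b) {
  kind <- if (a$kind == "rigid" && b$kind == "rigid") "rigid" else "affine"
  spatial_transform(a$matrix %*% b$matrix, kind)
}

#' Invert a transform
#' @param x a `spatial_transform`.
#' @export
invert_transform <- function(x) {
  spatial_transform(solve(x$matrix), x$kind, x$provenance)
}

#' Rigid ACPC alignment from three landmarks
#'
#' Builds the rigid transform that maps the anterior commissure (AC) to the
#' origin, the AC-to-PC direction onto the -y axis (so both commissures lie
#' on a horizontal line), and the midsagittal plane through AC, PC and a
#' third midline point onto x = 0.
#'
#' @param landmarks named list with `AC`, `PC` and `MS` (a midsagittal
#'   point off the AC-PC line), world mm.
#' @return a rigid `spatial_transform` (subject world -> aligned world).
#' @export
acpc_align <- function(landmarks) {
  ac <- as.numeric(landmarks$AC)
  pc <- as.numeric(landmarks$PC)
  ms <- as.numeric(landmarks$MS)
  v1 <- pc - ac
  v2 <- ms - ac
  cr <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  if (sqrt(sum(cr^2)) < 1e-9 * sqrt(sum(v1^2)) * sqrt(sum(v2^2))) {
    stop("ACPC landmarks are collinear; the midsagittal plane is undefined")
  }
  yhat <- -v1 / sqrt(sum(v1^2))               # AC -> PC maps to -y
  xhat <- cr / sqrt(sum(cr^2))                # midsagittal normal
  zhat <- c(xhat[2] * yhat[3] - xhat[3] * yhat[2],
            xhat[3] * yhat[1] - xhat[1] * yhat[3],
            xhat[1] * yhat[2] - xhat[2] * yhat[1])
  # the midsagittal reference point is superior by convention; this fixes
  # the left-right sign of the sagittal normal (flipping x flips z with it,
  # so the frame stays right-handed)
  if (sum(zhat * v2) < 0) {
    xhat <- -xhat
    zhat <- -zhat
  }
  Q <- cbind(xhat, yhat, zhat)                # aligned axes in subject frame
  R <- t(Q)
  m <- rigid_matrix(R, -as.vector(R %*% ac))
  spatial_transform(m, "rigid",
                    provenance = list(method = "acpc_landmarks"))
}

#' Resample a scalar map through a world transform onto a fixed grid
#'
#' @param map moving [scalar_map()].
#' @param transform `spatial_transform` mapping moving world to fixed world.
#' @param shape,affine target grid (defaults: the moving map's own grid).
#' @param method "trilinear" or "nearest".
#' @param fill value for voxels mapping outside the moving volume.
#' @return a [scalar_map()] on the target grid.
#' @export
resample_map <- function(map, transform, shape = dim(map$data),
                         affine = map$affine,
                         method = c("trilinear", "nearest"), fill = 0) {
  method <- match.arg(method)
  W <- grid_world_coords(shape, affine)
  src <- apply_transform(W, solve(transform$matrix))
  vals <- sample_map(map, src, method)
  vals[is.na(vals)] <- fill
  scalar_map(array(vals, shape), affine, map$kind)
}

#' Deterministic multiresolution affine registration of two scalar maps
#'
#' Estimates the 12-parameter affine (translation, rotation, anisotropic
#' scale, shear about the fixed-image centre) minimizing the mean squared
#' intensity difference, by coordinate-wise pattern search with a fixed
#' step schedule over a 3-level image pyramid. Entirely deterministic:
#' no random restarts, no stochastic sampling.
#'
#' @param moving,fixed [scalar_map()]s of the same modality (FA suggested).
#' @param levels number of pyramid levels (default 3; level k is block-
#'   averaged by 2^(levels-k)).
#' @param max_iter pattern-search sweeps per level.
#' @param init optional initial `spatial_transform` (moving -> fixed).
#' @return an affine `spatial_transform` (moving world -> fixed world);
#'   provenance records the final cost and the per-level cost trace (the
#'   cost never increases across levels).
#' @export
register_affine <- function(moving, fixed, levels = 3L, max_iter = 40L,
                            init = NULL) {
  stopifnot(inherits(moving, "scalar_map"), inherits(fixed, "scalar_map"))
  centre <- as.vector(voxel_to_world((dim(fixed$data) - 1) / 2,
                                     fixed$affine))
  # parameters: tx ty tz (mm), rx ry rz (deg), log-scale x3, shear x3
  par <- rep(0, 12)
  steps0 <- c(rep(8, 3), rep(8, 3), rep(0.12, 3), rep(0.08, 3))
  if (!is.null(init)) {
    stop_if_not_overlapping(moving, fixed, init)
  }
  # cost environment for the finest level (used for the comparable trace)
  finest <- make_msd_cost(moving, fixed, 1L, centre, init)
  cost_trace <- numeric(0)
  sweep_search <- function(cost, par, steps, steps0, active, max_iter) {
    cur <- cost(par)
    st <- steps
    for (it in seq_len(max_iter)) {
      improved <- FALSE
      for (j in active) {
        for (s in c(st[j], -st[j])) {
          cand <- par
          cand[j] <- cand[j] + s
          cc <- cost(cand)
          if (cc < cur - 1e-12) {
            par <- cand
            cur <- cc
            improved <- TRUE
          }
        }
      }
      if (!improved) {
        st <- st / 2
        if (max(st / steps0) < 1 / 256) break
      }
    }
    par
  }
  for (lev in seq_len(levels)) {
    fac <- 2L^(levels - lev)
    # the finest level runs its search on a stride-2 subgrid (8x cheaper),
    # followed by a short full-resolution polish with small steps
    stride <- if (fac == 1L) 2L else 1L
    cost <- make_msd_cost(moving, fixed, fac, centre, init, stride = stride)
    steps <- steps0 / 2^(lev - 1)
    # rigid parameters first, then the full affine set: scale and shear
    # cannot silently compensate an unresolved translation
    par <- sweep_search(cost, par, steps, steps0, 1:6, max_iter)
    par <- sweep_search(cost, par, steps, steps0, 1:12, max_iter)
    if (stride > 1L) {
      par <- sweep_search(finest, par, steps0 / 16, steps0, 1:12, 16L)
    }
    cost_trace <- c(cost_trace, finest(par))
    pt_log("register_affine level ", lev, " cost ",
           cost_trace[length(cost_trace)])
  }
  m <- params_to_affine(par, centre)
  if (!is.null(init)) m <- m %*% init$matrix
  spatial_transform(m, "affine",
                    provenance = list(cost = cost_trace[length(cost_trace)],
                                      cost_trace = cost_trace,
                                      params = par))
}

# build a closure computing the MSD cost at one pyramid level; the fixed
# grid world coordinates and data vector are precomputed once
make_msd_cost <- function(moving, fixed, fac, centre, init, stride = 1L) {
  fx <- downsample_map(fixed, fac)
  mv <- downsample_map(moving, fac)
  W <- grid_world_coords(dim(fx$data), fx$affine)
  fixvec <- as.vector(fx$data)
  if (stride > 1L) {
    d <- dim(fx$data)
    gi <- expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                      k = seq_len(d[3]))
    sel <- gi$i %% stride == 1L & gi$j %% stride == 1L &
           gi$k %% stride == 1L
    W <- W[sel, , drop = FALSE]
    fixvec <- fixvec[sel]
  }
  inv_init <- if (is.null(init)) NULL else solve(init$matrix)
  inv_mv_affine <- solve(mv$affine)
  mdata <- mv$data
  function(p) {
    m <- params_to_affine(p, centre)
    inv <- solve(m)
    if (!is.null(inv_init)) inv <- inv_init %*% inv
    A <- inv_mv_affine[1:3, 1:3] %*% inv[1:3, 1:3]
    b <- as.vector(inv_mv_affine[1:3, 1:3] %*% inv[1:3, 4] +
                     inv_mv_affine[1:3, 4])
    vox <- t(A %*% t(W) + b)
    vals <- trilinear_sample(mdata, vox)
    vals[is.na(vals)] <- 0
    mean((vals - fixvec)^2)
  }
}

stop_if_not_overlapping <- function(moving, fixed, init) {
  cw <- voxel_to_world((dim(fixed$data) - 1) / 2, fixed$affine)
  src <- apply_transform(cw, solve(init$matrix))
  vox <- world_to_voxel(src, moving$affine)
  d <- dim(moving$data)
  if (any(vox < -d) || any(vox > 2 * d)) {
    stop("initial transform places the images far apart; ",
         "fields of view do not overlap")
  }
}

# 12-parameter affine about a centre: T * C * Rz Ry Rx * Scale * Shear * C^-1
params_to_affine <- function(par, centre) {
  rad <- par[4:6] * pi / 180
  Rx <- rotation_matrix(c(1, 0, 0), rad[1])
  Ry <- rotation_matrix(c(0, 1, 0), rad[2])
  Rz <- rotation_matrix(c(0, 0, 1), rad[3])
  S <- diag(exp(par[7:9]))
  H <- diag(3)
  H[1, 2] <- par[10]; H[1, 3] <- par[11]; H[2, 3] <- par[12]
  A <- Rz %*% Ry %*% Rx %*% S %*% H
  m <- diag(4)
  m[1:3, 1:3] <- A
  m[1:3, 4] <- par[1:3] + centre - as.vector(A %*% centre)
  m
}

# block-average downsampling by an integer factor (pyramid level)
downsample_map <- function(map, fac) {
  if (fac <= 1L) return(map)
  d <- dim(map$data)
  nd <- pmax(1L, d %/% fac)
  arr <- map$data[seq_len(nd[1] * fac), seq_len(nd[2] * fac),
                  seq_len(nd[3] * fac), drop = FALSE]
  a <- array(arr, c(fac, nd[1], fac, nd[2], fac, nd[3]))
  sm <- apply(a, c(2, 4, 6), mean)
  aff <- map$affine
  aff[1:3, 1:3] <- aff[1:3, 1:3] * fac
  # voxel (0,0,0) of the coarse grid is the centre of the first fac^3 block
  shift <- voxel_to_world((fac - 1) / 2 * c(1, 1, 1), map$affine)
  aff[1:3, 4] <- as.vector(shift)
  scalar_map(sm, aff, map$kind)
}

#' Propagate resolved gate masks through a world transform
#'
#' Each mask is mapped with nearest-neighbour resampling onto the subject
#' grid; polarity is preserved. A gate whose mapped mask is empty is
#' recorded (`empty = TRUE`) and generally yields a missing tract
#' downstream.
#'
#' @param gates resolved gates from [resolve_gates()] (template space).
#' @param transform `spatial_transform` mapping template world to subject
#'   world.
#' @param shape,affine subject grid.
#' @return list of gates `list(polarity, mask, empty)` on the subject grid.
#' @export
propagate_rois <- function(gates, transform, shape, affine) {
  W <- grid_world_coords(shape, affine)
  src <- apply_transform(W, solve(transform$matrix))
  lapply(gates, function(g) {
    src_affine <- g$affine %||% affine
    vals <- nearest_sample(g$mask * 1, world_to_voxel(src, src_affine),
                           fill = 0)
    mask <- array(vals > 0, shape)
    if (!any(mask)) {
      pt_log("propagate_rois: gate mapped to an empty mask")
    }
    list(polarity = g$polarity, mask = mask, empty = !any(mask),
         affine = affine)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Atlas label volume with tract lookup table
#'
#' @param labels 3D integer array (0 = background).
#' @param affine 4x4 voxel-to-world matrix.
#' @param table data.frame with columns `id`, `tract`; every non-zero id in
#'   `labels` must appear.
#' @return object of class `atlas_labels`.
#' @export
atlas_labels <- function(labels, affine, table) {
  check_affine(affine)
  stopifnot(all(c("id", "tract") %in% names(table)))
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0]
  missing <- setdiff(ids, table$id)
  if (length(missing)) {
    stop("label id(s) absent from table: ", paste(missing, collapse = ", "))
  }
  structure(list(labels = labels, affine = affine,
                 table = table[, c("id", "tract")],
                 coverage = unique(table$tract)),
            class = "atlas_labels")
}

#' Read an atlas label table from TSV (columns: id, tract)
#' @param path TSV file path.
#' @export
read_label_table <- function(path) {
  utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
}

#' Extract per-tract mean metrics under warped atlas labels
#'
#' Maps every subject voxel back to atlas space (nearest-neighbour label
#' lookup) and averages each scalar map over the voxels of each label.
#' Labels with no mapped voxels produce a missing row (`generated = FALSE`,
#' metrics `NA`), not zeros. Partial atlases (covering only a subset of
#' the study tracts) are supported.
#'
#' @param maps named list with `FA`, `MD`, `L1`, `RD` [scalar_map()]s on
#'   the subject grid.
#' @param atlas an [atlas_labels()].
#' @param transform `spatial_transform` mapping atlas world to subject
#'   world (identity by default).
#' @return data.frame with one row per atlas tract: `tract`, `n_voxels`,
#'   `FA`, `MD`, `L1`, `RD`, `generated`.
#' @export
extract_label_metrics <- function(maps, atlas, transform = NULL) {
  stopifnot(inherits(atlas, "atlas_labels"))
  ref <- maps$FA
  shape <- dim(ref$data)
  if (is.null(transform)) transform <- spatial_transform(diag(4), "rigid")
  W <- grid_world_coords(shape, ref$affine)
  src <- apply_transform(W, solve(transform$matrix))
  lab <- nearest_sample(atlas$labels, world_to_voxel(src, atlas$affine),
                        fill = 0)
  rows <- lapply(seq_len(nrow(atlas$table)), function(i) {
    id <- atlas$table$id[i]
    sel <- which(lab == id)
    if (length(sel) == 0L) {
      return(data.frame(tract = atlas$table$tract[i], n_voxels = 0L,
                        FA = NA_real_, MD = NA_real_, L1 = NA_real_,
                        RD = NA_real_, generated = FALSE))
    }
    data.frame(tract = atlas$table$tract[i], n_voxels = length(sel),
               FA = mean(maps$FA$data[sel]), MD = mean(maps$MD$data[sel]),
               L1 = mean(maps$L1$data[sel]), RD = mean(maps$RD$data[sel]),
               generated = TRUE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
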