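# Per-tract metric aggregation, bilateral averaging, scaled radar and
# along-tract diffusion profiles, and the Evans' index.

#' Summarize diffusion metrics over a selected tract
#'
#' Each metric is the mean of the trilinearly sampled map values over all
#' streamline vertices (tractography-weighted averaging). Vertices falling
#' outside a map are excluded and counted.
#'
#' @param streamlines a [tractogram()] (the selected tract).
#' @param maps named list of [scalar_map()]s `FA`, `MD`, `L1`, `RD`.
#' @param subject,tract,side,method identifying tags stored in the result.
#' @return a one-row data.frame (`tract_metrics`): subject, tract, side,
#'   method, FA, MD, L1, RD, n_streamlines, n_outside, generated. An empty
#'   selection yields `generated = FALSE` with missing (`NA`) metrics,
#'   never zeros.
#' @export
tract_metrics <- function(streamlines, maps, subject = "subj", tract = "",
                          side = "midline", method = "pseudo_atlas") {
  base <- data.frame(subject = subject, tract = tract, side = side,
                     method = method, FA = NA_real_, MD = NA_real_,
                     L1 = NA_real_, RD = NA_real_, n_streamlines = 0L,
                     n_outside = 0L, generated = FALSE,
                     stringsAsFactors = FALSE)
  n <- length(streamlines$streamlines)
  if (n == 0L) return(base)
  verts <- do.call(rbind, streamlines$streamlines)
  vals <- lapply(maps[c("FA", "MD", "L1", "RD")], sample_map, world = verts)
  outside <- is.na(vals$FA)
  base$n_outside <- sum(outside)
  if (all(outside)) return(base)
  base$FA <- mean(vals$FA, na.rm = TRUE)
  base$MD <- mean(vals$MD, na.rm = TRUE)
  base$L1 <- mean(vals$L1, na.rm = TRUE)
  base$RD <- mean(vals$RD, na.rm = TRUE)
  base$n_streamlines <- n
  base$generated <- TRUE
  base
}

#' Average the left and right instances of a bilateral tract
#'
#' Arithmetic mean per metric. If exactly one side was generated, the
#' present side is carried over and flagged (`single_side = TRUE`); if
#' neither side was generated the result is missing.
#'
#' @param left,right one-row `tract_metrics` data.frames for the same
#'   tract and subject.
#' @return a one-row data.frame with `side = "both"`.
#' @export
bilateral_average <- function(left, right) {
  if (left$tract != right$tract) {
    stop("cannot average different tracts: ", left$tract, " vs ",
         right$tract)
  }
  if (left$subject != right$subject) {
    stop("cannot average different subjects")
  }
  out <- left
  out$side <- "both"
  out$single_side <- FALSE
  cols <- c("FA", "MD", "L1", "RD")
  if (left$generated && right$generated) {
    out[cols] <- (left[cols] + right[cols]) / 2
    out$n_streamlines <- left$n_streamlines + right$n_streamlines
  } else if (left$generated || right$generated) {
    src <- if (left$generated) left else right
    out[cols] <- src[cols]
    out$n_streamlines <- src$n_streamlines
    out$generated <- TRUE
    out$single_side <- TRUE
  } else {
    out[cols] <- NA_real_
    out$n_streamlines <- 0L
    out$generated <- FALSE
  }
  out
}

RADAR_SCALE <- c(FA = 20, MD = 1e4, L1 = 1e4, RD = 1e4)

#' Scaled radar representation of tract metrics
#'
#' FA is presented x20, the diffusivities x10^4, so that all four metrics
#' share one readable radar axis range.
#'
#' @param metrics one-row `tract_metrics` data.frame with complete metrics.
#' @return object of class `dti_profile`: tract, tags, scaled values.
#' @export
radar_profile <- function(metrics) {
  if (!isTRUE(metrics$generated) || any(is.na(metrics[c("FA", "MD", "L1",
                                                        "RD")]))) {
    stop("radar profiles require complete tract metrics")
  }
  vals <- c(FA = metrics$FA, MD = metrics$MD, L1 = metrics$L1,
            RD = metrics$RD) * RADAR_SCALE
  structure(list(tract = metrics$tract, subject = metrics$subject,
                 method = metrics$method, scaled = vals),
            class = "dti_profile")
}

#' Recover raw metrics from a radar profile
#' @param profile a `dti_profile`.
#' @return named numeric vector FA, MD, L1, RD on their natural scales.
#' @export
descale_profile <- function(profile) {
  profile$scaled / RADAR_SCALE
}

#' Plot one or more radar profiles
#'
#' @param profiles list of `dti_profile`s (drawn on shared axes).
#' @param main plot title.
#' @param cols line colours (recycled).
#' @return invisibly, NULL. Uses base graphics.
#' @export
plot_radar <- function(profiles, main = "DTI profile",
                       cols = c("#1b6ca8", "#c0392b", "#27ae60",
                                "#8e44ad")) {
  if (inherits(profiles, "dti_profile")) profiles <- list(profiles)
  axes <- names(RADAR_SCALE)
  k <- length(axes)
  ang <- pi / 2 - (seq_len(k) - 1) * 2 * pi / k
  rmax <- max(vapply(profiles, function(p) max(p$scaled), numeric(1))) * 1.1
  graphics::plot(NA, xlim = c(-rmax, rmax), ylim = c(-rmax, rmax),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  for (frac in c(0.25, 0.5, 0.75, 1)) {
    graphics::polygon(rmax * frac * cos(ang), rmax * frac * sin(ang),
                      border = "grey80")
  }
  graphics::text(1.08 * rmax * cos(ang), 1.08 * rmax * sin(ang),
                 c("FA x20", "MD x1e4", "L1 x1e4", "RD x1e4"), cex = 0.8)
  for (i in seq_along(profiles)) {
    v <- profiles[[i]]$scaled
    graphics::polygon(v * cos(ang), v * sin(ang), border = cols[(i - 1) %%
                        length(cols) + 1], lwd = 2)
  }
  invisible(NULL)
}

#' Along-tract metric profile
#'
#' Resamples every streamline to `n_nodes` equidistant arc-length points,
#' standardizes orientation by flipping each streamline so its start end is
#' nearer the bundle's canonical start (the mean first endpoint after
#' orienting to the first streamline), and averages the sampled map per
#' node.
#'
#' @param streamlines a [tractogram()] with at least one streamline.
#' @param map a [scalar_map()].
#' @param n_nodes number of profile nodes (>= 2, default 50).
#' @return data.frame with `node`, `arc_fraction`, `mean`, `sd`, `n`.
#' @export
along_tract_profile <- function(streamlines, map, n_nodes = 50L) {
  stopifnot(n_nodes >= 2L)
  sls <- Filter(function(s) nrow(s) >= 2L, streamlines$streamlines)
  if (!length(sls)) stop("along-tract profile requires >= 1 streamline")
  res <- lapply(sls, resample_streamline, n_nodes = n_nodes)
  # canonical orientation: align every streamline's start to the start of
  # the first one (flip when its endpoints are closer the other way round)
  anchor <- res[[1]][1, ]
  res <- lapply(res, function(s) {
    if (sum((s[1, ] - anchor)^2) > sum((s[n_nodes, ] - anchor)^2)) {
      s[n_nodes:1, , drop = FALSE]
    } else s
  })
  vals <- vapply(res, function(s) sample_map(map, s),
                 numeric(n_nodes))
  vals <- matrix(vals, nrow = n_nodes)
  data.frame(node = seq_len(n_nodes),
             arc_fraction = (seq_len(n_nodes) - 1) / (n_nodes - 1),
             mean = rowMeans(vals, na.rm = TRUE),
             sd = apply(vals, 1, stats::sd, na.rm = TRUE),
             n = rowSums(!is.na(vals)))
}

#' Resample a streamline to equidistant arc-length points
#' @param points n x 3 matrix.
#' @param n_nodes number of output points.
#' @return n_nodes x 3 matrix.
#' @export
resample_streamline <- function(points, n_nodes) {
  seg <- sqrt(rowSums(diff(points)^2))
  s <- c(0, cumsum(seg))
  target <- seq(0, s[length(s)], length.out = n_nodes)
  cbind(stats::approx(s, points[, 1], xout = target)$y,
        stats::approx(s, points[, 2], xout = target)$y,
        stats::approx(s, points[, 3], xout = target)$y)
}

#' Evans' index from ventricle and inner-skull masks
#'
#' The ratio of the maximal width of the frontal horns of the lateral
#' ventricles to the maximal internal width of the cranial vault, measured
#' on axial (z) slices. The frontal-horn compartment is taken as the
#' ventricle voxels anterior to the AC plane (y > `ac_y` after ACPC
#' alignment). Widths are left-right (x) extents in world mm, maximized
#' over slices; each voxel contributes its full pitch.
#'
#' @param ventricle_mask [scalar_map()] (kind "mask") of the lateral
#'   ventricles, ACPC aligned.
#' @param inner_skull_mask [scalar_map()] of the inner cranial vault.
#' @param ac_y world y coordinate of the AC plane (default 0).
#' @return object of class `evans_index`: `horn_width_mm`,
#'   `cranial_width_mm`, `ei`, `horn_slice`, `cranial_slice`.
#' @export
evans_index <- function(ventricle_mask, inner_skull_mask, ac_y = 0) {
  if (!any(ventricle_mask$data != 0)) stop("ventricle mask is empty")
  if (!any(inner_skull_mask$data != 0)) stop("inner-skull mask is empty")
  horn <- mask_world_coords(ventricle_mask)
  horn <- horn[horn[, 2] > ac_y, , drop = FALSE]
  if (nrow(horn) == 0L) {
    stop("no ventricle voxels anterior to the AC plane; check alignment")
  }
  skull <- mask_world_coords(inner_skull_mask)
  pitch_x <- sqrt(sum(ventricle_mask$affine[1:3, 1]^2))
  hw <- max_slice_width(horn, pitch_x)
  cw <- max_slice_width(skull, sqrt(sum(inner_skull_mask$affine[1:3,
                                                                1]^2)))
  structure(list(horn_width_mm = hw$width, cranial_width_mm = cw$width,
                 ei = hw$width / cw$width,
                 horn_slice = hw$slice, cranial_slice = cw$slice),
            class = "evans_index")
}

#' @export
print.evans_index <- function(x, ...) {
  cat(sprintf(
    "Evans' index: %.4f (frontal horns %.1f mm / cranial vault %.1f mm)\n",
    x$ei, x$horn_width_mm, x$cranial_width_mm))
  invisible(x)
}

mask_world_coords <- function(map) {
  idx <- which(map$data != 0, arr.ind = TRUE) - 1L
  voxel_to_world(idx, map$affine)
}

# max over axial slices of the x-extent; voxels binned to slices by their
# world z rounded to the slice pitch
max_slice_width <- function(coords, pitch_x) {
  z <- round(coords[, 3], 6)
  widths <- tapply(coords[, 1], z, function(x) diff(range(x)) + pitch_x)
  i <- which.max(widths)
  list(width = as.numeric(widths[i]),
       slice = as.numeric(names(widths)[i]))
}
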