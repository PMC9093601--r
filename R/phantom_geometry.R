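# Parametric bundle centerlines for digital phantoms. Each centerline type
# reports, for a set of query points, the distance to the curve and the
# local unit tangent at the closest point, which is all the voxelizer needs.

#' Straight-segment centerline
#' @param from,to endpoints in world mm.
#' @export
centerline_segment <- function(from, to) {
  structure(list(type = "segment", from = from, to = to),
            class = "centerline")
}

#' Circular-arc centerline
#'
#' The arc lies in the plane spanned by orthonormal `u`, `v` about `center`:
#' p(theta) = center + R (cos(theta) u + sin(theta) v), theta in
#' `[theta0, theta1]` radians.
#'
#' @param center arc centre (mm).
#' @param radius arc radius (mm).
#' @param u,v orthonormal in-plane axes.
#' @param theta0,theta1 angular range (radians).
#' @export
centerline_arc <- function(center, radius, u, v, theta0, theta1) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  structure(list(type = "arc", center = center, radius = radius,
                 u = u, v = v, theta0 = theta0, theta1 = theta1),
            class = "centerline")
}

#' Polyline centerline
#' @param points n x 3 matrix of vertices (mm).
#' @export
centerline_polyline <- function(points) {
  structure(list(type = "polyline", points = rbind3(points)),
            class = "centerline")
}

# distance + tangent + arc-length parameter of closest point, vectorized
# over an n x 3 query matrix; returns list(dist, tangent (n x 3), s)
centerline_query <- function(cl, pts) {
  pts <- rbind3(pts)
  switch(cl$type,
    segment = {
      ab <- cl$to - cl$from
      L <- sqrt(sum(ab^2))
      dir <- ab / L
      rel <- sweep(pts, 2, cl$from)
      t <- pmin(pmax(rel %*% dir, 0), L)
      closest <- outer(as.vector(t), dir) + rep(cl$from, each = nrow(pts))
      d <- sqrt(rowSums((pts - closest)^2))
      list(dist = d,
           tangent = matrix(dir, nrow(pts), 3, byrow = TRUE),
           s = as.vector(t))
    },
    arc = {
      rel <- sweep(pts, 2, cl$center)
      a <- rel %*% cl$u
      b <- rel %*% cl$v
      th <- atan2(b, a)
      # wrap into the arc's angular window, then clamp to the endpoints
      th <- cl$theta0 + (th - cl$theta0) %% (2 * pi)
      th <- pmin(th, cl$theta1)
      closest <- rep(cl$center, each = nrow(pts)) +
        cl$radius * (outer(as.vector(cos(th)), cl$u) +
                     outer(as.vector(sin(th)), cl$v))
      d <- sqrt(rowSums((pts - closest)^2))
      tang <- -outer(as.vector(sin(th)), cl$u) +
               outer(as.vector(cos(th)), cl$v)
      list(dist = d, tangent = tang, s = as.vector(th - cl$theta0) * cl$radius)
    },
    polyline = {
      n <- nrow(pts)
      best_d <- rep(Inf, n)
      best_t <- matrix(0, n, 3)
      best_s <- rep(0, n)
      s_off <- 0
      for (i in seq_len(nrow(cl$points) - 1L)) {
        seg <- centerline_segment(cl$points[i, ], cl$points[i + 1L, ])
        q <- centerline_query(seg, pts)
        upd <- q$dist < best_d
        best_d[upd] <- q$dist[upd]
        best_t[upd, ] <- q$tangent[upd, , drop = FALSE]
        best_s[upd] <- s_off + q$s[upd]
        s_off <- s_off + sqrt(sum((cl$points[i + 1L, ] - cl$points[i, ])^2))
      }
      list(dist = best_d, tangent = best_t, s = best_s)
    },
    stop("unknown centerline type: ", cl$type))
}

# total arc length of a centerline
centerline_arclength <- function(cl) {
  switch(cl$type,
    segment = sqrt(sum((cl$to - cl$from)^2)),
    arc = cl$radius * (cl$theta1 - cl$theta0),
    polyline = sum(sqrt(rowSums(diff(cl$points)^2))))
}

#' White matter bundle specification for the digital phantom
#'
#' @param name tract label (e.g. "CC", "PLIC_left").
#' @param centerline a `centerline` object.
#' @param radius tube radius in mm (must exceed the voxel size).
#' @param eigenvalues length-3 diffusion eigenvalues (mm^2/s),
#'   l1 >= l2 >= l3 > 0; the principal axis follows the local tangent.
#' @param laterality "midline", "left" or "right".
#' @export
bundle_spec <- function(name, centerline, radius, eigenvalues,
                        laterality = c("midline", "left", "right")) {
  laterality <- match.arg(laterality)
  ev <- as.numeric(eigenvalues)
  if (length(ev) != 3L || any(diff(ev) > 0) || ev[3] <= 0) {
    stop("eigenvalues must satisfy l1 >= l2 >= l3 > 0")
  }
  structure(list(name = name, centerline = centerline, radius = radius,
                 eigenvalues = ev, laterality = laterality),
            class = "bundle_spec")
}
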