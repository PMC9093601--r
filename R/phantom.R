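# Digital DWI phantom: multi-bundle tensor fields with known eigenvalues,
# paired ellipsoidal ventricles inside an ellipsoidal inner-skull shell,
# Stejskal-Tanner signal generation, Rician noise, and per-subject rigid
# pose jitter. Everything downstream (tracking, gating, registration,
# Evans' index, statistics) is testable against the recorded ground truth.

# run expr with a temporary RNG state seeded from `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Phantom cohort specification
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 2.7 mm isotropic voxels, 41 diffusion directions at b = 1,000 s/mm^2
#' plus 5 b0 volumes, white-matter-like bundle eigenvalues, CSF-filled
#' ventricles and a gray-matter-like isotropic background.
#'
#' @param shape grid dimensions (voxels).
#' @param voxel_size isotropic voxel edge (mm).
#' @param bundles list of [bundle_spec()]s; `NULL` for the default set
#'   (an arching midline corpus-callosum-like bundle, vertical bilateral
#'   internal-capsule-like bundles beside the ventricles, and
#'   anterior-posterior bilateral fronto-occipital-like bundles).
#' @param ventricle_halfwidths ellipsoid semi-axes (a, b, c) in mm of each
#'   lateral ventricle.
#' @param ventricle_offset centre of the right ventricle (mm); the left is
#'   mirrored in x.
#' @param skull_halfwidths semi-axes of the inner-skull ellipsoid (mm).
#' @param gtab gradient table; default [default_gradient_table()].
#' @param noise_sigma Rician noise sigma as a fraction of S0.
#' @param pose_rot_deg,pose_trans_mm maximum rigid pose jitter (rotation in
#'   degrees, translation per axis in mm) applied per subject.
#' @param background_diffusivity isotropic diffusivity of non-bundle brain
#'   tissue (mm^2/s).
#' @param csf_diffusivity isotropic diffusivity inside the ventricles.
#' @param s0 non-weighted signal inside the skull (arbitrary units).
#' @param seed base seed for cohort generation.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(48L, 48L, 48L),
                         voxel_size = 2.7,
                         bundles = NULL,
                         ventricle_halfwidths = c(6, 18, 8),
                         ventricle_offset = c(9, 4, 6),
                         skull_halfwidths = c(55, 58, 48),
                         gtab = default_gradient_table(),
                         noise_sigma = 0,
                         pose_rot_deg = 0,
                         pose_trans_mm = 0,
                         background_diffusivity = 0.9e-3,
                         csf_diffusivity = 3.0e-3,
                         s0 = 1000,
                         seed = 1L) {
  if (is.null(bundles)) bundles <- default_bundles()
  stopifnot(noise_sigma >= 0, pose_rot_deg >= 0, pose_trans_mm >= 0)
  for (b in bundles) {
    if (b$radius <= voxel_size) {
      stop("bundle '", b$name, "' radius (", b$radius,
           " mm) must exceed the voxel size (", voxel_size, " mm)")
    }
  }
  affine <- diag(c(rep(voxel_size, 3), 1))
  affine[1:3, 4] <- -(shape - 1) / 2 * voxel_size
  spec <- structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                         affine = affine, bundles = bundles,
                         ventricle_halfwidths = ventricle_halfwidths,
                         ventricle_offset = ventricle_offset,
                         skull_halfwidths = skull_halfwidths,
                         gtab = gtab, noise_sigma = noise_sigma,
                         pose_rot_deg = pose_rot_deg,
                         pose_trans_mm = pose_trans_mm,
                         background_diffusivity = background_diffusivity,
                         csf_diffusivity = csf_diffusivity,
                         s0 = s0, seed = as.integer(seed)),
                    class = "phantom_spec")
  half <- (shape - 1) / 2 * voxel_size
  for (b in bundles) {
    ends <- bundle_extremes(b)
    if (any(abs(ends) + b$radius > rep(half, each = nrow(ends)))) {
      stop("bundle '", b$name, "' does not fit inside the grid")
    }
  }
  spec
}

bundle_extremes <- function(b) {
  cl <- b$centerline
  switch(cl$type,
    segment = rbind(cl$from, cl$to),
    arc = {
      th <- seq(cl$theta0, cl$theta1, length.out = 33)
      rep(cl$center, each = 33) +
        cl$radius * (outer(cos(th), cl$u) + outer(sin(th), cl$v))
    },
    polyline = cl$points)
}

#' Default phantom bundle set
#'
#' One midline arching bundle (corpus-callosum-like, genu anterior at +y),
#' one vertical bilateral bundle adjacent to the ventricles (internal-
#' capsule-like) and one anterior-posterior bilateral bundle (fronto-
#' occipital-like). Eigenvalues are typical white-matter values.
#'
#' @return list of [bundle_spec()]s.
#' @export
default_bundles <- function() {
  deg <- pi / 180
  list(
    bundle_spec("CC",
                centerline_arc(center = c(0, 0, 2), radius = 32,
                               u = c(0, 1, 0), v = c(0, 0, 1),
                               theta0 = -20 * deg, theta1 = 200 * deg),
                radius = 5, eigenvalues = c(1.7e-3, 0.3e-3, 0.3e-3),
                laterality = "midline"),
    bundle_spec("PLIC_left",
                centerline_segment(c(-16, -8, -24), c(-16, -8, 24)),
                radius = 5, eigenvalues = c(1.6e-3, 0.35e-3, 0.35e-3),
                laterality = "left"),
    bundle_spec("PLIC_right",
                centerline_segment(c(16, -8, -24), c(16, -8, 24)),
                radius = 5, eigenvalues = c(1.6e-3, 0.35e-3, 0.35e-3),
                laterality = "right"),
    bundle_spec("IFO_left",
                centerline_segment(c(-30, -42, -8), c(-30, 42, -8)),
                radius = 5, eigenvalues = c(1.5e-3, 0.4e-3, 0.4e-3),
                laterality = "left"),
    bundle_spec("IFO_right",
                centerline_segment(c(30, -42, -8), c(30, 42, -8)),
                radius = 5, eigenvalues = c(1.5e-3, 0.4e-3, 0.4e-3),
                laterality = "right"))
}

# template-space ACPC landmarks of every phantom
phantom_landmarks <- function() {
  list(AC = c(0, 0, 0), PC = c(0, -25, 0), MS = c(0, 5, 30))
}

ellipsoid_mask <- function(coords, center, halfwidths) {
  rel <- sweep(coords, 2, center)
  (rel[, 1] / halfwidths[1])^2 + (rel[, 2] / halfwidths[2])^2 +
    (rel[, 3] / halfwidths[3])^2 <= 1
}

#' Generate one phantom subject
#'
#' The subject's anatomy is the template anatomy moved by a rigid pose drawn
#' from the spec's jitter limits (tensor orientations rotate with it);
#' diffusion signals then follow the Stejskal-Tanner equation with optional
#' Rician noise \eqn{S' = \sqrt{(S+\epsilon_1)^2 + \epsilon_2^2}},
#' \eqn{\epsilon \sim N(0, \sigma S_0)}.
#'
#' @param spec a [phantom_spec()].
#' @param subject_seed integer seed for this subject's pose and noise.
#' @param eigen_shift optional named list: bundle name -> length-3 additive
#'   eigenvalue offset (mm^2/s), used to emulate cohort-level shifts.
#' @param ventricle_scale multiplier on the ventricle semi-axes (graded
#'   ventriculomegaly).
#' @return list with `dwi` (a [dwi_volume()]) and `truth` (tensor field,
#'   per-bundle masks, ventricle/horn/skull masks, reference structure
#'   masks, applied pose, subject-space landmarks, analytic per-bundle
#'   metrics, overlap mask).
#' @export
generate_subject <- function(spec, subject_seed, eigen_shift = NULL,
                             ventricle_scale = 1) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(subject_seed, {
    pose <- draw_pose(spec$pose_rot_deg, spec$pose_trans_mm)
    subj <- build_subject(spec, pose, eigen_shift, ventricle_scale)
    if (spec$noise_sigma > 0) {
      s <- subj$dwi$data
      sd <- spec$noise_sigma * spec$s0
      e1 <- array(stats::rnorm(length(s), 0, sd), dim(s))
      e2 <- array(stats::rnorm(length(s), 0, sd), dim(s))
      subj$dwi$data <- sqrt((s + e1)^2 + e2^2)
    }
    subj
  })
}

draw_pose <- function(rot_deg, trans_mm) {
  if (rot_deg == 0 && trans_mm == 0) return(diag(4))
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, rot_deg) * pi / 180
  tr <- stats::runif(3, -trans_mm, trans_mm)
  rigid_matrix(rotation_matrix(ax, ang), tr)
}

build_subject <- function(spec, pose, eigen_shift = NULL,
                          ventricle_scale = 1) {
  shape <- spec$shape
  nvox <- prod(shape)
  W <- grid_world_coords(shape, spec$affine)        # subject-space coords
  inv_pose <- solve(pose)
  Xt <- apply_transform(W, inv_pose)                # template-space coords
  R <- pose[1:3, 1:3]

  skull <- ellipsoid_mask(Xt, c(0, 0, 0), spec$skull_halfwidths)
  vh <- spec$ventricle_halfwidths * ventricle_scale
  vc <- spec$ventricle_offset
  vent <- ellipsoid_mask(Xt, vc, vh) |
          ellipsoid_mask(Xt, vc * c(-1, 1, 1), vh)
  vent <- vent & skull
  horns <- vent & Xt[, 2] > 0                        # anterior of the AC

  tensors <- matrix(0, nvox, 6)
  bg <- spec$background_diffusivity
  tensors[skull, c(1, 4, 6)] <- bg
  tensors[vent, c(1, 4, 6)] <- spec$csf_diffusivity

  bundle_masks <- list()
  claimed <- rep(FALSE, nvox)
  overlap <- rep(FALSE, nvox)
  analytic <- list()
  for (b in spec$bundles) {
    ev <- b$eigenvalues
    if (!is.null(eigen_shift) && !is.null(eigen_shift[[b$name]])) {
      ev <- ev + eigen_shift[[b$name]]
    }
    q <- centerline_query(b$centerline, Xt)
    inside <- q$dist <= b$radius & skull
    overlap <- overlap | (inside & claimed)
    claimed <- claimed | inside
    if (any(inside)) {
      tang <- q$tangent[inside, , drop = FALSE] %*% t(R)  # rotate with pose
      lr <- (ev[2] + ev[3]) / 2
      # radially-symmetric tensor: l_r I + (l1 - l_r) t t^T
      tensors[inside, ] <- cbind(lr + (ev[1] - lr) * tang[, 1]^2,
                                 (ev[1] - lr) * tang[, 1] * tang[, 2],
                                 (ev[1] - lr) * tang[, 1] * tang[, 3],
                                 lr + (ev[1] - lr) * tang[, 2]^2,
                                 (ev[1] - lr) * tang[, 2] * tang[, 3],
                                 lr + (ev[1] - lr) * tang[, 3]^2)
    }
    bundle_masks[[b$name]] <- array(inside, shape)
    met <- eigenvalue_metrics(matrix(c(ev[1], rep((ev[2] + ev[3]) / 2, 2)),
                                     1))
    analytic[[b$name]] <- list(eigenvalues = ev, fa = met$fa, md = met$md,
                               l1 = met$l1, rd = met$rd)
  }

  s0vec <- ifelse(skull, spec$s0, 0)
  sig <- predict_signal(tensors, s0vec, spec$gtab)
  dwi <- dwi_volume(array(sig, c(shape, length(spec$gtab$bvals))),
                    spec$affine, spec$gtab)

  lm <- phantom_landmarks()
  lm_subj <- lapply(lm, function(p) as.vector(apply_transform(p, pose)))

  field <- structure(list(tensors = array(tensors, c(shape, 6L)),
                          s0 = array(s0vec, shape),
                          mask = array(skull, shape),
                          affine = spec$affine, gtab = spec$gtab),
                     class = "tensor_field")

  truth <- list(tensor_field = field,
                bundle_masks = bundle_masks,
                ventricle_mask = array(vent, shape),
                horn_mask = array(horns, shape),
                skull_mask = array(skull, shape),
                overlap_mask = array(overlap, shape),
                pose = pose,
                landmarks = lm_subj,
                analytic = analytic,
                structures = reference_structures(spec, Xt, bundle_masks,
                                                  skull),
                affine = spec$affine,
                ventricle_scale = ventricle_scale)
  list(dwi = dwi, truth = truth)
}

# named landmark structure masks the recipe gates can cite; all are defined
# in template anatomy and therefore move with the subject's pose
reference_structures <- function(spec, Xt, bundle_masks, skull) {
  shape <- spec$shape
  plic <- as.vector(bundle_masks[["PLIC_left"]]) |
          as.vector(bundle_masks[["PLIC_right"]])
  occip <- skull & Xt[, 2] >= -48 & Xt[, 2] <= -28
  stem <- skull & Xt[, 3] < -34 & sqrt(Xt[, 1]^2 + Xt[, 2]^2) < 20
  out <- list(
    corpus_callosum = bundle_masks[["CC"]],
    corticospinal_tract = array(plic, shape),
    plic = array(plic, shape),
    occipital_lobe = array(occip, shape),
    brainstem = array(stem, shape))
  out
}

#' Generate a phantom cohort
#'
#' @param spec a [phantom_spec()].
#' @param n number of subjects (>= 2).
#' @param eigen_shift optional per-bundle eigenvalue offsets applied to all
#'   subjects (named list, see [generate_subject()]).
#' @param seed cohort seed; subject seeds are derived deterministically.
#' @param ventricle_scales optional length-n vector of per-subject ventricle
#'   scale factors.
#' @return list of subjects as returned by [generate_subject()].
#' @export
generate_cohort <- function(spec, n, eigen_shift = NULL, seed = spec$seed,
                            ventricle_scales = NULL) {
  stopifnot(n >= 2)
  if (is.null(ventricle_scales)) ventricle_scales <- rep(1, n)
  stopifnot(length(ventricle_scales) == n)
  lapply(seq_len(n), function(i) {
    sseed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    subj <- generate_subject(spec, sseed, eigen_shift = eigen_shift,
                             ventricle_scale = ventricle_scales[i])
    subj$id <- sprintf("subj%02d", i)
    subj
  })
}

#' Generate a ventriculomegaly-graded cohort with coupled bundle changes
#'
#' Subjects receive linearly increasing ventricle enlargement; the
#' internal-capsule-like bundles respond to the enlargement with raised
#' axial and lowered radial diffusivity (the diffusion signature of tracts
#' under stretch/compression), with the axial rise dominating so that mean
#' diffusivity also increases.
#'
#' @param spec a [phantom_spec()].
#' @param n number of subjects.
#' @param scale_range range of ventricle scale factors across the cohort.
#' @param l1_coupling increase of the bundle's first eigenvalue per unit of
#'   ventricle enlargement (mm^2/s).
#' @param rd_coupling decrease of the radial eigenvalues per unit of
#'   enlargement (mm^2/s).
#' @param seed cohort seed.
#' @return list of subjects; each carries its `ventricle_scale` in truth.
#' @export
generate_ei_cohort <- function(spec, n, scale_range = c(1, 1.6),
                               l1_coupling = 0.45e-3,
                               rd_coupling = 0.075e-3,
                               seed = spec$seed) {
  scales <- seq(scale_range[1], scale_range[2], length.out = n)
  lapply(seq_len(n), function(i) {
    g <- scales[i] - 1
    shift <- list(
      PLIC_left = c(l1_coupling * g, -rd_coupling * g, -rd_coupling * g),
      PLIC_right = c(l1_coupling * g, -rd_coupling * g, -rd_coupling * g))
    sseed <- (as.integer(seed) + 7919L * i) %% .Machine$integer.max
    subj <- generate_subject(spec, sseed, eigen_shift = shift,
                             ventricle_scale = scales[i])
    subj$id <- sprintf("subj%02d", i)
    subj
  })
}

#' Build a deliberately mismatched atlas from phantom truth
#'
#' Emulates a group-average atlas that does not quite fit an individual:
#' each true bundle mask is dilated and shifted so the atlas labels spill
#' into surrounding tissue and CSF, which lowers label-mean FA and raises
#' label-mean MD relative to a tract-faithful extraction.
#'
#' @param truth a subject truth list from [generate_subject()].
#' @param shift_mm translation applied to every label (length-3, mm).
#' @param dilate_voxels number of 6-neighbourhood dilation passes.
#' @param tracts character vector of bundle names to include (a partial
#'   atlas is allowed, mirroring atlases that cover only some tracts).
#' @return an `atlas_labels` object (see [atlas_labels()]).
#' @export
mismatched_atlas <- function(truth, shift_mm = c(0, 4, 4),
                             dilate_voxels = 2L,
                             tracts = names(truth$bundle_masks)) {
  shape <- dim(truth$skull_mask)
  labels <- array(0L, shape)
  tab <- data.frame(id = integer(), tract = character())
  vox_shift <- round(shift_mm / abs(diag(truth$affine)[1:3]))
  for (i in seq_along(tracts)) {
    m <- truth$bundle_masks[[tracts[i]]]
    for (k in seq_len(dilate_voxels)) m <- dilate6(m)
    m <- shift_mask(m, vox_shift)
    labels[m] <- i
    tab <- rbind(tab, data.frame(id = i, tract = tracts[i]))
  }
  atlas_labels(labels, truth$affine, tab)
}

# one pass of 6-connected binary dilation
dilate6 <- function(m) {
  d <- dim(m)
  out <- m
  out[-1, , ] <- out[-1, , ] | m[-d[1], , ]
  out[-d[1], , ] <- out[-d[1], , ] | m[-1, , ]
  out[, -1, ] <- out[, -1, ] | m[, -d[2], ]
  out[, -d[2], ] <- out[, -d[2], ] | m[, -1, ]
  out[, , -1] <- out[, , -1] | m[, , -d[3]]
  out[, , -d[3]] <- out[, , -d[3]] | m[, , -1]
  out
}

# integer-voxel shift, zero fill
shift_mask <- function(m, s) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(a) {
    i <- seq_len(d[a]) - s[a]
    i
  })
  ok <- lapply(1:3, function(a) src[[a]] >= 1 & src[[a]] <= d[a])
  dst <- lapply(1:3, function(a) seq_len(d[a])[ok[[a]]])
  srcc <- lapply(1:3, function(a) src[[a]][ok[[a]]])
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[srcc[[1]], srcc[[2]], srcc[[3]]]
  out
}
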