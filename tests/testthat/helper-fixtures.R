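# Shared fixtures, built once per test run and memoized. Everything is
# generated in code; nothing is read from disk except the shipped recipe
# file.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# noise-free default phantom subject (no jitter)
fixture_subject <- function() {
  memo("subject", function() {
    generate_subject(phantom_spec(), subject_seed = 11L)
  })
}

# scalar maps of the subject's true (noise-free) tensor field
fixture_maps <- function() {
  memo("maps", function() scalar_maps(fixture_subject()$truth$tensor_field))
}

# whole-brain tractogram of the noise-free subject at default parameters
fixture_tractogram <- function() {
  memo("tractogram", function() {
    s <- fixture_subject()
    track_whole_brain(s$truth$tensor_field, fixture_maps()$FA,
                      tracking_params())
  })
}

fixture_recipes <- function() {
  memo("recipes", function() load_recipes())
}

# independent closed-form FA/MD for eigenvalue triples (test oracle,
# written directly from the definitions, no package code)
oracle_fa <- function(l) {
  md <- mean(l)
  if (sum(l^2) == 0) return(0)
  sqrt(3 / 2) * sqrt(sum((l - md)^2)) / sqrt(sum(l^2))
}

# brute-force AND/NOT selection oracle over per-streamline membership sets
oracle_select <- function(streamlines, gates, affine) {
  vapply(streamlines, function(sl) {
    vox <- round(world_to_voxel(sl, affine))
    inside <- function(mask) {
      d <- dim(mask)
      ok <- vox[, 1] >= 0 & vox[, 1] <= d[1] - 1 &
            vox[, 2] >= 0 & vox[, 2] <= d[2] - 1 &
            vox[, 3] >= 0 & vox[, 3] <= d[3] - 1
      any(mask[cbind(vox[ok, 1] + 1, vox[ok, 2] + 1, vox[ok, 3] + 1)])
    }
    keep <- TRUE
    for (g in gates) {
      hit <- inside(g$mask)
      keep <- keep && if (g$polarity == "AND") hit else !hit
    }
    keep
  }, logical(1))
}

# apply the linear + translation part of a 4x4 matrix to one point
apply_mat <- function(m, p) as.vector(m[1:3, 1:3] %*% p + m[1:3, 4])

# 4x4 rigid matrix from axis, angle (deg) and translation
rigid_mat <- function(axis, deg, trans) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation_matrix(axis, deg * pi / 180)
  m[1:3, 4] <- trans
  m
}

# random small tractogram on a given grid for gating property tests
random_tractogram <- function(n, extent_mm, n_pts = 8L) {
  sls <- lapply(seq_len(n), function(i) {
    start <- stats::runif(3, -extent_mm, extent_mm)
    dir <- stats::rnorm(3)
    dir <- dir / sqrt(sum(dir^2))
    t(vapply(seq_len(n_pts), function(k)
      start + (k - 1) * 2 * dir, numeric(3)))
  })
  tractogram(sls)
}
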