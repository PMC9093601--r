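uniform_field <- function(shape, voxel, axis, evals = c(1.7e-3, 0.3e-3,
                                                        0.3e-3)) {
  af <- diag(c(rep(voxel, 3), 1))
  af[1:3, 4] <- -(shape - 1) / 2 * voxel
  axis <- axis / sqrt(sum(axis^2))
  lr <- mean(evals[2:3])
  t6 <- c(lr + (evals[1] - lr) * axis[1]^2,
          (evals[1] - lr) * axis[1] * axis[2],
          (evals[1] - lr) * axis[1] * axis[3],
          lr + (evals[1] - lr) * axis[2]^2,
          (evals[1] - lr) * axis[2] * axis[3],
          lr + (evals[1] - lr) * axis[3]^2)
  tens <- matrix(rep(t6, each = prod(shape)), ncol = 6)
  field <- structure(list(tensors = array(tens, c(shape, 6L)),
                          s0 = array(1000, shape),
                          mask = array(TRUE, shape), affine = af),
                     class = "tensor_field")
  fa <- oracle_fa(c(evals[1], lr, lr))
  list(field = field, fa = scalar_map(array(fa, shape), af, "FA"))
}

arc_field <- function(R_arc = 20, tube = 4) {
  shape <- c(40, 40, 10)
  af <- diag(c(1.5, 1.5, 1.5, 1))
  af[1:3, 4] <- c(-10, -10, -7)
  cl <- centerline_arc(c(0, 0, 0), R_arc, c(1, 0, 0), c(0, 1, 0),
                       0, pi / 2)
  W <- pseudotract:::grid_world_coords(shape, af)
  q <- pseudotract:::centerline_query(cl, W)
  # restrict to the angular window so the tube has no end caps and the
  # analytic mean length is exactly that of the centerline family
  ang <- atan2(W[, 2], W[, 1])
  inside <- q$dist <= tube & ang >= 0 & ang <= pi / 2
  lr <- 0.3e-3
  l1 <- 1.7e-3
  tg <- q$tangent
  tens <- matrix(0, prod(shape), 6)
  tens[inside, ] <- cbind(lr + (l1 - lr) * tg[inside, 1]^2,
                          (l1 - lr) * tg[inside, 1] * tg[inside, 2],
                          (l1 - lr) * tg[inside, 1] * tg[inside, 3],
                          lr + (l1 - lr) * tg[inside, 2]^2,
                          (l1 - lr) * tg[inside, 2] * tg[inside, 3],
                          lr + (l1 - lr) * tg[inside, 3]^2)
  field <- structure(list(tensors = array(tens, c(shape, 6L)),
                          s0 = array(1000, shape),
                          mask = array(TRUE, shape), affine = af),
                     class = "tensor_field")
  faarr <- array(0, shape)
  faarr[array(inside, shape)] <- oracle_fa(c(l1, lr, lr))
  list(field = field, fa = scalar_map(faarr, af, "FA"))
}

test_that("a uniform field yields straight equispaced streamlines", {
  u <- uniform_field(c(20, 20, 20), 2, c(1, 0, 0))
  p <- tracking_params(min_length = 5)
  tg <- track_whole_brain(u$field, u$fa, p)
  expect_gt(length(tg), 0)
  dev <- vapply(tg$streamlines, function(s)
    max(abs(sweep(s[, 2:3, drop = FALSE], 2, s[1, 2:3]))), numeric(1))
  expect_lt(max(dev), 1e-6)
  # consecutive point spacing equals the step within 10%
  sp <- unlist(lapply(tg$streamlines, function(s)
    sqrt(rowSums(diff(s)^2))))
  step <- tg$provenance$params$step_size
  expect_true(all(abs(sp - step) / step < 0.1))
})

test_that("quarter-arc bundle lengths match the analytic arc length", {
  a <- arc_field(R_arc = 20)
  tg <- track_whole_brain(a$field, a$fa,
                          tracking_params(step_size = 0.5, min_length = 5))
  lens <- vapply(tg$streamlines, streamline_length, numeric(1))
  expect_lt(abs(mean(lens) - pi * 20 / 2) / (pi * 20 / 2), 0.05)
})

test_that("every streamline satisfies the termination constraints", {
  s <- fixture_subject()
  tg <- fixture_tractogram()
  p <- tracking_params()
  fa <- fixture_maps()$FA
  step <- 0.5 * 2.7
  for (sl in tg$streamlines[seq(1, length(tg), by = 7)]) {
    expect_gte(streamline_length(sl), p$min_length)
    expect_lte(streamline_length(sl), p$max_length * 1.01)
    v <- sample_map(fa, sl)
    expect_true(all(v >= p$fa_threshold, na.rm = TRUE))
    if (nrow(sl) > 2) {
      d <- diff(sl)
      d <- d / sqrt(rowSums(d^2))
      cosang <- rowSums(d[-nrow(d), , drop = FALSE] *
                          d[-1, , drop = FALSE])
      expect_true(all(cosang >= cos(p$angle_threshold * pi / 180) - 1e-9))
    }
  }
})

test_that("an abrupt 90-degree interface is never crossed", {
  shape <- c(20, 20, 8)
  af <- diag(c(2, 2, 2, 1))
  af[1:3, 4] <- -(shape - 1)
  W <- pseudotract:::grid_world_coords(shape, af)
  lr <- 0.3e-3
  l1 <- 1.7e-3
  tens <- matrix(0, prod(shape), 6)
  left <- W[, 1] < 0
  tens[left, c(1, 4, 6)] <- rep(c(l1, lr, lr), each = sum(left))   # +x
  tens[!left, c(1, 4, 6)] <- rep(c(lr, l1, lr), each = sum(!left)) # +y
  field <- structure(list(tensors = array(tens, c(shape, 6L)),
                          s0 = array(1000, shape),
                          mask = array(TRUE, shape), affine = af),
                     class = "tensor_field")
  fa <- scalar_map(array(oracle_fa(c(l1, lr, lr)), shape), af, "FA")
  tg <- track_whole_brain(field, fa,
                          tracking_params(angle_threshold = 45,
                                          min_length = 4))
  for (sl in tg$streamlines) {
    d <- diff(sl)
    d <- d / sqrt(rowSums(d^2))
    if (nrow(d) > 1) {
      cosang <- rowSums(d[-nrow(d), , drop = FALSE] * d[-1, , drop = FALSE])
      expect_true(all(cosang >= cos(45 * pi / 180) - 1e-9))
    }
  }
})

test_that("seed order does not affect the streamline set", {
  u <- uniform_field(c(10, 10, 10), 2, c(0, 1, 0))
  p <- tracking_params(min_length = 5)
  tg1 <- track_whole_brain(u$field, u$fa, p)
  # restrict seeds via a mask traversed in a different memory order
  msk <- array(TRUE, c(10, 10, 10))
  tg2 <- track_whole_brain(u$field, u$fa, p, seed_mask = msk)
  key <- function(tg) sort(vapply(tg$streamlines, function(s)
    paste(round(s[1, ], 6), collapse = ","), character(1)))
  expect_identical(key(tg1), key(tg2))
})

test_that("halving the step changes phantom bundle lengths by < 2%", {
  a <- arc_field(R_arc = 20)
  l <- vapply(c(1.0, 0.5), function(st) {
    tg <- track_whole_brain(a$field, a$fa,
                            tracking_params(step_size = st, min_length = 5))
    mean(vapply(tg$streamlines, streamline_length, numeric(1)))
  }, numeric(1))
  expect_lt(abs(l[2] - l[1]) / l[1], 0.02)
})

test_that("degenerate inputs are handled per contract", {
  u <- uniform_field(c(8, 8, 8), 2, c(1, 0, 0))
  # empty seed mask: empty tractogram, not an error
  tg <- track_whole_brain(u$field, u$fa, tracking_params(),
                          seed_mask = array(FALSE, c(8, 8, 8)))
  expect_length(tg$streamlines, 0L)
  # NaN inside the tracking mask: hard error
  bad <- u$field
  bad$tensors[4, 4, 4, 2] <- NaN
  expect_error(track_whole_brain(bad, u$fa, tracking_params()),
               "non-finite")
})
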