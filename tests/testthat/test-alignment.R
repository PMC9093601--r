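test_that("ACPC alignment recovers landmark frames in closed form", {
  lm <- list(AC = c(0, 0, 0), PC = c(0, -25, 0), MS = c(0, 5, 30))
  t0 <- acpc_align(lm)
  expect_equal(t0$kind, "rigid")
  expect_lt(max(abs(t0$matrix - diag(4))), 1e-9)

  # landmarks rotated 10 degrees about z (plus a shift): the recovered
  # rotation block is the exact inverse rotation
  R <- rotation_matrix(c(0, 0, 1), 10 * pi / 180)
  lm2 <- lapply(lm, function(p) as.vector(R %*% p) + c(4, -7, 2))
  t2 <- acpc_align(lm2)
  expect_lt(rotation_angle_deg(t2$matrix[1:3, 1:3] %*% R), 1e-5)
  expect_lt(max(abs(apply_mat(t2$matrix, lm2$AC))), 1e-9)
  pc_al <- apply_mat(t2$matrix, lm2$PC)
  expect_lt(abs(pc_al[1]), 1e-9)
  expect_lt(abs(pc_al[3]), 1e-9)
  expect_lt(pc_al[2], 0)

  expect_error(acpc_align(list(AC = c(0, 0, 0), PC = c(0, -10, 0),
                               MS = c(0, -20, 0))), "collinear")
})

test_that("phantom pose jitter is recovered to within 0.1 degree", {
  spec <- phantom_spec(pose_rot_deg = 25, pose_trans_mm = 8)
  for (sd in c(5L, 17L)) {
    s <- generate_subject(spec, sd)
    tr <- acpc_align(s$truth$landmarks)
    resid <- tr$matrix %*% s$truth$pose
    expect_lt(rotation_angle_deg(resid[1:3, 1:3]), 0.1)
    expect_lt(max(abs(resid[1:3, 4])), 0.1)
  }
})

test_that("rigid transforms validate their rotation block", {
  bad <- diag(4)
  bad[1, 1] <- 2
  expect_error(spatial_transform(bad, "rigid"), "orthonormal")
  expect_silent(spatial_transform(bad, "affine"))
})

test_that("affine registration recovers identity and known motions", {
  s <- fixture_subject()
  fa <- fixture_maps()$FA
  regI <- register_affine(fa, fa)
  expect_lt(max(abs(regI$matrix - diag(4))), 1e-3)
  # cost trace (evaluated on the finest grid) never increases
  expect_true(all(diff(regI$provenance$cost_trace) <= 1e-12))

  tmat <- diag(4)
  tmat[1:3, 4] <- c(3, -2, 5)
  mov <- resample_map(fa, invert_transform(spatial_transform(tmat,
                                                             "rigid")))
  reg <- register_affine(mov, fa)
  expect_lt(max(abs(reg$matrix[1:3, 4] - c(3, -2, 5))), 0.5)
  expect_true(all(diff(reg$provenance$cost_trace) <= 1e-12))
})

test_that("affine registration recovers rotation and scale", {
  fa <- fixture_maps()$FA
  Rm <- diag(4)
  Rm[1:3, 1:3] <- rotation_matrix(c(0, 0, 1), 5 * pi / 180) * 1.05
  mov <- resample_map(fa, invert_transform(spatial_transform(Rm,
                                                             "affine")))
  reg <- register_affine(mov, fa)
  pol <- svd(reg$matrix[1:3, 1:3])
  rot <- pol$u %*% t(pol$v)
  expect_lt(rotation_angle_deg(t(rot) %*%
                                 rotation_matrix(c(0, 0, 1), 5 * pi / 180)),
            0.5)
  expect_lt(max(abs(pol$d - 1.05)), 0.01)
})

test_that("gate propagation respects identity, shifts and out-of-field", {
  s <- fixture_subject()
  ref <- phantom_reference(s$truth)
  rec <- fixture_recipes()
  gates <- resolve_gates(rec$PLIC, ref, side = "left")
  shape <- dim(s$truth$skull_mask)
  af <- s$truth$affine

  idg <- propagate_rois(gates, spatial_transform(diag(4), "rigid"),
                        shape, af)
  for (i in seq_along(gates)) {
    expect_identical(idg[[i]]$mask, gates[[i]]$mask)
    expect_identical(idg[[i]]$polarity, gates[[i]]$polarity)
  }

  # pure translation by one voxel pitch shifts masks by exactly one voxel
  tm <- diag(4)
  tm[1, 4] <- 2.7
  sh <- propagate_rois(gates, spatial_transform(tm, "rigid"), shape, af)
  m0 <- gates[[1]]$mask
  m1 <- sh[[1]]$mask
  expect_identical(m1[-1, , ], m0[-shape[1], , ])

  # transform pushing the gate fully outside: empty mask, flagged
  far <- diag(4)
  far[1:3, 4] <- c(500, 500, 500)
  out <- propagate_rois(gates, spatial_transform(far, "rigid"), shape, af)
  expect_true(out[[1]]$empty)
  expect_false(any(out[[1]]$mask))
})

test_that("composed propagation equals sequential propagation", {
  s <- fixture_subject()
  ref <- phantom_reference(s$truth)
  gates <- resolve_gates(fixture_recipes()$bCC, ref)
  shape <- dim(s$truth$skull_mask)
  af <- s$truth$affine
  t1 <- spatial_transform(rigid_mat(c(0, 0, 1), 4, c(2.7, 0, 0)), "rigid")
  t2 <- spatial_transform(rigid_mat(c(1, 0, 0), -3, c(0, -2.7, 2.7)),
                          "rigid")
  oneshot <- propagate_rois(gates, compose_transform(t2, t1), shape, af)
  twostep <- propagate_rois(propagate_rois(gates, t1, shape, af), t2,
                            shape, af)
  for (i in seq_along(gates)) {
    a <- oneshot[[i]]$mask
    b <- twostep[[i]]$mask
    # agreement up to one-voxel resampling error at the mask boundary
    boundary_tol <- 0.15 * sum(a | b)
    expect_lt(sum(xor(a, b)), boundary_tol)
  }
})

test_that("atlas-label extraction matches truth under the identity", {
  s <- fixture_subject()
  maps <- fixture_maps()
  truth <- s$truth
  # self-atlas: the true bundle masks as labels, identity transform
  labels <- array(0L, dim(truth$skull_mask))
  tab <- data.frame(id = seq_along(truth$bundle_masks),
                    tract = names(truth$bundle_masks))
  for (i in seq_len(nrow(tab))) {
    labels[truth$bundle_masks[[tab$tract[i]]]] <- i
  }
  atl <- atlas_labels(labels, truth$affine, tab)
  res <- extract_label_metrics(maps, atl)
  for (i in seq_len(nrow(tab))) {
    m <- truth$bundle_masks[[tab$tract[i]]] & labels == i
    expect_equal(res$FA[i], mean(maps$FA$data[labels == i]),
                 tolerance = 1e-12)
  }
  # a partial atlas yields exactly as many rows as it covers
  sub <- tab[1:3, ]
  lab2 <- labels
  lab2[!labels %in% sub$id] <- 0L
  res3 <- extract_label_metrics(maps, atlas_labels(lab2, truth$affine,
                                                   sub))
  expect_equal(nrow(res3), 3L)
  # a label mapped outside the subject grid is missing, not zero
  far <- diag(4)
  far[1:3, 4] <- 1000
  resf <- extract_label_metrics(maps, atl,
                                spatial_transform(far, "rigid"))
  expect_true(all(!resf$generated))
  expect_true(all(is.na(resf$FA)))
  # unknown label ids are rejected
  expect_error(atlas_labels(labels, truth$affine, tab[-1, ]), "absent")
})
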