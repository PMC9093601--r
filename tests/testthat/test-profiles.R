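const_maps <- function(fa = 0.5, md = 7e-4, shape = c(10, 10, 10),
                       voxel = 4) {
  af <- diag(c(rep(voxel, 3), 1))
  af[1:3, 4] <- -(shape - 1) / 2 * voxel
  list(FA = scalar_map(array(fa, shape), af, "FA"),
       MD = scalar_map(array(md, shape), af, "MD"),
       L1 = scalar_map(array(md * 2, shape), af, "L1"),
       RD = scalar_map(array(md / 2, shape), af, "RD"))
}

test_that("tract metrics average sampled map values over vertices", {
  maps <- const_maps(fa = 0.5)
  sl <- list(cbind(seq(-10, 10, by = 1), 0, 0),
             cbind(0, seq(-8, 8, by = 2), 3))
  tm <- tract_metrics(tractogram(sl), maps, tract = "PLIC")
  expect_true(tm$generated)
  expect_equal(tm$FA, 0.5, tolerance = 1e-12)
  expect_equal(tm$MD, 7e-4, tolerance = 1e-15)
  expect_equal(tm$n_streamlines, 2L)

  # map linear in x: mean equals the value at the vertex centroid
  shape <- c(11, 11, 11)
  af <- diag(c(2, 2, 2, 1))
  af[1:3, 4] <- -10
  W <- pseudotract:::grid_world_coords(shape, af)
  lin <- scalar_map(array(0.02 * W[, 1] + 0.5, shape), af, "FA")
  maps2 <- const_maps()
  maps2$FA <- lin
  sl2 <- list(cbind(seq(-8, 8, by = 0.5), 1, -1))
  tm2 <- tract_metrics(tractogram(sl2), maps2)
  centroid_x <- mean(sl2[[1]][, 1])
  expect_lt(abs(tm2$FA - (0.02 * centroid_x + 0.5)), 1e-6)

  # empty selection: missing, not zero
  tm0 <- tract_metrics(tractogram(list()), maps)
  expect_false(tm0$generated)
  expect_true(is.na(tm0$FA))

  # vertices outside the map are excluded and counted
  sl3 <- list(rbind(c(0, 0, 0), c(0, 0, 4), c(500, 0, 0)))
  tm3 <- tract_metrics(tractogram(sl3), maps)
  expect_equal(tm3$n_outside, 1L)
  expect_equal(tm3$FA, 0.5, tolerance = 1e-12)
})

test_that("bilateral averaging follows the single-side policy", {
  maps <- const_maps()
  mk <- function(fa, generated = TRUE) {
    r <- tract_metrics(
      if (generated) tractogram(list(cbind(0:5 * 2 - 5, 0, 0))) else
        tractogram(list()),
      maps, subject = "s1", tract = "UF")
    if (generated) r$FA <- fa
    r
  }
  l <- mk(0.4)
  r <- mk(0.6)
  avg <- bilateral_average(l, r)
  expect_equal(avg$FA, 0.5)
  expect_false(avg$single_side)

  one <- bilateral_average(mk(0.6), mk(NA, generated = FALSE))
  expect_equal(one$FA, 0.6)
  expect_true(one$single_side)

  none <- bilateral_average(mk(NA, FALSE), mk(NA, FALSE))
  expect_false(none$generated)
  expect_true(is.na(none$FA))

  bad <- mk(0.4)
  bad$tract <- "ILF"
  expect_error(bilateral_average(mk(0.4), bad), "different tracts")
})

test_that("radar scaling is the exact documented bijection", {
  maps <- const_maps(fa = 0.45, md = 7e-4)
  tm <- tract_metrics(tractogram(list(cbind(0:5 * 2 - 5, 0, 0))), maps,
                      tract = "gCC")
  pr <- radar_profile(tm)
  expect_equal(unname(pr$scaled["FA"]), 0.45 * 20, tolerance = 1e-12)
  expect_equal(unname(pr$scaled["FA"]), 9.0, tolerance = 1e-12)
  expect_equal(unname(pr$scaled["MD"]), 7.0, tolerance = 1e-12)
  back <- descale_profile(pr)
  expect_equal(unname(back["FA"]), tm$FA, tolerance = 1e-15)
  expect_equal(unname(back["MD"]), tm$MD, tolerance = 1e-18)
  expect_equal(unname(back["L1"]), tm$L1, tolerance = 1e-18)
  expect_equal(unname(back["RD"]), tm$RD, tolerance = 1e-18)

  tm$generated <- FALSE
  tm$FA <- NA_real_
  expect_error(radar_profile(tm), "complete")

  # plotting writes a figure file
  td <- withr::local_tempdir()
  grDevices::png(file.path(td, "radar.png"), width = 400, height = 400)
  pr2 <- radar_profile(tract_metrics(
    tractogram(list(cbind(0:5 * 2 - 5, 0, 0))), maps, tract = "gCC"))
  plot_radar(list(pr2))
  grDevices::dev.off()
  expect_true(file.exists(file.path(td, "radar.png")))
})

test_that("along-tract profiles resample by arc length", {
  maps <- const_maps(fa = 0.37)
  sl <- lapply(1:5, function(i) cbind(seq(-12, 12, by = 1.5), i - 3, 0))
  tg <- tractogram(sl)
  flat <- along_tract_profile(tg, maps$FA, n_nodes = 20)
  expect_equal(nrow(flat), 20L)
  expect_lt(max(abs(flat$mean - 0.37)), 1e-12)

  # linear map along a straight bundle: profile linear in node index
  shape <- c(15, 15, 15)
  af <- diag(c(2, 2, 2, 1))
  af[1:3, 4] <- -14
  W <- pseudotract:::grid_world_coords(shape, af)
  lin <- scalar_map(array(0.01 * W[, 1] + 0.5, shape), af, "FA")
  prof <- along_tract_profile(tg, lin, n_nodes = 25)
  fit <- lm(prof$mean ~ prof$node)
  rel_resid <- max(abs(residuals(fit))) / diff(range(prof$mean))
  expect_lt(rel_resid, 0.01)

  # two nodes: the endpoint means
  p2 <- along_tract_profile(tg, lin, n_nodes = 2)
  ends <- t(vapply(sl, function(s) c(s[1, 1], s[nrow(s), 1]), numeric(2)))
  expect_equal(p2$mean, 0.01 * colMeans(ends) + 0.5, tolerance = 1e-9)

  expect_error(along_tract_profile(tractogram(list()), maps$FA), ">= 1")
})

test_that("Evans' index equals the analytic width ratio of built masks", {
  shape <- c(61, 41, 21)
  af <- diag(4)
  af[1:3, 4] <- c(-30, -10, -10)
  W <- pseudotract:::grid_world_coords(shape, af)
  # frontal-horn block: width 38 mm in x (centres -18.5..18.5), anterior
  # voxel centres are at integer x; [-19, 18] spans 38 voxel centres of
  # 1 mm pitch, i.e. an analytic width of 38 mm
  horn <- W[, 1] >= -19 & W[, 1] <= 18.5 & W[, 2] >= 5 & W[, 2] <= 15 &
    abs(W[, 3]) <= 4
  # cranial interior: 60 voxel centres wide = 60 mm
  skull <- W[, 1] >= -30 & W[, 1] <= 29.5 & W[, 2] >= -5 & W[, 2] <= 25 &
    abs(W[, 3]) <= 8
  vent <- scalar_map(array(horn * 1, shape), af, "mask")
  sk <- scalar_map(array(skull * 1, shape), af, "mask")
  ei <- evans_index(vent, sk, ac_y = 0)
  expect_equal(ei$horn_width_mm, 38, tolerance = 1e-9)
  expect_equal(ei$cranial_width_mm, 60, tolerance = 1e-9)
  expect_equal(ei$ei, 38 / 60, tolerance = 1e-12)

  # ventricle mask equal to the skull mask: EI = 1 (degenerate bound)
  ei1 <- evans_index(sk, sk, ac_y = -6)
  expect_equal(ei1$ei, 1.0, tolerance = 1e-12)

  # isotropic scaling leaves the ratio unchanged
  af2 <- af
  af2[1:3, 1:3] <- af[1:3, 1:3] * 2
  af2[1:3, 4] <- af[1:3, 4] * 2
  ei2 <- evans_index(scalar_map(array(horn * 1, shape), af2, "mask"),
                     scalar_map(array(skull * 1, shape), af2, "mask"),
                     ac_y = 0)
  expect_equal(ei2$ei, ei$ei, tolerance = 1e-12)

  expect_error(evans_index(scalar_map(array(0, shape), af, "mask"), sk),
               "empty")
})

test_that("EI is stable under joint rigid motion plus re-alignment", {
  s <- fixture_subject()
  base <- subject_evans_index(s, acpc = FALSE)
  spec <- phantom_spec(pose_rot_deg = 20, pose_trans_mm = 6)
  sj <- generate_subject(spec, 13L)
  # same anatomy, jittered pose, ACPC re-aligned: each width can gain or
  # lose one voxel at each of its two faces, so widths agree to two
  # pitches and the ratio to the propagated bound
  realigned <- subject_evans_index(sj, acpc = TRUE)
  expect_lte(abs(realigned$horn_width_mm - base$horn_width_mm),
             2 * 2.7 + 1e-9)
  expect_lte(abs(realigned$cranial_width_mm - base$cranial_width_mm),
             2 * 2.7 + 1e-9)
  ei_bound <- 2 * 2.7 * (1 + base$ei) / base$cranial_width_mm
  expect_lte(abs(realigned$ei - base$ei), ei_bound)
})
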