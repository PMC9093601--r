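test_that("the shipped recipe file encodes the eight study tracts", {
  rec <- fixture_recipes()
  expect_length(rec, 8L)
  expect_setequal(names(rec), c("gCC", "bCC", "ATR", "IFO", "ILF", "PLIC",
                                "PTR", "UF"))
  gate_counts <- vapply(rec, function(r) length(r$gates), integer(1))
  expect_equal(gate_counts[c("gCC", "bCC", "ATR", "IFO", "ILF", "PLIC",
                             "PTR", "UF")],
               c(gCC = 2L, bCC = 2L, ATR = 4L, IFO = 3L, ILF = 4L,
                 PLIC = 3L, PTR = 4L, UF = 4L))
  # two midline + six bilateral recipes expand to 14 instances
  expect_equal(nrow(expand_instances(rec)), 14L)
  lat <- vapply(rec, `[[`, character(1), "laterality")
  expect_setequal(names(lat[lat == "midline"]), c("gCC", "bCC"))
  # the body recipe carries the axial exclusion just beneath it
  bcc_not <- Filter(function(g) g$polarity == "NOT", rec$bCC$gates)
  expect_length(bcc_not, 1L)
  expect_equal(bcc_not[[1]]$plane, "axial")
})

test_that("recipe validation rejects malformed recipes", {
  expect_error(tract_recipe("gCC", "midline", list(
    list(polarity = "NOT", plane = "sagittal",
         placement = list(type = "midline")))), "no AND gate")
  expect_error(tract_recipe("XYZ", "midline", list()), "unknown tract")
  expect_error(roi_gate("AND", "parasagittal",
                        list(type = "lateral_of", structure = "s")),
               "side")
  td <- withr::local_tempdir()
  writeLines("- tract: gCC\n  gates:\n    - polarity: AND",
             file.path(td, "bad.yaml"))
  expect_error(load_recipes(file.path(td, "bad.yaml")), "laterality")
})

test_that("fractional placements resolve by anterior-posterior arithmetic", {
  # structure spanning y in [0, 60] mm on a 1 mm grid
  shape <- c(21L, 81L, 11L)
  af <- diag(4)
  af[2, 4] <- -10
  af[1, 4] <- -10
  struct <- array(FALSE, shape)
  W <- pseudotract:::grid_world_coords(shape, af)
  struct[array(abs(W[, 1]) <= 3 & W[, 2] >= 0 & W[, 2] <= 60 &
                 W[, 3] <= 4, shape)] <- TRUE
  ref <- reference_geometry(shape, af, list(cc = struct))
  rec <- tract_recipe("gCC", "midline", list(
    list(polarity = "AND", plane = "sagittal",
         placement = list(type = "fraction", structure = "cc",
                          edge = "anterior", from = 0, to = 1 / 6),
         extent = "entire")))
  g <- resolve_gates(rec, ref)[[1]]
  ys <- W[as.vector(g$mask), 2]
  # anterior 1/6 of the padded extent [-0.5, 60.5]: y in [50.33, 60.5]
  expect_gte(min(ys), 60.5 - 61 / 6 - 0.51)
  expect_lte(max(ys), 60.5)
  expect_gt(length(ys), 0)

  # posterior 1/4 complement slab
  rec2 <- tract_recipe("bCC", "midline", list(
    list(polarity = "AND", plane = "sagittal",
         placement = list(type = "fraction", structure = "cc",
                          edge = "posterior", from = 0, to = 1 / 4),
         extent = "entire")))
  ys2 <- W[as.vector(resolve_gates(rec2, ref)[[1]]$mask), 2]
  expect_lte(max(ys2), -0.5 + 61 / 4 + 0.51)

  # entire central sagittal slice
  rec3 <- tract_recipe("gCC", "midline", list(
    list(polarity = "AND", plane = "sagittal",
         placement = list(type = "midline"), extent = "entire")))
  m3 <- resolve_gates(rec3, ref)[[1]]$mask
  xs <- W[as.vector(m3), 1]
  expect_true(all(abs(xs) <= 1.5 + 1e-9))
  expect_equal(sort(unique(W[as.vector(m3), 3])), sort(unique(W[, 3])))

  # a rule citing an unknown structure errors with its name
  rec4 <- tract_recipe("gCC", "midline", list(
    list(polarity = "AND", plane = "coronal",
         placement = list(type = "slice", structure = "pons",
                          edge = "anterior"), extent = "entire")))
  expect_error(resolve_gates(rec4, ref), "pons")
})

test_that("AND/NOT selection equals brute-force set logic", {
  set.seed(31)
  shape <- c(20L, 20L, 20L)
  af <- diag(c(3, 3, 3, 1))
  af[1:3, 4] <- -28.5
  n_agree <- 0L
  n_total <- 0L
  for (rep in 1:12) {
    tg <- random_tractogram(60, 28)
    gates <- lapply(seq_len(3), function(i) {
      m <- array(runif(prod(shape)) < 0.12, shape)
      list(polarity = sample(c("AND", "NOT"), 1), mask = m)
    })
    got <- select_tract(tg, gates, af)$kept
    want <- oracle_select(tg$streamlines, gates, af)
    n_agree <- n_agree + sum(got == want)
    n_total <- n_total + length(want)
    expect_identical(got, want)
  }
  expect_equal(n_agree, n_total)
})

test_that("adding gates never increases the kept count", {
  set.seed(17)
  shape <- c(16L, 16L, 16L)
  af <- diag(c(3, 3, 3, 1))
  af[1:3, 4] <- -22.5
  tg <- random_tractogram(80, 22)
  base_gate <- list(polarity = "AND",
                    mask = array(runif(prod(shape)) < 0.5, shape))
  kept0 <- sum(select_tract(tg, list(base_gate), af)$kept)
  for (i in 1:10) {
    extra_and <- list(polarity = "AND",
                      mask = array(runif(prod(shape)) < 0.3, shape))
    extra_not <- list(polarity = "NOT",
                      mask = array(runif(prod(shape)) < 0.3, shape))
    expect_lte(sum(select_tract(tg, list(base_gate, extra_and),
                                af)$kept), kept0)
    expect_lte(sum(select_tract(tg, list(base_gate, extra_not),
                                af)$kept), kept0)
  }
})

test_that("degenerate gates behave as annihilator and identity", {
  shape <- c(10L, 10L, 10L)
  af <- diag(c(4, 4, 4, 1))
  af[1:3, 4] <- -18
  tg <- random_tractogram(25, 16)
  all_mask <- array(TRUE, shape)
  none <- select_tract(tg, list(list(polarity = "NOT", mask = all_mask)),
                       af)
  expect_false(none$generated)
  expect_length(none$streamlines$streamlines, 0L)
  all_sel <- select_tract(tg, list(list(polarity = "AND",
                                        mask = all_mask)), af)
  expect_true(all_sel$generated)
  expect_length(all_sel$streamlines$streamlines, length(tg))
  # AND mask containing exactly one streamline's midpoint
  mid <- tg$streamlines[[5]][4, ]
  vox <- round(world_to_voxel(mid, af))
  if (all(vox >= 0) && all(vox <= 9)) {
    m <- array(FALSE, shape)
    m[vox[1] + 1, vox[2] + 1, vox[3] + 1] <- TRUE
    sel <- select_tract(tg, list(list(polarity = "AND", mask = m)), af)
    expect_true(sel$kept[5])
    expect_identical(sel$kept,
                     oracle_select(tg$streamlines,
                                   list(list(polarity = "AND", mask = m)),
                                   af))
  }
})

test_that("recipes isolate their phantom bundles with high fidelity", {
  s <- fixture_subject()
  ref <- phantom_reference(s$truth)
  tg <- fixture_tractogram()
  rec <- fixture_recipes()
  af <- s$truth$affine
  seedpt <- tg$provenance$seed_points
  seed_in <- function(mask) {
    v <- round(world_to_voxel(seedpt, af))
    mask[cbind(v[, 1] + 1, v[, 2] + 1, v[, 3] + 1)]
  }
  plic_l <- select_tract(tg, resolve_gates(rec$PLIC, ref, side = "left"),
                         af)$kept
  plic_r <- select_tract(tg, resolve_gates(rec$PLIC, ref, side = "right"),
                         af)$kept
  gcc <- select_tract(tg, resolve_gates(rec$gCC, ref), af)$kept
  bcc <- select_tract(tg, resolve_gates(rec$bCC, ref), af)$kept
  in_pl <- seed_in(s$truth$bundle_masks$PLIC_left)
  in_pr <- seed_in(s$truth$bundle_masks$PLIC_right)
  in_cc <- seed_in(s$truth$bundle_masks$CC)
  # capture of the true bundles
  expect_gte(mean(plic_l[in_pl]), 0.95)
  expect_gte(mean(plic_r[in_pr]), 0.95)
  expect_gte(mean((gcc | bcc)[in_cc]), 0.95)
  # zero capture from disjoint decoy bundles
  decoys <- c("IFO_left", "IFO_right")
  for (d in decoys) {
    in_d <- seed_in(s$truth$bundle_masks[[d]])
    expect_equal(sum(plic_l[in_d]) + sum(plic_r[in_d]) +
                   sum(gcc[in_d]) + sum(bcc[in_d]), 0L)
  }
  expect_equal(sum(plic_l[in_cc]) + sum(plic_r[in_cc]), 0L)
  expect_equal(sum(gcc[in_pl | in_pr]) + sum(bcc[in_pl | in_pr]), 0L)
})
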