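codes <- label_codes()

test_that("largest_foreground keeps the biggest component with a deterministic tie-break", {
  lab <- array(0L, c(12, 12, 3))
  lab[3:8, 3:8, 1:3] <- codes["FAT"]          # 108-voxel blob
  lv <- label_volume(lab, c(1, 1, 1))
  expect_identical(largest_foreground(lv)$labels, lab)

  lab2 <- lab
  lab2[11, 11, 1] <- codes["DENSE"]           # 1-voxel satellite
  out <- largest_foreground(label_volume(lab2, c(1, 1, 1)))
  expect_identical(out$labels, lab)           # satellite removed
  # oracle: component sizes by direct counting
  comp <- mammoskin:::connected_components(lab2 != 0, 26L)
  expect_equal(sort(tabulate(comp[comp > 0])), c(1L, 108L))

  # two equal blobs: the one containing the smallest linear index survives
  lab3 <- array(0L, c(12, 12, 1))
  lab3[2:3, 2:3, 1] <- codes["FAT"]
  lab3[8:9, 8:9, 1] <- codes["FAT"]
  out3 <- largest_foreground(label_volume(lab3, c(1, 1, 1)))
  expect_true(all(out3$labels[2:3, 2:3, 1] == codes["FAT"]))
  expect_true(all(out3$labels[8:9, 8:9, 1] == 0L))

  expect_error(largest_foreground(label_volume(array(0L, c(8, 8, 1)), c(1, 1, 1))),
               "foreground")
})

test_that("open_close smooths borders like the erosion/dilation composition", {
  lab <- array(0L, c(16, 16, 1))
  lab[4:12, 4:12, 1] <- codes["FAT"]
  lv <- label_volume(lab, c(1, 1, 1))
  expect_identical(open_close(lv)$labels, lab)     # large solid block unchanged

  iso <- array(0L, c(16, 16, 1)); iso[8, 8, 1] <- codes["FAT"]
  expect_true(all(open_close(label_volume(iso, c(1, 1, 1)))$labels == 0L))

  notch <- lab
  notch[8, 4, 1] <- 0L                              # one-voxel border notch
  out <- open_close(label_volume(notch, c(1, 1, 1)))
  # oracle: dilate(erode(.)) then erode(dilate(.)) with plain 3x3 shifts
  fg <- notch[, , 1] != 0
  ref <- erode3_ref(dilate3_ref(dilate3_ref(erode3_ref(fg))))
  expect_identical(out$labels[, , 1] != 0, ref)
  expect_equal(out$labels[8, 4, 1], codes[["FAT"]])   # notch filled, labelled
})

test_that("the boundary march labels the skin shell and respects truth geometry", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 13))
  sb <- split_breasts(ph$volume)
  tr <- roi_truth(ph$truth, sb$left)
  # candidates straight from truth: skin and dense are dark candidates
  lab <- tr
  lab[tr == codes["SKIN"]] <- codes["DENSE"]
  lv <- label_volume(lab, ph$truth$spacing)
  out <- separate_skin_dense(sb$left$volume, lv)
  skin_t <- tr == codes["SKIN"]
  skin_p <- out$labels == codes["SKIN"]
  dice <- 2 * sum(skin_p & skin_t) / (sum(skin_p) + sum(skin_t))
  expect_gt(dice, 0.95)
  # interior dense blobs (not touching skin) stay dense
  expect_true(all(out$labels[tr == codes["DENSE"]] == codes["DENSE"]))
})

test_that("the nipple-band depth limit caps the skin march at 3 mm", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 14, dense_at_nipple = TRUE,
                                               dense_fraction = 0))
  sb <- split_breasts(ph$volume)
  tr <- roi_truth(ph$truth, sb$left)
  lab <- tr
  lab[tr == codes["SKIN"]] <- codes["DENSE"]
  lv <- label_volume(lab, ph$truth$spacing)
  # global-limit mode makes the cap exact everywhere: 3 mm at 1 mm in-plane
  # spacing is 3 voxel steps, so no skin sits deeper than 3 and the fused
  # blob's deeper voxels stay dense
  params <- skin_params(global_depth_limit = TRUE)
  out <- separate_skin_dense(sb$left$volume, lv, params)
  d <- dim(out$labels)
  deep_skin <- 0L; blob_dense <- 0L
  for (s in seq_len(d[3])) {
    sl <- out$labels[, , s]
    fg <- sl != 0L
    if (!any(fg)) next
    depth <- mammoskin:::slice_depth(fg, out$spacing)
    deep_skin <- deep_skin + sum(sl == codes["SKIN"] & depth > 3 + 1e-9)
    blob_dense <- blob_dense + sum(sl == codes[["DENSE"]])
  }
  expect_equal(deep_skin, 0L)   # no skin beyond the cap
  expect_gt(blob_dense, 0L)     # the blob's deep part stays dense

  # in the default mode the limit binds only in the nipple band; elsewhere
  # the march runs to the first fat voxel, so it can only label more skin
  out2 <- separate_skin_dense(sb$left$volume, lv, skin_params())
  expect_gte(sum(out2$labels == codes["SKIN"]), sum(out$labels == codes["SKIN"]))
  # and within the nipple band no skin sits beyond the cap either
  for (s in seq_len(d[3])) {
    sl <- out2$labels[, , s]
    fg <- sl != 0L
    if (!any(fg)) next
    depth <- mammoskin:::slice_depth(fg, out2$spacing)
    rows_fg <- range(which(rowSums(fg) > 0))
    band <- seq_len(d[1]) <= rows_fg[1] + params$nipple_band_fraction * diff(rows_fg)
    in_band <- matrix(rep(band, d[2]), d[1], d[2])
    expect_equal(sum(sl == codes["SKIN"] & in_band & depth > 3 + 1e-9), 0L)
  }
})

test_that("a breast with no dark boundary candidates yields no skin, with a warning", {
  lab <- array(0L, c(16, 16, 2))
  lab[5:12, 5:12, ] <- codes["FAT"]
  lv <- label_volume(lab, c(1, 1, 2))
  v <- gray_volume(array(100, c(16, 16, 2)), c(1, 1, 2))
  expect_warning(out <- separate_skin_dense(v, lv), "no SKIN")
  expect_false(any(out$labels == codes["SKIN"]))
  empty <- label_volume(array(0L, c(16, 16, 2)), c(1, 1, 2))
  expect_error(separate_skin_dense(v, empty), "foreground")
})

test_that("absorb_isolated_dense moves only single dense pixels touching skin", {
  lab <- array(0L, c(12, 12, 1))
  lab[4:9, 4, 1] <- codes["SKIN"]
  lab[6, 5, 1] <- codes["DENSE"]                   # lone pixel 4-adjacent to skin
  lab[2, 10, 1] <- codes["DENSE"]                  # lone pixel, far from skin
  lab[9:10, 8, 1] <- codes["DENSE"]                # 2-voxel component near skin
  lab[9, 7, 1] <- codes["SKIN"]
  lv <- label_volume(lab, c(1, 1, 1))
  out <- absorb_isolated_dense(lv)
  expect_equal(out$labels[6, 5, 1], codes[["SKIN"]])
  expect_equal(out$labels[2, 10, 1], codes[["DENSE"]])
  expect_true(all(out$labels[9:10, 8, 1] == codes["DENSE"]))
  # rule replay: every other voxel untouched
  changed <- which(out$labels != lab)
  expect_equal(changed, which(seq_along(lab) == (5 - 1) * 12 + 6))
})

test_that("interior smoothness removes one-voxel filaments and is idempotent at fixpoint", {
  # 11x11 fixture worked by hand: a closed one-voxel skin ring (each ring
  # voxel has two skin neighbours, so it survives) with a one-voxel skin
  # filament protruding into the fat interior
  sl <- matrix(codes[["BACKGROUND"]], 11, 11)
  sl[3:9, 3:9] <- codes[["FAT"]]
  ring <- matrix(FALSE, 11, 11)
  ring[3:9, c(3, 9)] <- TRUE; ring[c(3, 9), 3:9] <- TRUE
  sl[ring] <- codes[["SKIN"]]
  sl[6, 4:6] <- codes[["SKIN"]]                    # filament off the ring
  lab <- array(sl, c(11, 11, 1))
  out <- interior_smoothness(label_volume(lab, c(1, 1, 1)))
  # by-hand iteration: the filament erodes from its tip one voxel per pass
  # ((6,6): 3 of 4 neighbours fat -> fat; then (6,5); then (6,4)); the ring
  # is untouched throughout
  expect_true(all(out$labels[, , 1][ring] == codes[["SKIN"]]))
  expect_true(all(out$labels[6, 4:6, 1] == codes[["FAT"]]))
  again <- interior_smoothness(out)
  expect_identical(again$labels, out$labels)

  # a solid 2-voxel-thick shell is untouched
  shell <- matrix(0L, 10, 10)
  shell[3:8, 3:8] <- codes["FAT"]
  shell[3:8, 3:4] <- codes["SKIN"]
  lab2 <- array(shell, c(10, 10, 1))
  out2 <- interior_smoothness(label_volume(lab2, c(1, 1, 1)))
  expect_identical(out2$labels, lab2)

  # a one-voxel dense spur on the ring is removed (to the majority class)
  sp <- sl
  sp[6, 4:6] <- codes[["FAT"]]                     # drop the filament
  sp[6, 4] <- codes[["DENSE"]]                     # spur touching the ring
  out3 <- interior_smoothness(label_volume(array(sp, c(11, 11, 1)), c(1, 1, 1)))
  expect_equal(out3$labels[6, 4, 1], codes[["FAT"]])  # 3 fat vs 1 skin neighbour
})

test_that("close_skin_3d seals exposed tissue and only exposed tissue", {
  # closed box: skin shell around fat, already sealed -> unchanged
  lab <- array(0L, c(10, 10, 5))
  lab[3:8, 3:8, 2:4] <- codes["SKIN"]
  lab[4:7, 4:7, 3] <- codes["FAT"]
  lv <- label_volume(lab, c(1, 1, 1))
  out <- close_skin_3d(lv)
  expect_identical(out$labels, lab)

  # one-voxel hole: exactly the fat voxel behind it converts
  hole <- lab
  hole[4, 3, 3] <- 0L                              # open the shell
  before <- exposed_tissue_count(label_volume(hole, c(1, 1, 1)), 6L)
  expect_equal(before, 1L)                         # adjacency-count oracle
  outh <- close_skin_3d(label_volume(hole, c(1, 1, 1)))
  expect_equal(exposed_tissue_count(outh, 6L), 0L)
  expect_equal(outh$labels[4, 4, 3], codes[["SKIN"]])
  expect_equal(sum(outh$labels != hole), 1L)

  # skin deleted on a whole slice: closure reseals the 3D surface
  ph <- make_breast_phantom(small_phantom_spec(seed = 10, interslice_gap = 12L))
  res <- run_pipeline(ph$volume, pipeline_config(seed = 10))
  for (roi in res$rois)
    expect_equal(exposed_tissue_count(roi$labels, 6L), 0L)
})

test_that("skin-growing stages never shrink the skin", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 15))
  sb <- split_breasts(ph$volume)
  v0 <- sb$left$volume
  lab <- recluster_mixed(v0, partition_4(low_threshold(curvature_flow(v0), 6),
                                         seed = 1), seed = 2)
  lab <- open_close(largest_foreground(lab))
  lab <- separate_skin_dense(v0, lab)
  n1 <- sum(lab$labels == codes[["SKIN"]])
  lab2 <- absorb_isolated_dense(lab)
  expect_gte(sum(lab2$labels == codes["SKIN"]), n1)
  lab3 <- interior_smoothness(lab2)
  n3 <- sum(lab3$labels == codes[["SKIN"]])
  lab4 <- close_skin_3d(lab3)
  expect_gte(sum(lab4$labels == codes["SKIN"]), n3)
})

test_that("the fixed-thickness baseline labels a uniform shell", {
  lab <- array(0L, c(20, 20, 1))
  lab[3:18, 3:18, 1] <- codes["FAT"]
  out <- fixed_thickness_skin(label_volume(lab, c(1, 1, 1)), 3)
  depth <- mammoskin:::slice_depth(lab[, , 1] != 0, c(1, 1, 1))
  expect_true(all((out$labels[, , 1] == codes["SKIN"]) ==
                    (lab[, , 1] != 0 & depth <= 3 + 1e-9)))
})
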