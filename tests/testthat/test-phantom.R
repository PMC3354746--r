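test_that("phantoms are deterministic in the seed and validate their spec", {
  a <- make_breast_phantom(small_phantom_spec(seed = 3))
  b <- make_breast_phantom(small_phantom_spec(seed = 3))
  c <- make_breast_phantom(small_phantom_spec(seed = 4))
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$labels, b$truth$labels)
  expect_false(identical(a$volume$data, c$volume$data))

  expect_error(phantom_spec(intensity_means = list(fat = 50, dense = 60,
                                                   skin = 55, background = 2,
                                                   axial = 90)),
               "contrast")
  expect_error(phantom_spec(skin_thickness_mm = 0.4), "thickness")
  expect_error(phantom_spec(dense_fraction = 1.5), "dense_fraction")
  # breasts must fit inside the volume
  expect_error(make_breast_phantom(small_phantom_spec(breast_radius_mm = 60)),
               "border")
})

test_that("a noiseless dense-free phantom has pure fat inside and 4 intensity levels", {
  ph <- make_breast_phantom(small_phantom_spec(noise_sigma = 0, hetero_sigma = 0,
                                               dense_fraction = 0))
  codes <- label_codes()
  expect_false(any(ph$truth$labels == codes["DENSE"]))
  inside <- ph$truth$labels %in% codes[c("FAT", "DENSE")]
  expect_true(all(ph$truth$labels[inside] == codes["FAT"]))
  expect_equal(length(unique(as.vector(ph$volume$data))), 4L)
})

test_that("the truth skin shell has the specified in-plane thickness", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 1))  # 2 mm skin, 1 mm in-plane
  codes <- label_codes()
  s <- 12  # central slice
  tr <- ph$truth$labels[, , s]
  # the chest band counts as tissue here: skin thickness is measured from
  # true exterior air, not from the breast/chest attachment
  fg <- tr != codes["BACKGROUND"] | ph$meta$axial[, , s]
  # oracle: 2D distance transform from the true background
  dmm <- mammoskin:::distance_to_background(fg, c(1, 1))
  skin <- tr == codes["SKIN"]
  expect_true(all(dmm[skin] <= 2 + 1e-9))
  interior <- tr %in% codes[c("FAT", "DENSE")]
  expect_true(all(dmm[interior] > 2))
  # marching inward from the anterior pole crosses exactly 2 skin voxels
  ctr <- round(ph$meta$centers[[1]])
  run <- rle(tr[, ctr[2]])
  expect_equal(run$lengths[run$values == codes["SKIN"]][1], 2L)
})

test_that("truth labels partition the volume and skin seals the interior", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 8))
  codes <- label_codes()
  expect_true(all(ph$truth$labels %in% codes[c("BACKGROUND", "SKIN", "FAT", "DENSE")]))
  # no internal tissue voxel touches true exterior (background minus chest)
  lab <- ph$truth$labels
  lab[ph$meta$axial] <- codes["SKIN"]  # chest band is not exterior
  sealed <- label_volume(lab, ph$truth$spacing)
  expect_equal(exposed_tissue_count(sealed, 6L), 0L)

  # gap mode deliberately exposes tissue on the gap slice
  phg <- make_breast_phantom(small_phantom_spec(seed = 8, interslice_gap = 12L))
  labg <- phg$truth$labels
  expect_false(any(labg[, , 12] == codes["SKIN"]))
  labg[phg$meta$axial] <- codes["SKIN"]
  expect_gt(exposed_tissue_count(label_volume(labg, phg$truth$spacing), 6L), 0L)
})

test_that("the generated dense fraction tracks the requested fraction", {
  for (f in c(0.1, 0.3)) {
    ph <- make_breast_phantom(small_phantom_spec(seed = 5, dense_fraction = f))
    codes <- label_codes()
    nd <- sum(ph$truth$labels == codes["DENSE"])
    ni <- sum(ph$truth$labels %in% codes[c("FAT", "DENSE")])
    expect_lt(abs(nd / ni - f), 0.02)
  }
})

test_that("evaluate_segmentation matches direct set counting", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 2))
  ev <- evaluate_segmentation(ph$truth, ph$truth)
  expect_true(all(ev$dice == 1))
  expect_true(all(ev$precision == 1) && all(ev$recall == 1))

  codes <- label_codes()
  # swap SKIN and FAT codes and check dice(SKIN) against direct counting
  sw <- ph$truth$labels
  sw[ph$truth$labels == codes["SKIN"]] <- codes["FAT"]
  sw[ph$truth$labels == codes["FAT"]] <- codes["SKIN"]
  pred <- label_volume(sw, ph$truth$spacing)
  ev2 <- evaluate_segmentation(pred, ph$truth)
  nS <- sum(ph$truth$labels == codes["SKIN"])
  nF <- sum(ph$truth$labels == codes["FAT"])
  # predicted skin = true fat, so the overlap is empty
  expect_equal(ev2$dice[ev2$class == "skin"], 2 * 0 / (nF + nS))

  # all-background prediction: recall(SKIN) is 0
  pred0 <- label_volume(array(0L, dim(sw)), ph$truth$spacing)
  ev3 <- evaluate_segmentation(pred0, ph$truth)
  expect_equal(ev3$recall[ev3$class == "skin"], 0)
  # a class absent from both scores 1
  ph0 <- make_breast_phantom(small_phantom_spec(seed = 2, dense_fraction = 0))
  ev4 <- evaluate_segmentation(ph0$truth, ph0$truth)
  expect_equal(ev4$dice[ev4$class == "dense"], 1)

  expect_error(evaluate_segmentation(pred0,
    label_volume(array(0L, c(8, 8, 1)), c(1, 1, 1))), "shape")
})
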