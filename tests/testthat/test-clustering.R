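test_that("c_means degenerate cases: k = 1 and k = number of distinct values", {
  x <- c(4, 8, 15, 16, 23, 42)
  cm1 <- c_means(x, k = 1)
  expect_equal(cm1$means, mean(x))
  expect_equal(cm1$sse, sum((x - mean(x))^2))

  x2 <- rep(c(1, 5, 9), times = c(3, 4, 2))
  cmk <- c_means(x2, k = 3)
  expect_equal(cmk$sse, 0)
  expect_equal(cmk$means, c(1, 5, 9))
  expect_error(c_means(c(1, 1, 2), k = 3), "distinct")
})

test_that("c_means finds the exhaustive contiguous-split optimum on small 1-D samples", {
  x <- c(0.5, 1.1, 1.3, 2.0, 7.2, 7.9, 8.4, 9.0, 9.2, 15.0)
  cm <- c_means(x, k = 2, seed = 1)
  expect_equal(cm$sse, best_split_sse(x), tolerance = 1e-12)

  set.seed(404)
  miss <- 0L
  for (i in 1:40) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n, sd = sample(c(1, 5, 20), 1)), 3)
    if (length(unique(x)) < 2) next
    cm <- c_means(x, k = 2, seed = i)
    ref <- best_split_sse(x)
    if (!isTRUE(all.equal(cm$sse, ref, tolerance = 1e-9))) {
      miss <- miss + 1L
      expect_gte(cm$sse, ref - 1e-9)  # never better than the true optimum
    }
  }
  expect_lt(miss, 3L)
})

test_that("c_means SSE is non-increasing, deterministic, and leaves no empty cluster", {
  set.seed(7)
  for (i in 1:25) {
    x <- c(rnorm(30), rnorm(20, sample(0:8, 1)))
    k <- sample(2:4, 1)
    cm <- c_means(x, k = k, seed = i, init = sample(c("quantile", "random"), 1))
    expect_true(all(diff(cm$sse_trace) <= 1e-9))
    expect_true(all(cm$sizes > 0))
    expect_equal(cm$sse, sum((x - cm$means[cm$assignment])^2), tolerance = 1e-9)
  }
  x <- rnorm(200)
  a <- c_means(x, k = 3, seed = 42, init = "random")
  b <- c_means(x, k = 3, seed = 42, init = "random")
  expect_identical(a$assignment, b$assignment)
  expect_identical(a$means, b$means)
})

test_that("c_means agrees with an independent clustering implementation on separated data", {
  set.seed(11)
  x <- c(rnorm(60, 0, 0.5), rnorm(50, 10, 0.5), rnorm(40, 25, 0.5))
  cm <- c_means(x, k = 3, seed = 1)
  km <- stats::kmeans(x, centers = 3, nstart = 10)
  expect_equal(cm$sse, km$tot.withinss, tolerance = 1e-6)
  expect_equal(sort(cm$means), sort(as.numeric(km$centers)), tolerance = 1e-6)
})

test_that("partition_4 recovers the generating means of a noiseless phantom", {
  ph <- make_breast_phantom(small_phantom_spec(noise_sigma = 0, hetero_sigma = 0,
                                               dense_fraction = 0))
  expect_equal(sort(unique(as.vector(ph$volume$data))), c(2, 57, 90, 200))
  lab <- partition_4(ph$volume, seed = 1)
  expect_equal(attr(lab, "model")$means, c(2, 57, 90, 200))
  expect_equal(attr(lab, "model")$sse, 0)
  # the two middle clusters, and only those, are MIXED
  mid <- attr(lab, "model")$assignment %in% c(2L, 3L)
  expect_identical(as.vector(lab$labels == label_codes()["MIXED"]), mid)
})

test_that("partition_4 puts nearly all true fat in the brightest cluster", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 5))
  sb <- split_breasts(ph$volume)
  roi <- sb$left
  v2 <- low_threshold(curvature_flow(roi$volume), 6)
  lab <- partition_4(v2, seed = 2)
  tr <- roi_truth(ph$truth, roi)
  fat_t <- tr == label_codes()["FAT"]
  expect_gt(sum(lab$labels[fat_t] == label_codes()["FAT"]) / sum(fat_t), 0.95)
})

test_that("recluster_mixed splits on original intensities and maps sub-clusters sanely", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 9))
  sb <- split_breasts(ph$volume)
  v0 <- sb$left$volume
  v2 <- low_threshold(curvature_flow(v0), 6)   # changes essentially every voxel
  lab4 <- partition_4(v2, seed = 3)
  out <- recluster_mixed(v0, lab4, seed = 4)
  sub <- attr(out, "submodel")
  # sub-cluster statistics must come from the original, unfiltered volume
  mixed <- lab4$labels == label_codes()["MIXED"]
  vals <- v0$data[mixed]
  expect_equal(sub$sse, sum((vals - sub$means[sub$assignment])^2),
               tolerance = 1e-6)
  expect_equal(sort(unique(c(sub$means))),
               sort(vapply(1:2, function(j) mean(vals[sub$assignment == j]), 0)),
               tolerance = 1e-9)
  # voxels outside MIXED are untouched
  expect_identical(out$labels[!mixed], lab4$labels[!mixed])
  expect_false(any(out$labels == label_codes()["MIXED"]))

  # two separated populations: boundary equals the exhaustive-split optimum
  lab <- lab4
  vals2 <- v0$data
  vals2[mixed] <- rep(c(10, 60), length.out = sum(mixed)) +
    rep(c(0.1, -0.1), length.out = sum(mixed))
  v0b <- gray_volume(vals2, v0$spacing)
  outb <- recluster_mixed(v0b, lab, seed = 1)
  subb <- attr(outb, "submodel")
  expect_equal(subb$sse, best_split_sse(vals2[mixed]), tolerance = 1e-9)

  # degenerate inputs
  vals3 <- v0$data; vals3[mixed] <- 42
  expect_error(recluster_mixed(gray_volume(vals3, v0$spacing), lab, seed = 1),
               "distinct")
  lab_none <- label_volume(array(0L, dim(v0$data)), v0$spacing)
  expect_warning(out0 <- recluster_mixed(v0, lab_none), "no MIXED")
  expect_identical(out0$labels, lab_none$labels)
})

test_that("recluster_mixed mapping modes control the darker sub-cluster", {
  ph <- make_breast_phantom(small_phantom_spec(seed = 9))
  sb <- split_breasts(ph$volume)
  v0 <- sb$left$volume
  lab4 <- partition_4(low_threshold(curvature_flow(v0), 6), seed = 3)
  mixed <- lab4$labels == label_codes()["MIXED"]
  a <- recluster_mixed(v0, lab4, seed = 1, mapping = "auto")
  b <- recluster_mixed(v0, lab4, seed = 1, mapping = "background")
  c <- recluster_mixed(v0, lab4, seed = 1, mapping = "candidate")
  expect_identical(attr(b, "darker_mapped_to"), "background")
  expect_identical(attr(c, "darker_mapped_to"), "candidate")
  expect_true(all(c$labels[mixed] == label_codes()["DENSE"]))
  expect_true(any(b$labels[mixed] == label_codes()["BACKGROUND"]))
  # on this volume the halo is background-like, so auto chooses background
  expect_identical(a$labels, b$labels)
})
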