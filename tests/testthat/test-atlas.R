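test_that("pose normalization maps the stated ranges onto the unit cube", {
  expect_equal(unname(normalize_pose(slice_pose(-10, 10, 0), 1324)),
               c(0, 1, 0))
  expect_equal(unname(normalize_pose(slice_pose(0, 0, 662), 1324)),
               c(0.5, 0.5, 0.5))
  expect_equal(unname(normalize_pose(slice_pose(5, -5, 331), 1324)),
               c(0.75, 0.25, 0.25))
})

test_that("out-of-range poses are rejected with the offending field named", {
  expect_error(normalize_pose(slice_pose(-11, 0, 0), 1324), "x_angle_deg")
  expect_error(normalize_pose(slice_pose(0, 12, 0), 1324), "y_angle_deg")
  expect_error(normalize_pose(slice_pose(0, 0, 2000), 1324), "ap_index")
})

test_that("normalize/denormalize round-trips to floating-point tolerance", {
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    p <- slice_pose(runif(1, -10, 10), runif(1, -10, 10), runif(1, 0, 1324))
    q <- denormalize_pose(normalize_pose(p, 1324), 1324)
    worst <- max(worst, abs(q$x_angle_deg - p$x_angle_deg),
                 abs(q$y_angle_deg - p$y_angle_deg),
                 abs(q$ap_index - p$ap_index))
  }
  expect_lt(worst, 1e-9)
})

test_that("zero-angle integer-AP slices reproduce the stored axial plane", {
  vol <- test_volume()
  for (k in c(0, 10, 24, 47)) {
    s <- slice_volume(vol, slice_pose(0, 0, k))
    expect_identical(s$image, vol$intensity[k + 1, , ])
    expect_identical(s$labels, vol$labels[k + 1, , ])
  }
})

test_that("slicing a constant volume returns that constant inside the volume", {
  d <- c(40, 40, 40)
  vol <- atlas_volume(array(7, d), array(1L, d))
  s <- slice_volume(vol, slice_pose(6, -4, 20))
  # interior pixels only: trilinear interpolation blends with the zero fill
  # within one voxel of the boundary, so erode the footprint by 2 px
  m <- s$labels == 1
  er <- m
  for (k in 1:2) {
    p <- matrix(FALSE, nrow(er) + 2, ncol(er) + 2)
    p[2:(nrow(er) + 1), 2:(ncol(er) + 1)] <- er
    er <- p[1:nrow(er), 2:(ncol(er) + 1)] & p[3:(nrow(er) + 2), 2:(ncol(er) + 1)] &
          p[2:(nrow(er) + 1), 1:ncol(er)] & p[2:(nrow(er) + 1), 3:(ncol(er) + 2)] &
          p[2:(nrow(er) + 1), 2:(ncol(er) + 1)]
  }
  expect_true(any(er))
  expect_true(all(abs(s$image[er] - 7) < 1e-9))
})

test_that("oblique label slices never invent label ids", {
  vol <- test_volume()
  ids <- unique(as.vector(vol$labels))
  for (p in list(slice_pose(7, 3, 12), slice_pose(-9, -9, 30),
                 slice_pose(0, 10, 44.5))) {
    s <- slice_volume(vol, p)
    expect_true(all(unique(as.vector(s$labels)) %in% c(0, ids)))
  }
})

test_that("oblique slab fraction matches a supersampled brute-force sampler", {
  # slab phantom spanning AP indices 14..20 of a 40^3 volume
  d <- c(40, 40, 40)
  labels <- array(0L, d)
  labels[15:21, , ] <- 1L
  vol <- atlas_volume(array(as.numeric(labels), d), labels)
  pose <- slice_pose(5, 0, 17)
  s <- slice_volume(vol, pose)
  frac <- mean(s$labels == 1)
  frac_oracle <- oracle_slab_fraction(vol, pose, 1L, supersample = 4)
  expect_lt(abs(frac - frac_oracle), 0.01)
})

test_that("fully out-of-volume poses are rejected", {
  vol <- test_volume()
  expect_error(slice_volume(vol, slice_pose(0, 0, 500)), "AP range")
})

test_that("pose angle averaging is the arithmetic mean", {
  expect_equal(unname(average_pose_angles(list(slice_pose(2, 4, 0),
                                               slice_pose(4, 0, 9)))),
               c(3, 2))
  expect_equal(unname(average_pose_angles(list(slice_pose(1.5, -2, 3)))),
               c(1.5, -2))
  expect_equal(unname(average_pose_angles(list(slice_pose(-1, -1, 0),
                                               slice_pose(1, 1, 0),
                                               slice_pose(0, 0, 0)))),
               c(0, 0))
  expect_error(average_pose_angles(list()), "non-empty")
  shared <- apply_average_angles(list(slice_pose(2, 4, 5), slice_pose(4, 0, 9)))
  expect_equal(shared[[1]]$x_angle_deg, 3)
  expect_equal(shared[[2]]$y_angle_deg, 2)
  expect_equal(shared[[2]]$ap_index, 9)   # AP preserved per section
})

test_that("training-sample generation is reproducible and well distributed", {
  vol <- test_volume()
  a <- generate_training_samples(vol, 10, seed = 7, size = 64)
  b <- generate_training_samples(vol, 10, seed = 7, size = 64)
  expect_identical(a, b)
  expect_true(all(vapply(a, function(s) all(dim(s$image) == c(64, 64)),
                         logical(1))))
  expect_true(all(vapply(a, function(s)
    all(s$pose_normalized >= 0 & s$pose_normalized <= 1), logical(1))))
  expect_error(generate_training_samples(vol, 0, seed = 1), ">= 1")
})

test_that("hemisphere cropping happens for about half of training samples", {
  vol <- test_volume()
  s <- generate_training_samples(vol, 2000, seed = 1, size = 32)
  hemi <- vapply(s, function(x) x$hemisphere, character(1))
  frac <- mean(hemi != "both")
  expect_gte(frac, 0.45)
  expect_lte(frac, 0.55)
  # left/right equiprobable within crops
  lr <- hemi[hemi != "both"]
  expect_gt(mean(lr == "left"), 0.4)
  expect_lt(mean(lr == "left"), 0.6)
  # uniform angles: normalized means near 0.5
  nrm <- t(vapply(s, function(x) x$pose_normalized, numeric(3)))
  expect_true(all(colMeans(nrm)[1:2] > 0.48 & colMeans(nrm)[1:2] < 0.52))
})

test_that("pose predictors return normalized triples and locate the AP axis", {
  vol <- test_volume()
  stub <- pose_predictor_constant(c(0.2, 0.8, 0.5))
  expect_equal(stub(matrix(0, 256, 256)), c(0.2, 0.8, 0.5))
  pred <- pose_predictor_template(vol, n_templates = 24)
  for (ap in c(10, 24, 38)) {
    sec <- slice_volume(vol, slice_pose(0, 0, ap), with_labels = FALSE)
    z <- pred(resize_image(sec$image, 256, 256))[3]
    expect_lt(abs(z * ap_max(vol) - ap), 5)
  }
})
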