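test_that("MI of a two-valued pattern with itself equals its marginal entropy", {
  x <- matrix(rep(c(0, 1), 32), 8, 8)
  p <- mean(x)
  entropy <- -(p * log(p) + (1 - p) * log(1 - p))
  expect_equal(-mattes_mi(x, x), entropy, tolerance = 1e-12)
  y <- matrix(rep(c(2, 2, 9), length.out = 64), 8, 8)
  py <- table(y) / 64
  expect_equal(-mattes_mi(y, y), -sum(py * log(py)), tolerance = 1e-12)
})

test_that("MI matches the brute-force joint-histogram oracle", {
  set.seed(31)
  for (k in 1:5) {
    f <- matrix(runif(32 * 32), 32, 32)
    m <- 0.6 * f + 0.4 * matrix(runif(32 * 32), 32, 32)
    expect_equal(mattes_mi(f, m), oracle_mi(f, m), tolerance = 1e-6)
  }
})

test_that("shuffling destroys mutual information", {
  set.seed(17)
  x <- matrix(runif(256), 16, 16)
  self <- -mattes_mi(x, x)
  shuffled <- replicate(20, {
    -mattes_mi(x, matrix(sample(x), 16, 16))
  })
  expect_lt(mean(shuffled), self)
})

test_that("MI mask semantics: full mask is identity, constant pair is zero", {
  set.seed(13)
  f <- matrix(runif(100), 10, 10); m <- matrix(runif(100), 10, 10)
  expect_identical(mattes_mi(f, m, fixed_mask = matrix(TRUE, 10, 10)),
                   mattes_mi(f, m))
  expect_equal(mattes_mi(matrix(1, 8, 8), matrix(2, 8, 8)), 0)
  half <- matrix(FALSE, 10, 10); half[1:5, ] <- TRUE
  expect_equal(mattes_mi(f, m, fixed_mask = half),
               oracle_mi(f[1:5, ], m[1:5, ]), tolerance = 1e-6)
})

test_that("neighborhood correlation scores perfect and affine-intensity matches as -1", {
  set.seed(19)
  f <- gaussian_blur(matrix(runif(256), 16, 16), 1)
  expect_equal(neighborhood_correlation(f, f, 3), -1, tolerance = 1e-9)
  expect_equal(neighborhood_correlation(f, 2.5 * f + 7, 3), -1, tolerance = 1e-9)
  expect_error(neighborhood_correlation(matrix(0, 4, 4), matrix(0, 4, 4), 3),
               "smaller")
})

test_that("neighborhood correlation matches the windowed-Pearson oracle", {
  set.seed(23)
  for (r in c(1, 3)) {
    f <- matrix(runif(256), 16, 16)
    m <- 0.5 * f + 0.5 * matrix(runif(256), 16, 16)
    expect_equal(neighborhood_correlation(f, m, r), oracle_ncc(f, m, r),
                 tolerance = 1e-6)
  }
})

test_that("centered initialization recovers translations via centroids", {
  img <- matrix(0, 60, 60)
  img[20:30, 25:35] <- 1
  t0 <- init_centered_affine(img, img)
  expect_equal(t0$A, diag(2))
  expect_equal(t0$b, c(0, 0), tolerance = 1e-9)
  shifted <- matrix(0, 60, 60)
  shifted[20:30, 35:45] <- 1     # moving shifted +10 in x
  t1 <- init_centered_affine(img, shifted)
  expect_equal(t1$b, c(-10, 0), tolerance = 1e-9)
  expect_warning(init_centered_affine(img, matrix(0, 60, 60)), "constant")
})

test_that("the affine stage recovers known transforms on phantom sections", {
  vol <- test_volume()
  atl <- slice_volume(vol, slice_pose(1, 0, 24), with_labels = FALSE)
  f <- pad_image(to_gradient(resize_image(atl$image, 180, 180)), 25)
  cfg <- fast_opt_cfg()
  # identity
  t_id <- fit_affine(f, f, cfg)
  expect_lt(max(abs(t_id$A - diag(2))), 1e-2)
  expect_lt(sqrt(sum(t_id$b^2)), 0.5)
  # 5 degree rotation about center
  th <- 5 * pi / 180
  gt <- affine_transform(A = matrix(c(cos(th), -sin(th), sin(th), cos(th)),
                                    2, 2, byrow = TRUE),
                         center = c(114.5, 114.5))
  fixed <- apply_transform(f, gt)
  t_rot <- fit_affine(fixed, f, cfg)
  ang <- atan2(t_rot$A[2, 1], t_rot$A[1, 1]) * 180 / pi
  expect_lt(abs(ang - 5), 0.5)
  # 1.1x scale
  gs <- affine_transform(A = diag(2) * 1.1, center = c(114.5, 114.5))
  fixed_s <- apply_transform(f, gs)
  t_scl <- fit_affine(fixed_s, f, cfg)
  scl <- sqrt(abs(det(t_scl$A)))
  expect_gte(scl, 1.08)
  expect_lte(scl, 1.12)
})

test_that("the B-spline stage recovers a known same-mesh deformation", {
  vol <- test_volume()
  atl <- slice_volume(vol, slice_pose(0, 1, 22), with_labels = FALSE)
  f <- pad_image(to_gradient(resize_image(atl$image, 180, 180)), 25)
  cfg <- fast_opt_cfg()
  # identity: control points stay still
  b_id <- fit_bspline(f, f, cfg)
  expect_lt(max(abs(c(b_id$Px, b_id$Py))), 0.5)
  # known 4 px bulge of the same parameterization
  set.seed(44)
  Px <- matrix(runif(49, -4, 4), 7, 7); Py <- matrix(runif(49, -4, 4), 7, 7)
  gt <- bspline_transform(mesh = c(4, 4), Px = Px, Py = Py, domain = dim(f))
  fixed <- apply_transform(f, gt)
  b_fit <- fit_bspline(fixed, f, cfg)
  u_gt <- bspline_displacement(gt)
  u_ft <- bspline_displacement(b_fit)
  rms <- sqrt(mean((u_gt$ux - u_ft$ux)^2 + (u_gt$uy - u_ft$uy)^2))
  expect_lt(rms, 1)
  # optimizer contract: the accepted-step metric log is non-increasing
  expect_true(all(diff(attr(b_fit, "trace")) <= 0))
})
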