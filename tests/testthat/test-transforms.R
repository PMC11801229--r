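test_that("identity transforms leave images unchanged", {
  set.seed(5)
  img <- matrix(runif(400), 20, 20)
  aff <- affine_transform()
  expect_equal(apply_transform(img, aff), img)
  bsp <- bspline_transform(mesh = c(4, 4), domain = c(20, 20))
  expect_equal(apply_transform(img, bsp), img)
  ct <- composite_transform(aff, bsp)
  expect_equal(apply_transform(img, ct), img)
})

test_that("a pure translation moves an impulse by exactly its offset", {
  img <- matrix(0, 21, 21); img[11, 11] <- 1
  t <- affine_transform(b = c(3, 0))
  out <- apply_transform(img, t, "nearest")
  expect_equal(which(out == 1, arr.ind = TRUE)[1, ], c(row = 11, col = 14))
  t2 <- affine_transform(b = c(-2, 4))
  out2 <- apply_transform(img, t2, "nearest")
  expect_equal(which(out2 == 1, arr.ind = TRUE)[1, ], c(row = 15, col = 9))
})

test_that("nearest-neighbor warping never invents label ids", {
  set.seed(8)
  labs <- matrix(sample(c(0, 3, 7, 9), 900, TRUE), 30, 30)
  th <- 11 * pi / 180
  t <- composite_transform(
    affine_transform(A = matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2),
                     b = c(2, -1), center = c(14.5, 14.5)),
    bspline_transform(mesh = c(4, 4), Px = matrix(runif(49, -3, 3), 7, 7),
                      Py = matrix(runif(49, -3, 3), 7, 7), domain = c(30, 30)))
  out <- apply_transform(labs, t, "nearest")
  expect_true(all(out %in% c(labs, 0)))
})

test_that("composite application equals sequential stage application", {
  set.seed(9)
  img <- gaussian_blur(matrix(runif(3600), 60, 60), 1)
  aff <- affine_transform(A = matrix(c(1.05, 0.02, -0.03, 0.97), 2, 2),
                          b = c(1.5, -2), center = c(29.5, 29.5))
  bsp <- bspline_transform(mesh = c(4, 4), Px = matrix(runif(49, -2, 2), 7, 7),
                           Py = matrix(runif(49, -2, 2), 7, 7), domain = c(60, 60))
  ct <- composite_transform(aff, bsp)
  a <- apply_transform(img, ct)
  b <- apply_transform(apply_transform(img, aff), bsp)
  expect_lt(mean(abs(a - b)), 1e-4)
})

test_that("B-spline displacement interpolates its control points smoothly", {
  # a single interior control point produces a localized smooth bump
  Px <- matrix(0, 7, 7); Px[4, 4] <- 10
  t <- bspline_transform(mesh = c(4, 4), Px = Px, domain = c(81, 81))
  u <- bspline_displacement(t)
  expect_equal(max(abs(u$uy)), 0)
  expect_gt(max(u$ux), 10 * (2 / 3)^2 - 1e-6)   # central basis weight squared
  expect_lt(max(u$ux), 10)
  expect_equal(u$ux[1, 1], 0)                    # outside the support
})

test_that("transform JSON serialization round-trips exactly", {
  aff <- affine_transform(A = matrix(c(1.017, -0.0831, 0.0779, 0.9641), 2, 2),
                          b = c(3.14159, -2.71828), center = c(179.5, 179.5))
  bsp <- bspline_transform(mesh = c(4, 4),
                           Px = matrix(rnorm(49), 7, 7),
                           Py = matrix(rnorm(49), 7, 7), domain = c(460, 460))
  ct <- composite_transform(aff, bsp,
                            meta = list(working_size = 360, pad_px = 50,
                                        native_size = c(72, 72)))
  f <- tempfile(fileext = ".json")
  transform_to_json(ct, f)
  back <- transform_from_json(f)
  expect_identical(back$affine$A, ct$affine$A)
  expect_identical(back$affine$b, ct$affine$b)
  expect_identical(back$bspline$Px, ct$bspline$Px)
  expect_identical(back$bspline$Py, ct$bspline$Py)
  expect_equal(back$meta$native_size, c(72, 72))
  img <- matrix(runif(460 * 460), 460, 460)
  expect_identical(apply_transform(img, back), apply_transform(img, ct))
})

test_that("degenerate transforms are rejected", {
  expect_error(affine_transform(A = matrix(c(1, 2, 2, 4), 2, 2)), "det")
  expect_error(bspline_transform(mesh = c(1, 4), domain = c(10, 10)), ">= 2")
  img <- matrix(0, 10, 10)
  t <- bspline_transform(mesh = c(4, 4), domain = c(20, 20))
  expect_error(apply_transform(img, t), "domain")
})
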