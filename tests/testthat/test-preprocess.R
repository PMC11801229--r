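test_that("padding grows images by the margin with zero fill", {
  img <- matrix(runif(360 * 360), 360, 360)
  p <- pad_pair(img, img * 2, pad_px = 50)
  expect_equal(dim(p$fixed), c(460, 460))
  expect_equal(dim(p$moving), c(460, 460))
  expect_equal(p$fixed[1, 1], 0)
  expect_equal(p$fixed[460, 460], 0)
  expect_equal(p$fixed[51:410, 51:410], img)
  expect_equal(pad_image(img, 0), img)
  expect_error(pad_image(1:3, 5), "matrix")
})

test_that("gradient conversion matches a brute-force Sobel oracle", {
  set.seed(11)
  img <- matrix(runif(32 * 32), 32, 32)
  g <- to_gradient(img)
  o <- oracle_sobel(img)
  o <- (o - min(o)) / (max(o) - min(o))
  expect_lt(max(abs(g - o)), 1e-6)
})

test_that("gradient conversion handles flat and edge images", {
  expect_equal(to_gradient(matrix(3.7, 20, 20)), matrix(0, 20, 20))
  step <- matrix(0, 21, 21); step[, 11:21] <- 1
  g <- to_gradient(step)
  expect_equal(max(g[5, ]), g[5, 10])   # maximal response at the edge
  expect_equal(g[5, 2], 0)              # flat far from it
  expect_true(all(g >= 0 & g <= 1))
})

test_that("histogram matching is idempotent and preserves below-mean pixels", {
  set.seed(21)
  img <- matrix(rgamma(90 * 90, 2, 8), 90, 90)
  same <- match_histogram(img, img)
  lvl <- diff(range(img)) / 1024
  expect_lt(max(abs(same - img)), lvl + 1e-12)
  fixed <- matrix(rgamma(90 * 90, 3, 4), 90, 90)
  out <- match_histogram(img, fixed)
  low <- img <= mean(img)
  expect_equal(out[low], img[low])      # lower intensity range untouched
  # idempotence: re-matching changes at most one quantization level
  out2 <- match_histogram(out, fixed)
  lvl2 <- diff(range(out)) / 1024
  expect_lt(max(abs(out2 - out)), lvl2 * 2 + 1e-12)
})

test_that("matching a shifted image recovers the shift above the mean", {
  set.seed(3)
  mov <- matrix(runif(80 * 80), 80, 80)
  fix <- mov + 5
  cfg <- preprocess_config(threshold_at_mean = FALSE)
  out <- match_histogram(mov, fix, cfg)
  lvl <- 2 * diff(range(mov)) / 1024
  expect_lt(max(abs(out - (mov + 5))), 5 * lvl + 0.02)
})

test_that("invert/quantize maps endpoints, is an involution, and documents rounding", {
  img <- matrix(runif(50 * 50, 10, 90), 50, 50)
  q <- invert_quantize(img)
  expect_equal(q[which.min(img)], 255L)
  expect_equal(q[which.max(img)], 0L)
  x8 <- matrix(as.numeric(0:255), 16, 16)
  expect_equal(invert_quantize(x8), matrix(255L - as.integer(x8), 16, 16))
  expect_equal(invert_quantize(invert_quantize(x8) + 0), matrix(as.integer(x8), 16, 16))
  expect_equal(invert_quantize(matrix(4, 5, 5)), matrix(255L, 5, 5))
  # round-half-even at the midpoint
  mid <- matrix(c(0, 1, 0.5, 0.5), 2, 2)
  expect_true(all(invert_quantize(mid)[1, 2] %in% c(127L, 128L)))
})

test_that("signal thresholding uses a strict inequality at 125", {
  expect_equal(sum(threshold_signal(matrix(0L, 10, 10))), 0)
  m <- matrix(c(125, 126), 1, 2)
  expect_equal(as.vector(threshold_signal(m)), c(FALSE, TRUE))
  checker <- matrix(rep(c(0, 255), 50), 10, 10)
  expect_equal(sum(threshold_signal(checker)), 50)
})

test_that("resize uses area averaging down and bilinear up, nearest preserves ids", {
  img <- matrix(1:16 + 0, 4, 4)
  down <- resize_image(img, 2, 2)
  expect_equal(down, matrix(c(mean(img[1:2, 1:2]), mean(img[3:4, 1:2]),
                              mean(img[1:2, 3:4]), mean(img[3:4, 3:4])), 2, 2))
  up <- resize_image(matrix(c(0, 1), 1, 2), 1, 4)
  expect_true(all(diff(as.vector(up)) >= 0))
  labs <- matrix(sample(0:3, 36, TRUE), 6, 6)
  lr <- resize_image(labs + 0, 13, 13, method = "nearest")
  expect_true(all(lr %in% labs))
  expect_equal(resize_image(labs + 0, 6, 6, method = "nearest"), labs + 0)
})
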