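test_that("tiling covers every pixel with the expected stride", {
  cfg <- tiling_config()
  img1 <- matrix(runif(640 * 640), 640, 640)
  t1 <- tile_image(img1, cfg)
  expect_length(t1, 1)
  expect_equal(unname(t1[[1]]$offset), c(0, 0))
  img2 <- matrix(runif(640 * 1280), 640, 1280)
  t2 <- tile_image(img2, cfg)
  expect_length(t2, 3)
  expect_setequal(vapply(t2, function(t) t$offset[["x"]], numeric(1)),
                  c(0, 320, 640))
  # pixel-coverage oracle on an odd-sized image
  cfg3 <- tiling_config(tile_size = 64, overlap_fraction = 0.5)
  img3 <- matrix(runif(150 * 97), 150, 97)
  cov <- matrix(0, 150, 97)
  for (t in tile_image(img3, cfg3)) {
    rows <- (t$offset[["y"]] + 1):min(t$offset[["y"]] + 64, 150)
    cols <- (t$offset[["x"]] + 1):min(t$offset[["x"]] + 64, 97)
    cov[rows, cols] <- cov[rows, cols] + 1
    # tile content matches the source at its offset
    expect_equal(t$tile[seq_along(rows), seq_along(cols)], img3[rows, cols])
  }
  expect_true(all(cov >= 1))
  # small image: one zero-padded tile
  t4 <- tile_image(matrix(1, 10, 10), cfg3)
  expect_length(t4, 1)
  expect_equal(dim(t4[[1]]$tile), c(64, 64))
  expect_equal(t4[[1]]$tile[64, 64], 0)
  expect_equal(t4[[1]]$tile[11, 1], 0)
})

test_that("NMS removes duplicates, keeps disjoint boxes, matches the exhaustive oracle", {
  two <- data.frame(x_min = c(10, 10), y_min = c(10, 10),
                    x_max = c(20, 20), y_max = c(20, 20),
                    confidence = c(0.9, 0.8))
  expect_equal(nms(two, 0.5)$confidence, 0.9)
  disjoint <- data.frame(x_min = c(0, 50), y_min = c(0, 50),
                         x_max = c(10, 60), y_max = c(10, 60),
                         confidence = c(0.5, 0.4))
  expect_equal(nrow(nms(disjoint, 0.5)), 2)
  set.seed(41)
  for (k in 1:3) {
    n <- 50
    x0 <- runif(n, 0, 80); y0 <- runif(n, 0, 80)
    d <- data.frame(x_min = x0, y_min = y0, x_max = x0 + runif(n, 5, 25),
                    y_max = y0 + runif(n, 5, 25),
                    confidence = round(runif(n), 3))
    expect_equal(nms(d, 0.5), oracle_nms(d, 0.5))
  }
})

test_that("the blob detector finds isolated Gaussian blobs and rejects noise", {
  set.seed(51)
  # single blob, SNR 10
  sc <- scatter_synthetic_cells(c(96, 96), n = 1, radius_range_px = c(5, 5),
                                intensity_range = c(1, 1), noise_sigma = 0.1,
                                seed = 2)
  det <- default_blob_detector(sc$image)
  expect_equal(nrow(det), 1)
  cx <- (det$x_min + det$x_max) / 2; cy <- (det$y_min + det$y_max) / 2
  tx <- (sc$boxes$x_min + sc$boxes$x_max) / 2
  ty <- (sc$boxes$y_min + sc$boxes$y_max) / 2
  expect_lt(sqrt((cx - tx)^2 + (cy - ty)^2), 2)
  # pure noise: no detections in >= 95% of seeds, up to noise SD 0.1
  fp <- vapply(1:40, function(s) {
    img <- scatter_synthetic_cells(c(96, 96), n = 0,
                                   noise_sigma = if (s %% 2) 0.05 else 0.1,
                                   seed = s)$image
    nrow(default_blob_detector(img))
  }, numeric(1))
  expect_gte(mean(fp == 0), 0.95)
  # two blobs 20 px apart are separated
  img2 <- matrix(0.1, 96, 96)
  xs <- matrix(rep(1:96, each = 96), 96); ys <- matrix(rep(1:96, 96), 96)
  img2 <- img2 + exp(-((xs - 40)^2 + (ys - 48)^2) / (2 * 2.5^2)) +
    exp(-((xs - 60)^2 + (ys - 48)^2) / (2 * 2.5^2))
  expect_equal(nrow(default_blob_detector(img2)), 2)
})

test_that("tiled detection merges duplicates across tile boundaries", {
  cfg <- tiling_config(tile_size = 64, overlap_fraction = 0.5,
                       confidence_threshold = 0.25)
  # one cell straddling the boundary between tiles (x = 64 with stride 32)
  img <- matrix(0.1, 64, 128)
  xs <- matrix(rep(1:128, each = 64), 64); ys <- matrix(rep(1:64, 128), 64)
  img <- img + exp(-((xs - 64)^2 + (ys - 32)^2) / (2 * 2.5^2))
  det <- tiled_detect(img, default_blob_detector, cfg)
  expect_equal(nrow(det), 1)
  expect_lt(abs((det$x_min + det$x_max) / 2 - 64), 2)
  # empty image yields an empty frame
  expect_equal(nrow(tiled_detect(matrix(0, 32, 32), default_blob_detector, cfg)), 0)
})

test_that("a perfect oracle detector yields exactly the planted count", {
  sc <- scatter_synthetic_cells(c(300, 300), n = 100, seed = 9,
                                min_spacing_px = 16)
  cfg <- tiling_config(tile_size = 128, overlap_fraction = 0.5,
                       confidence_threshold = 0.1)
  oracle_det <- function(tile) {
    # ground truth in tile-local coordinates; a detector only reports cells
    # whose center falls inside its tile
    off <- attr(tile, "offset")
    b <- sc$boxes
    b$x_min <- b$x_min - off[["x"]]; b$x_max <- b$x_max - off[["x"]]
    b$y_min <- b$y_min - off[["y"]]; b$y_max <- b$y_max - off[["y"]]
    cx <- (b$x_min + b$x_max) / 2; cy <- (b$y_min + b$y_max) / 2
    b[cx >= 1 & cx <= ncol(tile) & cy >= 1 & cy <= nrow(tile), , drop = FALSE]
  }
  final <- tiled_detect(sc$image, oracle_det, cfg)
  expect_equal(nrow(final), 100)
})

test_that("tiled detection is deterministic, order-invariant and in-bounds", {
  sc <- scatter_synthetic_cells(c(200, 200), n = 40, seed = 3)
  cfg <- tiling_config(tile_size = 96, overlap_fraction = 0.5)
  a <- tiled_detect(sc$image, default_blob_detector, cfg)
  b <- tiled_detect(sc$image, default_blob_detector, cfg)
  expect_identical(a, b)
  expect_true(all(a$x_min >= 1 & a$x_max <= 200 &
                  a$y_min >= 1 & a$y_max <= 200))
  expect_true(all(a$confidence >= cfg$confidence_threshold))
})

test_that("a failing detector skips its tile and is reported", {
  cfg <- tiling_config(tile_size = 64, overlap_fraction = 0)
  img <- matrix(0.1, 64, 128)
  calls <- 0
  flaky <- function(tile) {
    calls <<- calls + 1
    if (calls == 1) stop("synthetic failure")
    empty_detections()
  }
  expect_message(det <- tiled_detect(img, flaky, cfg), "synthetic failure")
  expect_equal(attr(det, "failed_tiles"), 1L)
})
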