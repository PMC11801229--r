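test_that("per-region pixel counting matches an exhaustive tally", {
  set.seed(61)
  labels <- matrix(sample(0:4, 64 * 64, TRUE), 64, 64)
  mask <- matrix(runif(64 * 64) < 0.3, 64, 64)
  tab <- count_pixels_by_region(mask, labels)
  for (k in sort(unique(as.vector(labels)))) {
    row <- tab[tab$region_id == k, ]
    expect_equal(row$total_px, sum(labels == k))
    expect_equal(row$signal_px, sum(mask & labels == k))
    expect_equal(row$proportion, row$signal_px / row$total_px)
  }
  # empty mask: all proportions zero
  t0 <- count_pixels_by_region(matrix(FALSE, 64, 64), labels)
  expect_true(all(t0$proportion == 0))
  # mask == region k: proportion 1 there, 0 elsewhere
  tk <- count_pixels_by_region(labels == 2, labels)
  expect_equal(tk$proportion[tk$region_id == 2], 1)
  expect_true(all(tk$proportion[tk$region_id != 2] == 0))
  expect_error(count_pixels_by_region(mask[1:10, ], labels), "shape")
})

test_that("signal pixels are conserved across regions", {
  set.seed(62)
  for (i in 1:100) {
    labels <- matrix(sample(0:sample(1:6, 1), 32 * 32, TRUE), 32, 32)
    mask <- matrix(runif(32 * 32) < runif(1), 32, 32)
    tab <- count_pixels_by_region(mask, labels)
    expect_identical(sum(tab$signal_px), sum(mask))
    expect_identical(sum(tab$total_px), 1024L)
  }
})

test_that("detections are assigned to the region under their box center", {
  labels <- matrix(0L, 40, 40)
  labels[10:20, 10:20] <- 5L
  det <- data.frame(x_min = 12, y_min = 12, x_max = 18, y_max = 18,
                    confidence = 0.9)
  tab <- assign_detections_to_regions(det, labels)
  expect_equal(tab$cell_count[tab$region_id == 5], 1)
  # background center counts under "unassigned"
  det0 <- data.frame(x_min = 30, y_min = 30, x_max = 36, y_max = 36,
                     confidence = 0.8)
  tab0 <- assign_detections_to_regions(det0, labels)
  expect_equal(tab0$cell_count[tab0$region_id == 0], 1)
  expect_equal(tab0$acronym[tab0$region_id == 0], "unassigned")
  # no detections: all zero
  tz <- assign_detections_to_regions(empty_detections(), labels)
  expect_true(all(tz$cell_count == 0))
})

test_that("synthetic cells scattered in one region all count there", {
  labels <- matrix(0L, 200, 200)
  labels[60:140, 60:140] <- 3L
  sc <- scatter_synthetic_cells(c(200, 200), n = 100,
                                region_mask = labels == 3, seed = 4,
                                min_spacing_px = 4)
  tab <- assign_detections_to_regions(sc$boxes, labels)
  expect_equal(tab$cell_count[tab$region_id == 3], 100)
})

test_that("ontology rollup sums descendants into the nearest target ancestor", {
  ont <- toy_ontology()
  tab <- count_pixels_by_region(
    mask = matrix(c(TRUE, FALSE), 8, 8),
    labels = matrix(rep(c(0L, 3L, 4L, 5L), 16), 8, 8), ont)
  # roll leaves up to CTX + MB
  up <- rollup(tab, ont, c("CTX", "MB"))
  ctx <- up[up$acronym == "CTX", ]
  expect_equal(ctx$total_px, sum(tab$total_px[tab$region_id %in% c(2, 3, 4)]))
  expect_equal(ctx$signal_px, sum(tab$signal_px[tab$region_id %in% c(2, 3, 4)]))
  expect_equal(up$total_px[up$acronym == "MB"],
               tab$total_px[tab$region_id == 5])
  # totals preserved exactly
  expect_identical(sum(up$total_px), sum(tab$total_px))
  expect_identical(sum(up$signal_px), sum(tab$signal_px))
  # rollup to the root keeps one tissue row plus unassigned
  root <- rollup(tab, ont, "root")
  expect_identical(sum(root$signal_px), sum(tab$signal_px))
  # rollup to the leaf set is the identity on leaf rows
  leaves <- rollup(tab, ont, c("L23", "L5", "MB"))
  expect_equal(leaves$signal_px[leaves$region_id == 3],
               tab$signal_px[tab$region_id == 3])
  expect_error(rollup(tab, ont, "missing"), "not in ontology")
})

test_that("cyclic ontologies are rejected", {
  df <- data.frame(id = c(1, 2, 3), acronym = c("a", "b", "c"),
                   name = c("a", "b", "c"), parent_id = c(NA, 3, 2))
  expect_error(ontology(df), "cycle")
})

test_that("hand-worked three-level rollup", {
  ont <- toy_ontology()
  tab <- data.frame(region_id = c(3, 4, 5), acronym = c("L23", "L5", "MB"),
                    total_px = c(10L, 20L, 30L), signal_px = c(1L, 2L, 3L),
                    proportion = c(0.1, 0.1, 0.1), cell_count = c(4L, 5L, 6L))
  class(tab) <- c("region_table", "data.frame")
  up <- rollup(tab, ont, "CTX")
  expect_equal(up$signal_px[up$acronym == "CTX"], 3L)  # 1 + 2
  expect_equal(up$cell_count[up$acronym == "CTX"], 9L) # 4 + 5
  expect_equal(up$cell_count[up$acronym == "MB"], 6L)  # untouched, no target
})
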