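# register_composite tests run at a reduced working geometry (180 px + 25 px
# pad) to keep the suite fast; the full 360 px default geometry is exercised
# by the acceptance suite.

make_pair <- function(seed, d = NULL, section_size = 180) {
  vol <- test_volume()
  set.seed(seed)
  pose <- slice_pose(runif(1, -4, 4), runif(1, -4, 4), runif(1, 18, 30))
  if (is.null(d))
    d <- deformation_spec(rotation_deg = runif(1, -5, 5),
                          translation_px = runif(2, -8, 8),
                          bspline_amplitude_px = 5, noise_sigma = 0.02,
                          seed = seed * 7)
  md <- make_deformed_section(vol, pose, d, section_size = section_size)
  atl <- slice_volume(vol, pose)
  atl_rs <- section(image = resize_image(atl$image, section_size, section_size),
                    labels = resize_image(atl$labels, section_size,
                                          section_size, method = "nearest"),
                    pose = pose)
  list(fixed = md$section, atlas = atl_rs, truth = md)
}

test_that("registering an atlas slice to itself is the identity", {
  vol <- test_volume()
  pose <- slice_pose(1, -1, 24)
  atl <- slice_volume(vol, pose)
  reg <- register_composite(atl, atl, pre_cfg = fast_pre_cfg(),
                            opt_cfg = fast_opt_cfg())
  expect_gte(dice(reg$warped_labels > 0, atl$labels > 0), 0.99)
  expect_lt(max(abs(reg$transform$affine$A - diag(2))), 1e-2)
  expect_lt(sqrt(sum(reg$transform$affine$b^2)), 0.5)
})

test_that("moderate synthetic deformations are recovered and the B-spline helps", {
  p <- make_pair(101)
  reg <- register_composite(p$fixed, p$atlas, pre_cfg = fast_pre_cfg(),
                            opt_cfg = fast_opt_cfg())
  d_comp <- dice(reg$warped_labels > 0, p$fixed$labels > 0)
  d_aff <- dice(reg$warped_labels_affine > 0, p$fixed$labels > 0)
  expect_gte(d_comp, 0.9)
  expect_gte(d_comp, d_aff)
  # warped labels never invent ids
  expect_true(all(unique(as.vector(reg$warped_labels)) %in%
                  c(0, unique(as.vector(p$atlas$labels)))))
})

test_that("registration is deterministic", {
  p <- make_pair(103)
  a <- register_composite(p$fixed, p$atlas, pre_cfg = fast_pre_cfg(),
                          opt_cfg = fast_opt_cfg())
  b <- register_composite(p$fixed, p$atlas, pre_cfg = fast_pre_cfg(),
                          opt_cfg = fast_opt_cfg())
  expect_identical(a$transform$affine$A, b$transform$affine$A)
  expect_identical(a$transform$bspline$Px, b$transform$bspline$Px)
  expect_identical(a$warped_labels, b$warped_labels)
})

test_that("masking a corner artifact keeps unmasked-area alignment stable", {
  p <- make_pair(105, d = deformation_spec(rotation_deg = 3,
                                           translation_px = c(5, -4),
                                           bspline_amplitude_px = 4,
                                           noise_sigma = 0.02, seed = 55))
  n <- nrow(p$fixed$image)
  side <- round(sqrt(0.2) * n)          # ~20% of the area
  artifact <- matrix(FALSE, n, n)
  artifact[seq_len(side), seq_len(side)] <- TRUE
  damaged <- p$fixed$image
  set.seed(66)
  damaged[artifact] <- 0.8 + rnorm(sum(artifact), sd = 0.05)
  clean_reg <- register_composite(p$fixed, p$atlas, pre_cfg = fast_pre_cfg(),
                                  opt_cfg = fast_opt_cfg())
  dmg_sec <- section(image = damaged, labels = p$fixed$labels)
  dmg_reg <- register_composite(dmg_sec, p$atlas, mask = artifact,
                                pre_cfg = fast_pre_cfg(),
                                opt_cfg = fast_opt_cfg())
  keep <- !artifact
  d_clean <- dice((clean_reg$warped_labels > 0) & keep,
                  (p$fixed$labels > 0) & keep)
  d_masked <- dice((dmg_reg$warped_labels > 0) & keep,
                   (p$fixed$labels > 0) & keep)
  expect_lt(abs(d_clean - d_masked), 0.02)
  # damaged atlas pixels are zeroed in the masked output
  expect_true(all(dmg_reg$warped_atlas[artifact] == 0))
})

test_that("stage errors carry their stage tag", {
  expect_error(register_composite(matrix(1, 50, 50), matrix(1, 50, 50),
                                  mask = matrix(FALSE, 10, 10)),
               "mask")
})
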