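# Build a complete on-disk experiment fixture: phantom volume (NRRD),
# deformed counterstain sections, synthetic-cell signal sections, ontology,
# and the fine-tuned pose file. Returns the paths plus per-section ground
# truth.
build_experiment_fixture <- function(root, n_sections = 3, section_size = 180,
                                     seed = 1) {
  vol <- test_volume()
  dir.create(file.path(root, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(root, "signal"), showWarnings = FALSE)
  vi <- file.path(root, "intensity.nrrd")
  vl <- file.path(root, "labels.nrrd")
  write_nrrd(vol$intensity, vi, type = "float", encoding = "gzip")
  write_nrrd(vol$labels, vl, type = "int32", encoding = "gzip")
  ont_path <- file.path(root, "ontology.csv")
  write.csv(data.frame(id = c(99, 1, 2, 3, 4, 5),
                       acronym = c("root", "shell4", "shell3", "shell2",
                                   "shell1", "nucleus"),
                       name = c("root", "outer shell", "shell 3", "shell 2",
                                "core shell", "deep nucleus"),
                       parent_id = c(NA, 99, 99, 99, 99, 99)),
            ont_path, row.names = FALSE)
  poses <- list()
  truth <- list()
  set.seed(seed)
  aps <- seq(16, 32, length.out = n_sections)
  for (k in seq_len(n_sections)) {
    nm <- sprintf("s%02d.tif", k)
    pose <- slice_pose(runif(1, -3, 3), runif(1, -3, 3), aps[k])
    d <- deformation_spec(rotation_deg = runif(1, -4, 4),
                          translation_px = runif(2, -6, 6),
                          bspline_amplitude_px = 4, noise_sigma = 0.02,
                          seed = seed * 100 + k)
    md <- make_deformed_section(vol, pose, d, section_size = section_size)
    write_section_image(md$section$image, file.path(root, "images", nm),
                        normalize = TRUE)
    sig <- scatter_synthetic_cells(dim(md$section$image), n = 25,
                                   region_mask = md$section$labels > 0,
                                   radius_range_px = c(3, 5),
                                   seed = seed * 200 + k,
                                   min_spacing_px = 10)
    write_section_image(sig$image, file.path(root, "signal", nm),
                        normalize = TRUE)
    poses[[nm]] <- pose
    truth[[nm]] <- md
  }
  write_pose_file(poses, ap_max = ap_max(vol), file.path(root, "poses.json"))
  list(volume_intensity = vi, volume_labels = vl,
       images_dir = file.path(root, "images"),
       signal_dir = file.path(root, "signal"),
       ontology_path = ont_path,
       pose_file = file.path(root, "poses.json"),
       truth = truth)
}
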