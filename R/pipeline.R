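#' Experiment configuration
#'
#' Collects the paths and stage configurations of one experiment. Referenced
#' paths are validated at run time by [run_pipeline()], which reports the
#' offending field by name.
#'
#' @param volume_intensity,volume_labels volume files (NRRD or raw + JSON
#'   sidecar).
#' @param images_dir directory of counterstain section images (TIFF/PNG),
#'   processed in sorted name order.
#' @param signal_dir optional directory of signal-channel images with the
#'   same file names.
#' @param masks_dir optional directory of damage masks (PNG, nonzero =
#'   damaged) with the same file names.
#' @param ontology_path optional ontology CSV (id, acronym, name, parent_id).
#' @param pose_file optional pose JSON (the fine-tuning override format); if
#'   absent, poses are predicted with the template matcher and written to
#'   `<out_dir>/poses.json` for editing.
#' @param out_dir output root.
#' @param seed integer seed for any stochastic step.
#' @param signal_mode "ish" (signal dark on light background: invert,
#'   quantize to 8 bit, threshold) or "fluorescence" (signal bright:
#'   quantize, threshold).
#' @param pre_cfg,opt_cfg,tile_cfg stage configurations.
#' @return an object of class `experiment_config`.
#' @export
experiment_config <- function(volume_intensity, volume_labels, images_dir,
                              signal_dir = NULL, masks_dir = NULL,
                              ontology_path = NULL, pose_file = NULL,
                              out_dir, seed = 1,
                              signal_mode = c("ish", "fluorescence"),
                              pre_cfg = preprocess_config(),
                              opt_cfg = optimizer_config(),
                              tile_cfg = tiling_config()) {
  structure(list(volume_intensity = volume_intensity,
                 volume_labels = volume_labels,
                 images_dir = images_dir, signal_dir = signal_dir,
                 masks_dir = masks_dir, ontology_path = ontology_path,
                 pose_file = pose_file, out_dir = out_dir,
                 seed = as.integer(seed),
                 signal_mode = match.arg(signal_mode),
                 pre_cfg = pre_cfg, opt_cfg = opt_cfg, tile_cfg = tile_cfg),
            class = "experiment_config")
}

validate_config <- function(config) {
  need <- c("volume_intensity", "volume_labels", "images_dir")
  opt <- c("signal_dir", "masks_dir", "ontology_path", "pose_file")
  for (f in need) {
    p <- config[[f]]
    if (is.null(p) || !file.exists(p))
      stop(sprintf("config field '%s' does not point to an existing path (%s)",
                   f, if (is.null(p)) "NULL" else p))
  }
  for (f in opt) {
    p <- config[[f]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("config field '%s' does not point to an existing path (%s)",
                   f, p))
  }
  invisible(TRUE)
}

config_hash <- function(config) {
  keep <- config[setdiff(names(config), c("pre_cfg", "opt_cfg", "tile_cfg"))]
  keep$pre <- unclass(config$pre_cfg)
  keep$opt <- unclass(config$opt_cfg)
  keep$tile <- unclass(config$tile_cfg)
  js <- jsonlite::toJSON(keep, auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(js), f)
  unname(tools::md5sum(f))
}

signal_mask_from_image <- function(img, mode, threshold) {
  q <- invert_quantize(img)
  if (mode == "fluorescence") q <- 255L - q
  threshold_signal(q, threshold)
}

log_line <- function(con, stage, section, ...) {
  kv <- list(...)
  extra <- if (length(kv))
    paste(sprintf("%s=%s", names(kv), vapply(kv, format, character(1))),
          collapse = " ")
  else ""
  line <- sprintf("stage=%s section=%s %s", stage, section, extra)
  if (!is.null(con)) writeLines(line, con)
  message(line)
}

#' Run the full pipeline on one experiment
#'
#' Executes the four-step workflow: predict (or load) per-section poses,
#' slice the atlas and register each section (affine + B-spline composite),
#' detect signals, and integrate (per-region pixel proportions and cell
#' counts, alignment quality metrics). Writes, under `out_dir`: `poses.json`,
#' `transforms/<name>.json`, `labels/<name>.tif` (warped annotations),
#' `atlas/<name>.tif` (warped atlas image), `detections/<name>.csv`,
#' `regions/<name>.csv`, `metrics.csv`, `regions_experiment.csv`, `run.log`
#' and `manifest.json` (package version, config hash, seed, per-section
#' status). Completed sections are skipped on re-runs unless `force = TRUE`.
#' Sections are processed independently; a failing section is recorded and
#' skipped, and the run exit status is nonzero only when every section fails
#' or the configuration is invalid.
#'
#' @param config an [experiment_config()].
#' @param force recompute sections whose outputs already exist.
#' @return list with `status` (0 = at least one section succeeded), and
#'   `manifest`.
#' @export
run_pipeline <- function(config, force = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  validate_config(config)
  out <- config$out_dir
  for (d in c("", "transforms", "labels", "atlas", "detections", "regions"))
    dir.create(file.path(out, d), showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(out, "run.log"), "a")
  on.exit(close(logf))

  volume <- read_volume(config$volume_intensity, config$volume_labels)
  apmx <- ap_max(volume)
  files <- sort(list.files(config$images_dir, "\\.(tif|tiff|png)$",
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no section images found in 'images_dir'")
  ont <- if (is.null(config$ontology_path)) NULL
         else read_ontology(config$ontology_path)

  # --- poses: load the override file if present, else predict ---------------
  pose_path <- config$pose_file %||% file.path(out, "poses.json")
  if (file.exists(pose_path)) {
    pf <- read_pose_file(pose_path)
    poses <- pf$poses
    log_line(logf, "predict", "*", source = "pose_file", n = length(poses))
  } else {
    imgs <- lapply(files, function(f)
      read_section_image(file.path(config$images_dir, f)))
    names(imgs) <- files
    predictor <- pose_predictor_template(volume)
    poses <- predict_poses(imgs, predictor, apmx)
    write_pose_file(poses, apmx, pose_path)
    log_line(logf, "predict", "*", source = "template_matcher", n = length(poses))
  }

  statuses <- character(0)
  metrics <- list()
  region_tabs <- list()
  for (f in files) {
    nm <- sub("\\.(tif|tiff|png)$", "", f, ignore.case = TRUE)
    outs <- c(transform = file.path(out, "transforms", paste0(nm, ".json")),
              labels = file.path(out, "labels", paste0(nm, ".tif")),
              atlas = file.path(out, "atlas", paste0(nm, ".tif")),
              regions = file.path(out, "regions", paste0(nm, ".csv")))
    if (!force && all(file.exists(outs))) {
      statuses[nm] <- "ok (cached)"
      log_line(logf, "align", nm, status = "cached")
      region_tabs[[nm]] <- read.csv(outs[["regions"]])
      next
    }
    statuses[nm] <- tryCatch({
      pose <- poses[[f]] %||% poses[[nm]]
      if (is.null(pose)) stop("no pose for section ", f)
      fixed_img <- read_section_image(file.path(config$images_dir, f))
      mask <- NULL
      if (!is.null(config$masks_dir)) {
        mp <- file.path(config$masks_dir, paste0(nm, ".png"))
        if (file.exists(mp)) mask <- read_section_image(mp) > 0.5
      }
      atl <- slice_volume(volume, pose)
      atl_rs <- section(image = resize_image(atl$image, nrow(fixed_img), ncol(fixed_img)),
                        labels = resize_image(atl$labels, nrow(fixed_img),
                                              ncol(fixed_img), method = "nearest"),
                        pose = pose, pixel_size_um = atl$pixel_size_um)
      reg <- register_composite(fixed_img, atl_rs, mask = mask,
                                pre_cfg = config$pre_cfg,
                                opt_cfg = config$opt_cfg)
      log_line(logf, "align", nm,
               affine_metric = signif(tail(reg$trace$affine[[length(reg$trace$affine)]], 1), 6),
               bspline_metric = signif(tail(reg$trace$bspline, 1), 6),
               bspline_iters = length(reg$trace$bspline))
      transform_to_json(reg$transform, outs[["transform"]])
      write_label_image(reg$warped_labels, outs[["labels"]])
      write_section_image(reg$warped_atlas, outs[["atlas"]])

      # detection + quantification
      det <- empty_detections()
      sig_mask <- matrix(FALSE, nrow(fixed_img), ncol(fixed_img))
      if (!is.null(config$signal_dir)) {
        sp <- file.path(config$signal_dir, f)
        if (file.exists(sp)) {
          sig <- read_section_image(sp)
          sig_mask <- signal_mask_from_image(sig, config$signal_mode,
                                             config$pre_cfg$ish_threshold)
          det <- tiled_detect(sig, default_blob_detector, config$tile_cfg)
          write_detections_csv(det, file.path(out, "detections",
                                              paste0(nm, ".csv")), section = nm)
          log_line(logf, "detect", nm, n = nrow(det),
                   failed_tiles = attr(det, "failed_tiles"))
        }
      }
      px <- count_pixels_by_region(sig_mask, reg$warped_labels, ont)
      cc <- assign_detections_to_regions(det, reg$warped_labels, ont)
      tab <- merge_region_tables(px, cc)
      write_region_table(tab, outs[["regions"]])
      region_tabs[[nm]] <- tab

      ev <- evaluate_alignment(reg$warped_labels, tissue_mask(fixed_img))
      metrics[[nm]] <- cbind(section = nm, ev)
      log_line(logf, "evaluate", nm, dice = signif(ev$dice, 4))
      "ok"
    }, error = function(e) {
      log_line(logf, "error", nm, message = conditionMessage(e))
      paste("error:", conditionMessage(e))
    })
  }

  if (length(metrics))
    write.csv(do.call(rbind, metrics), file.path(out, "metrics.csv"),
              row.names = FALSE)
  if (length(region_tabs)) {
    agg <- do.call(rbind, Map(function(nm, tb) cbind(section = nm, tb),
                              names(region_tabs), region_tabs))
    write.csv(agg, file.path(out, "regions_experiment.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "historeg",
    version = as.character(utils::packageVersion("historeg")),
    config_hash = config_hash(config),
    seed = config$seed,
    sections = as.list(statuses))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- grepl("^ok", unlist(statuses))
  list(status = if (any(ok)) 0L else 1L, manifest = manifest)
}
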