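#' Reference atlas volume
#'
#' Bundles a 3D intensity volume (e.g. an averaged Nissl template) with its
#' voxel-wise integer region annotation volume. Axis order is fixed as
#' (anterior -> posterior, dorsal -> ventral, left -> right), so
#' `intensity[k, , ]` is the perfectly coronal plane at anterior-posterior
#' index `k - 1` (poses use 0-based AP indices, matching the 0..ap_max
#' convention of digital coronal atlases).
#'
#' @param intensity 3D numeric array.
#' @param labels 3D array of non-negative integer region ids, same shape;
#'   0 is background.
#' @param voxel_size_um isotropic voxel size in micrometers (default 10).
#' @return an object of class `atlas_volume`.
#' @export
atlas_volume <- function(intensity, labels, voxel_size_um = 10) {
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("'intensity' must be a 3D array")
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array")
  if (!identical(dim(intensity), dim(labels)))
    stop("'intensity' and 'labels' must have identical shape")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("'labels' must contain non-negative integers")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L || voxel_size_um <= 0)
    stop("'voxel_size_um' must be a positive scalar")
  structure(
    list(intensity = intensity, labels = labels, voxel_size_um = voxel_size_um),
    class = "atlas_volume")
}

#' @export
print.atlas_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<atlas_volume> %d x %d x %d voxels (AP x DV x LR), %g um/voxel, %d regions\n",
              d[1], d[2], d[3], x$voxel_size_um,
              length(setdiff(unique(as.vector(x$labels)), 0))))
  invisible(x)
}

#' Oblique section pose
#'
#' Locates one oblique coronal section in the atlas: the x cut angle rotates
#' the slicing-plane normal from the anterior-posterior (AP) axis toward the
#' left-right axis (the "x-z plane"), the y cut angle toward the dorsal-
#' ventral axis (the "y-z plane"), applied in that order; `ap_index` is the
#' (possibly fractional, 0-based) position along the AP axis.
#'
#' @param x_angle_deg,y_angle_deg cut angles in degrees, each in \[-10, 10\].
#' @param ap_index anterior-posterior index in \[0, ap_max\].
#' @return an object of class `slice_pose`.
#' @export
slice_pose <- function(x_angle_deg = 0, y_angle_deg = 0, ap_index = 0) {
  structure(list(x_angle_deg = as.numeric(x_angle_deg),
                 y_angle_deg = as.numeric(y_angle_deg),
                 ap_index = as.numeric(ap_index)),
            class = "slice_pose")
}

#' @export
print.slice_pose <- function(x, ...) {
  cat(sprintf("<slice_pose> x = %+.3f deg, y = %+.3f deg, AP = %.2f\n",
              x$x_angle_deg, x$y_angle_deg, x$ap_index))
  invisible(x)
}

ANGLE_MIN <- -10
ANGLE_MAX <- 10

#' Normalize a section pose to the unit cube
#'
#' Affine bijection used to express cut angles and the AP position on a
#' common \[0, 1\] scale: angles map from \[-10, 10\] degrees via
#' `(angle + 10) / 20`; the AP index maps via `ap_index / ap_max` (0 the most
#' anterior, `ap_max` the most posterior coronal plane; 1324 for the 10 um
#' reference volume).
#'
#' @param pose a [slice_pose()].
#' @param ap_max maximum AP index (positive).
#' @return numeric triple `(x, y, z)` in \[0, 1\]^3.
#' @seealso [denormalize_pose()]
#' @export
normalize_pose <- function(pose, ap_max) {
  stopifnot(inherits(pose, "slice_pose"))
  if (!is.numeric(ap_max) || length(ap_max) != 1L || ap_max <= 0)
    stop("'ap_max' must be a positive scalar")
  for (f in c("x_angle_deg", "y_angle_deg")) {
    a <- pose[[f]]
    if (a < ANGLE_MIN || a > ANGLE_MAX)
      stop(sprintf("'%s' = %g is outside [%g, %g]", f, a, ANGLE_MIN, ANGLE_MAX))
  }
  if (pose$ap_index < 0 || pose$ap_index > ap_max)
    stop(sprintf("'ap_index' = %g is outside [0, %g]", pose$ap_index, ap_max))
  c(x = (pose$x_angle_deg - ANGLE_MIN) / (ANGLE_MAX - ANGLE_MIN),
    y = (pose$y_angle_deg - ANGLE_MIN) / (ANGLE_MAX - ANGLE_MIN),
    z = pose$ap_index / ap_max)
}

#' Invert [normalize_pose()]
#'
#' @param triple numeric triple in \[0, 1\]^3.
#' @param ap_max maximum AP index.
#' @return a [slice_pose()].
#' @export
denormalize_pose <- function(triple, ap_max) {
  if (length(triple) != 3L || any(triple < -1e-12) || any(triple > 1 + 1e-12))
    stop("'triple' must be three values in [0, 1]")
  slice_pose(x_angle_deg = triple[[1]] * (ANGLE_MAX - ANGLE_MIN) + ANGLE_MIN,
             y_angle_deg = triple[[2]] * (ANGLE_MAX - ANGLE_MIN) + ANGLE_MIN,
             ap_index = triple[[3]] * ap_max)
}

#' Maximum AP index of a volume
#' @param volume an [atlas_volume()].
#' @return `dim(volume)[1] - 1` (0-based indexing).
#' @export
ap_max <- function(volume) {
  stopifnot(inherits(volume, "atlas_volume"))
  dim(volume$intensity)[1] - 1L
}

# in-plane/normal basis of the oblique plane for a pose, in (AP, DV, LR)
# vector components
pose_basis <- function(pose) {
  tx <- pose$x_angle_deg * pi / 180
  ty <- pose$y_angle_deg * pi / 180
  # normal: AP axis rotated toward LR by tx (x-z plane), then toward DV by ty
  n <- c(cos(tx) * cos(ty), cos(tx) * sin(ty), sin(tx))
  u <- c(-sin(tx) * cos(ty), -sin(tx) * sin(ty), cos(tx)) # section columns (~LR)
  v <- c(-sin(ty), cos(ty), 0)                            # section rows (~DV)
  list(n = n, u = u, v = v)
}

#' Extract an oblique coronal section from a volume
#'
#' Samples the plane through the point (`ap_index`, volume center, volume
#' center) whose normal is the AP axis rotated by the pose's x then y cut
#' angles. Intensity is sampled with trilinear interpolation, labels with
#' nearest-neighbor; samples falling outside the volume are filled with 0
#' (background). The section pixel grid spacing equals the voxel size, and
#' the rotation pivots at the section's center point on the AP axis.
#'
#' @param volume an [atlas_volume()].
#' @param pose a [slice_pose()]; fractional `ap_index` is allowed.
#' @param with_labels also slice the annotation volume (default TRUE).
#' @return a `section`: list with `image`, `labels` (or NULL), `pose`,
#'   `pixel_size_um`, `channel`.
#' @export
slice_volume <- function(volume, pose, with_labels = TRUE) {
  stopifnot(inherits(volume, "atlas_volume"), inherits(pose, "slice_pose"))
  d <- dim(volume$intensity)
  if (pose$ap_index < 0 || pose$ap_index > d[1] - 1)
    stop(sprintf("'ap_index' = %g is outside the volume AP range [0, %d]",
                 pose$ap_index, d[1] - 1L))
  b <- pose_basis(pose)
  img <- slice_volume_cpp(volume$intensity, pose$ap_index, b$u, b$v, 0L)
  labs <- NULL
  if (with_labels) {
    labs <- slice_volume_cpp(volume$labels, pose$ap_index, b$u, b$v, 1L)
    storage.mode(labs) <- "integer"
  }
  section(image = img, labels = labs, pose = pose,
          pixel_size_um = volume$voxel_size_um, channel = "counterstain")
}

#' 2D tissue section
#'
#' @param image 2D numeric matrix.
#' @param labels optional 2D integer label matrix, same shape.
#' @param pose optional [slice_pose()].
#' @param pixel_size_um pixel size in micrometers.
#' @param channel "counterstain" or "signal".
#' @return an object of class `section`.
#' @export
section <- function(image, labels = NULL, pose = NULL, pixel_size_um = 10,
                    channel = c("counterstain", "signal")) {
  stopifnot_image(image)
  channel <- match.arg(channel)
  if (!is.null(labels) && !identical(dim(labels), dim(image)))
    stop("'labels' must have the same shape as 'image'")
  structure(list(image = image, labels = labels, pose = pose,
                 pixel_size_um = pixel_size_um, channel = channel),
            class = "section")
}

#' @export
print.section <- function(x, ...) {
  cat(sprintf("<section> %d x %d px (%s channel)%s\n", nrow(x$image),
              ncol(x$image), x$channel,
              if (is.null(x$labels)) "" else ", with labels"))
  invisible(x)
}

#' Average the cut angles of several poses
#'
#' Sections from one brain share the blockface cut angles, so per-section
#' angle estimates are pooled by their arithmetic mean and re-applied to every
#' section while keeping each section's own AP index.
#'
#' @param poses non-empty list of [slice_pose()] objects.
#' @return named numeric `c(x_angle_deg, y_angle_deg)`.
#' @export
average_pose_angles <- function(poses) {
  if (length(poses) == 0L) stop("'poses' must be a non-empty list")
  c(x_angle_deg = mean(vapply(poses, function(p) p$x_angle_deg, numeric(1))),
    y_angle_deg = mean(vapply(poses, function(p) p$y_angle_deg, numeric(1))))
}

#' Apply shared average angles to a pose list
#'
#' @param poses list of [slice_pose()].
#' @return the pose list with every pose's angles replaced by the means.
#' @export
apply_average_angles <- function(poses) {
  ang <- average_pose_angles(poses)
  lapply(poses, function(p)
    slice_pose(ang[["x_angle_deg"]], ang[["y_angle_deg"]], p$ap_index))
}

#' Generate pose-labeled training samples by random slicing
#'
#' Draws poses uniformly (angles in \[-10, 10\] degrees, AP index in
#' \[0, ap_max\]), slices the volume, crops to a single randomly chosen
#' hemisphere with probability 0.5 (left/right equiprobable, mirroring how
#' experimental sections may carry one or both hemispheres), and resizes each
#' image to `size x size` (default 256). Deterministic for a given seed.
#'
#' @param volume an [atlas_volume()].
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @param size output image side length (default 256).
#' @return list of `n` elements, each `list(image, pose_normalized, pose,
#'   hemisphere)` with `hemisphere` one of "both", "left", "right".
#' @export
generate_training_samples <- function(volume, n, seed, size = 256L) {
  stopifnot(inherits(volume, "atlas_volume"))
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop("'n' must be >= 1")
  n <- as.integer(n)
  apmx <- ap_max(volume)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      pose <- slice_pose(runif(1, ANGLE_MIN, ANGLE_MAX),
                         runif(1, ANGLE_MIN, ANGLE_MAX),
                         runif(1, 0, apmx))
      sec <- slice_volume(volume, pose, with_labels = FALSE)
      img <- sec$image
      hemi <- "both"
      if (runif(1) < 0.5) {
        w <- ncol(img)
        half <- w %/% 2L
        if (runif(1) < 0.5) {
          hemi <- "left";  img <- img[, seq_len(half), drop = FALSE]
        } else {
          hemi <- "right"; img <- img[, (w - half + 1L):w, drop = FALSE]
        }
      }
      img <- resize_image(img, size, size)
      list(image = img, pose_normalized = normalize_pose(pose, apmx),
           pose = pose, hemisphere = hemi)
    })
  })
}
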