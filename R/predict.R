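#' Pose predictors
#'
#' A pose predictor is any callable mapping a 256 x 256 section image to a
#' normalized pose triple in \[0, 1\]^3 (see [normalize_pose()]). The trained
#' network this interface models is pluggable: the package ships a constant
#' stub (testing, or "start from the middle") and a weights-free
#' nearest-template matcher. Predictions are starting points; users fine-tune
#' them per section via the pose file.
#'
#' @name pose_predictor
NULL

#' Constant pose predictor
#'
#' Always predicts the same normalized triple (default the volume midpoint).
#'
#' @param triple normalized pose returned for every image.
#' @return a predictor function(image) -> normalized triple.
#' @export
pose_predictor_constant <- function(triple = c(0.5, 0.5, 0.5)) {
  force(triple)
  function(image) triple
}

#' Nearest-template pose predictor
#'
#' Weights-free default predictor: the volume is sliced at `n_templates`
#' evenly spaced AP positions (zero cut angles), every template and query
#' image is reduced to a small Sobel-gradient thumbnail, and the query is
#' assigned the AP position of the template with the highest global
#' normalized cross-correlation. Cut angles are predicted as 0 degrees
#' (normalized 0.5); angle refinement is left to user fine-tuning.
#'
#' @param volume an [atlas_volume()].
#' @param n_templates number of evenly spaced templates (default 32).
#' @param thumb_size thumbnail side length (default 64).
#' @return a predictor function(image) -> normalized triple.
#' @export
pose_predictor_template <- function(volume, n_templates = 32, thumb_size = 64) {
  stopifnot(inherits(volume, "atlas_volume"))
  apmx <- ap_max(volume)
  aps <- seq(0, apmx, length.out = n_templates)
  thumb <- function(img) {
    g <- to_gradient(resize_image(img, thumb_size, thumb_size))
    g - mean(g)
  }
  templates <- lapply(aps, function(ap) {
    thumb(slice_volume(volume, slice_pose(0, 0, ap), with_labels = FALSE)$image)
  })
  function(image) {
    q <- thumb(image)
    qn <- sqrt(sum(q^2))
    score <- vapply(templates, function(tm) {
      tn <- sqrt(sum(tm^2))
      if (qn == 0 || tn == 0) return(-Inf)
      sum(q * tm) / (qn * tn)
    }, numeric(1))
    c(0.5, 0.5, aps[which.max(score)] / apmx)
  }
}

#' Predict poses for a set of section images
#'
#' Applies a pose predictor to each image, denormalizes, then pools the cut
#' angles: the per-section x and y angle estimates are averaged and the means
#' re-applied to every section (sections from one brain share the blockface
#' angles), keeping each section's own AP index.
#'
#' @param images named list of 2D matrices (names become pose-file entries).
#' @param predictor a predictor function (see [pose_predictor]).
#' @param ap_max maximum AP index used for denormalization.
#' @param average_angles pool angles across sections (default TRUE).
#' @return named list of [slice_pose()].
#' @export
predict_poses <- function(images, predictor, ap_max, average_angles = TRUE) {
  poses <- lapply(images, function(img) {
    img256 <- resize_image(img, 256, 256)
    denormalize_pose(predictor(img256), ap_max)
  })
  if (average_angles && length(poses) > 1L) poses_out <- apply_average_angles(poses)
  else poses_out <- poses
  names(poses_out) <- names(images)
  poses_out
}
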