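#' Dice similarity coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)` between two binary masks. Two empty
#' masks overlap perfectly by convention and score 1.0.
#'
#' @param a,b equal-shape logical (or 0/1) matrices.
#' @return scalar in \[0, 1\].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must have equal shape")
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1.0)
  2 * sum(a & b) / denom
}

#' Per-region mean Dice between two label images
#'
#' Mean of the per-id Dice over the union of nonzero ids present in either
#' image.
#'
#' @param a,b equal-shape integer label matrices.
#' @return scalar in \[0, 1\].
#' @export
label_dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("label images must have equal shape")
  ids <- setdiff(union(unique(as.vector(a)), unique(as.vector(b))), 0)
  if (length(ids) == 0L) return(1.0)
  mean(vapply(ids, function(k) dice(a == k, b == k), numeric(1)))
}

#' Boundary-pixel contour of a mask
#'
#' A boundary pixel is a foreground pixel 4-adjacent to background (pixels on
#' the image border count their outside neighbors as background). Returned as
#' an (x, y) point matrix in 1-based pixel-center coordinates; empty mask ->
#' zero rows.
#'
#' @param mask logical matrix.
#' @return two-column matrix `(x, y)`.
#' @export
mask_contour <- function(mask) {
  m <- mask > 0
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- m
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
        pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  b <- which(core & !nb, arr.ind = TRUE)
  cbind(x = b[, 2], y = b[, 1])
}

#' Directed Hausdorff distance between point sets
#'
#' `max over p in a of (min over q in b of ||p - q||)`; generally asymmetric.
#'
#' @param a,b non-empty two-column point matrices `(x, y)`.
#' @return distance in pixels.
#' @export
directed_hausdorff <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("point sets must be non-empty")
  directed_hausdorff_cpp(a, b)
}

#' Centroid distance between two masks
#'
#' Euclidean distance between the foreground-pixel mean coordinates.
#'
#' @param a,b non-empty logical matrices.
#' @return distance in pixels.
#' @export
centroid_distance <- function(a, b) {
  a <- a > 0; b <- b > 0
  if (!any(a) || !any(b)) stop("masks must be non-empty")
  ca <- colMeans(which(a, arr.ind = TRUE))
  cb <- colMeans(which(b, arr.ind = TRUE))
  sqrt(sum((ca - cb)^2))
}

#' Pearson correlation between two count vectors
#'
#' @param counts_a,counts_b equal-length numeric vectors, n >= 3.
#' @return list with `r` and two-sided `p`.
#' @export
count_correlation <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) stop("vectors must have equal length")
  if (length(counts_a) < 3L) stop("need at least 3 pairs")
  if (sd(counts_a) == 0 || sd(counts_b) == 0)
    stop("zero variance in a count vector")
  ct <- cor.test(counts_a, counts_b, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Tissue foreground mask of an intensity image
#'
#' Foreground = intensity above the Otsu threshold; the default foreground
#' definition for whole-tissue Dice/contour/centroid comparisons of aligned
#' sections (warped annotations use `label > 0` instead).
#'
#' @param image 2D numeric matrix.
#' @return logical matrix.
#' @export
tissue_mask <- function(image) {
  image > otsu_threshold(image)
}

#' Alignment-quality metrics for one section
#'
#' Dice, directed Hausdorff distance between boundary contours (both
#' directions), and centroid distance between a predicted and a reference
#' mask.
#'
#' @param pred,truth logical masks (or label images, compared as `> 0`).
#' @return one-row data.frame `dice, hausdorff, hausdorff_rev,
#'   centroid_distance`.
#' @export
evaluate_alignment <- function(pred, truth) {
  pm <- pred > 0; tm <- truth > 0
  cp <- mask_contour(pm); ct <- mask_contour(tm)
  data.frame(
    dice = dice(pm, tm),
    hausdorff = if (nrow(cp) && nrow(ct)) directed_hausdorff(cp, ct) else NA_real_,
    hausdorff_rev = if (nrow(cp) && nrow(ct)) directed_hausdorff(ct, cp) else NA_real_,
    centroid_distance = if (any(pm) && any(tm)) centroid_distance(pm, tm) else NA_real_)
}
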