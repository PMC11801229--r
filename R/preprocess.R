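#' Preprocessing configuration
#'
#' The conditioning chain applied before registration, with defaults matching
#' the pipeline's standard working geometry: both images are resized to a
#' square working size of 360 px, converted to Sobel gradient-magnitude
#' images, min-max normalized, padded by 50 px of zeros to mitigate boundary
#' effects, and the moving gradient image is histogram-matched onto the fixed
#' one (1024 histogram levels, 10 match points, modifying only pixels above
#' the moving image's mean). The ISH chain inverts, quantizes to 8 bit and
#' thresholds at 125.
#'
#' @param pad_px zero-padding margin (pixels).
#' @param working_size square working side length (pixels).
#' @param hist_levels histogram levels for matching.
#' @param hist_match_points equally spaced quantile match points.
#' @param threshold_at_mean modify only above-mean pixels when matching.
#' @param ish_threshold 8-bit threshold for ISH signal masks.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(pad_px = 50, working_size = 360,
                              hist_levels = 1024, hist_match_points = 10,
                              threshold_at_mean = TRUE, ish_threshold = 125) {
  vals <- c(pad_px = pad_px, working_size = working_size,
            hist_levels = hist_levels, hist_match_points = hist_match_points,
            ish_threshold = ish_threshold)
  if (any(vals < 0) || working_size < 1 || hist_levels < 2 || hist_match_points < 2)
    stop("preprocess_config values must be positive")
  structure(list(pad_px = as.integer(pad_px),
                 working_size = as.integer(working_size),
                 hist_levels = as.integer(hist_levels),
                 hist_match_points = as.integer(hist_match_points),
                 threshold_at_mean = isTRUE(threshold_at_mean),
                 ish_threshold = ish_threshold),
            class = "preprocess_config")
}

#' Zero-pad an image
#'
#' @param image 2D numeric matrix.
#' @param pad_px margin added on all four sides (pad value 0).
#' @return padded matrix, `2 * pad_px` larger per axis, stored as double.
#' @export
pad_image <- function(image, pad_px) {
  stopifnot_image(image)
  p <- as.integer(pad_px)
  if (p < 0) stop("'pad_px' must be >= 0")
  if (p == 0) return(image + 0)
  out <- matrix(0, nrow(image) + 2L * p, ncol(image) + 2L * p)
  out[(p + 1L):(p + nrow(image)), (p + 1L):(p + ncol(image))] <- image
  out
}

#' Pad a fixed/moving image pair
#'
#' Extends both images by a uniform zero margin on all sides to mitigate
#' boundary effects during registration; both are returned in floating-point
#' form.
#'
#' @param fixed,moving 2D numeric matrices.
#' @param pad_px margin in pixels (default 50).
#' @return list `fixed`, `moving` of padded matrices.
#' @export
pad_pair <- function(fixed, moving, pad_px = 50) {
  list(fixed = pad_image(fixed, pad_px), moving = pad_image(moving, pad_px))
}

#' Sobel gradient-magnitude image, min-max normalized
#'
#' Per-pixel `sqrt(Gx^2 + Gy^2)` from the 3x3 Sobel operators (replicated
#' borders), then min-max normalized to \[0, 1\] so gradient images from
#' different sources share a common scale. A constant input yields an
#' all-zero output.
#'
#' @param image 2D numeric matrix.
#' @return gradient-magnitude matrix in \[0, 1\].
#' @export
to_gradient <- function(image) {
  stopifnot_image(image)
  g <- sobel_cpp(image)
  r <- max(g) - min(g)
  if (r <= 0) return(matrix(0, nrow(g), ncol(g)))
  (g - min(g)) / r
}

#' Histogram-match a moving image onto a fixed image
#'
#' Piecewise-linear intensity remap built from quantile correspondence at
#' `hist_match_points` equally spaced quantiles computed over `hist_levels`
#' histogram bins. With `threshold_at_mean` on, quantiles are estimated from
#' (and the remap applied to) only the pixels above the moving image's mean
#' intensity, preserving the lower intensity range (background) untouched.
#'
#' @param moving,fixed 2D numeric matrices.
#' @param cfg a [preprocess_config()].
#' @return the remapped moving image.
#' @export
match_histogram <- function(moving, fixed, cfg = preprocess_config()) {
  stopifnot_image(moving); stopifnot_image(fixed)
  if (length(moving) == 0L || length(fixed) == 0L) stop("empty image")
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("images must be finite")
  mv <- as.vector(moving); fv <- as.vector(fixed)
  sel_m <- rep(TRUE, length(mv)); sel_f <- rep(TRUE, length(fv))
  if (cfg$threshold_at_mean) {
    sel_m <- mv > mean(mv)
    sel_f <- fv > mean(fv)
  }
  if (!any(sel_m) || !any(sel_f)) return(moving + 0)
  qs <- seq(0, 1, length.out = cfg$hist_match_points)
  # quantiles from a binned (hist_levels) representation of each image
  qm <- binned_quantiles(mv[sel_m], qs, cfg$hist_levels)
  qf <- binned_quantiles(fv[sel_f], qs, cfg$hist_levels)
  out <- mv
  out[sel_m] <- piecewise_map(mv[sel_m], qm, qf)
  matrix(out, nrow(moving), ncol(moving))
}

# quantiles of x computed from an nbins-level histogram (midpoint convention)
binned_quantiles <- function(x, probs, nbins) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(rep(lo, length(probs)))
  b <- pmin(as.integer((x - lo) / (hi - lo) * nbins), nbins - 1L)
  cdf <- cumsum(tabulate(b + 1L, nbins)) / length(x)
  vapply(probs, function(p) {
    k <- which(cdf >= p - 1e-12)[1]
    if (is.na(k)) k <- nbins
    lo + (k - 0.5) / nbins * (hi - lo)
  }, numeric(1))
}

# monotone piecewise-linear map through (src_i, dst_i)
piecewise_map <- function(x, src, dst) {
  o <- order(src)
  src <- src[o]; dst <- dst[o]
  keep <- c(TRUE, diff(src) > 1e-300)
  src <- src[keep]; dst <- dst[keep]
  if (length(src) < 2L) return(x + (dst[1] - src[1]))
  stats::approx(src, dst, xout = x, rule = 2)$y
}

#' Invert and quantize an image to 8 bit
#'
#' `round(255 * (1 - (x - min) / (max - min)))` with round-half-even
#' (banker's) rounding; a constant input maps to all 255. This is the first
#' step of the ISH signal chain, where signal is dark on a light background.
#'
#' @param image 2D numeric matrix.
#' @return integer matrix with values in 0..255.
#' @export
invert_quantize <- function(image) {
  stopifnot_image(image)
  r <- max(image) - min(image)
  if (r <= 0) return(matrix(255L, nrow(image), ncol(image)))
  out <- round(255 * (1 - (image - min(image)) / r))
  matrix(as.integer(out), nrow(image), ncol(image))
}

#' Threshold an 8-bit signal image into a binary mask
#'
#' Strict inequality: a pixel belongs to the mask iff its value is `> t`.
#'
#' @param image8 matrix of 8-bit values (0..255).
#' @param t threshold (default 125).
#' @return logical matrix.
#' @export
threshold_signal <- function(image8, t = 125) {
  if (!is.matrix(image8)) stop("'image8' must be a matrix")
  if (any(image8 < 0 | image8 > 255)) stop("'image8' must hold 8-bit values")
  image8 > t
}
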