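#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' caller's RNG state, so no package operation leaks randomness into (or
#' depends on) the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a 2D numeric matrix", name))
  invisible(x)
}

#' Resize an image
#'
#' Area-averaging when shrinking and bilinear (pixel-center aligned)
#' interpolation when enlarging, applied separably per axis. `method =
#' "nearest"` uses nearest-neighbor sampling and is mandatory for label
#' images.
#'
#' @param image 2D numeric matrix.
#' @param height,width output extents in pixels.
#' @param method "auto" (area/bilinear) or "nearest".
#' @return resized matrix.
#' @export
resize_image <- function(image, height, width, method = c("auto", "nearest")) {
  stopifnot_image(image)
  method <- match.arg(method)
  if (height < 1 || width < 1) stop("output extents must be positive")
  if (method == "nearest") resize_nearest_cpp(image, as.integer(height), as.integer(width))
  else resize_image_cpp(image, as.integer(height), as.integer(width))
}

#' Gaussian blur
#'
#' Separable Gaussian smoothing with mirrored borders; `sigma <= 0` returns
#' the input unchanged. Accepts 2D matrices or 3D arrays.
#'
#' @param x matrix or 3D array.
#' @param sigma standard deviation in pixels/voxels.
#' @return blurred object of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  if (is.matrix(x)) return(gaussian_blur_cpp(x, sigma))
  if (is.array(x) && length(dim(x)) == 3L) return(gaussian_blur3d_cpp(x, sigma))
  stop("'x' must be a matrix or a 3D array")
}

#' Otsu threshold of a grayscale image
#'
#' Classic between-class-variance maximization over a 256-bin histogram of the
#' min-max normalized image; returns the threshold on the original intensity
#' scale. Used to derive whole-tissue foreground masks.
#'
#' @param image 2D numeric matrix.
#' @return scalar threshold; pixels `> threshold` are foreground.
#' @export
otsu_threshold <- function(image) {
  stopifnot_image(image)
  v <- as.vector(image)
  v <- v[is.finite(v)]
  if (length(v) == 0L) stop("image has no finite pixels")
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)
  nb <- 256L
  b <- pmin(as.integer((v - lo) / (hi - lo) * nb), nb - 1L)
  h <- tabulate(b + 1L, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nb) - 1))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b) - 1L
  lo + (k + 0.5) / nb * (hi - lo)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
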