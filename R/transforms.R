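#' Affine transform (push-forward, moving -> fixed)
#'
#' A point `x` in moving-image coordinates lands at `A (x - center) + center +
#' b` in fixed-image coordinates; resampling evaluates the closed-form
#' inverse. Coordinates are (x, y) = (column, row) with 0-based pixel centers.
#'
#' @param A 2x2 matrix with nonzero determinant.
#' @param b length-2 translation (pixels).
#' @param center length-2 rotation center (fixed-image frame).
#' @return an object of class `affine_transform`.
#' @export
affine_transform <- function(A = diag(2), b = c(0, 0), center = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < .Machine$double.eps) stop("det(A) must be nonzero")
  structure(list(A = A, b = as.numeric(b), center = as.numeric(center)),
            class = "affine_transform")
}

#' B-spline transform (pull-back free-form deformation)
#'
#' Cubic B-spline displacement field `u(x) = sum_i P_i B_i(x)` over a
#' `mesh[1] x mesh[2]`-cell control grid spanning the image domain; control
#' matrices carry the cubic boundary padding, i.e. `(mesh + 3)` points per
#' axis. Resampling evaluates `out(x) = in(x + u(x))`: the stored
#' displacements are sampling offsets in the target (fixed) frame.
#'
#' @param mesh c(cells_x, cells_y), each >= 2.
#' @param Px,Py control-point displacement matrices, `(mesh[2] + 3) x
#'   (mesh[1] + 3)`, x- and y-components in pixels.
#' @param domain c(height, width) of the image frame the field is defined on.
#' @return an object of class `bspline_transform`.
#' @export
bspline_transform <- function(mesh = c(4, 4), Px = NULL, Py = NULL,
                              domain = NULL) {
  mesh <- as.integer(mesh)
  if (length(mesh) != 2L || any(mesh < 2)) stop("'mesh' must be >= 2 cells per axis")
  gdim <- c(mesh[2] + 3L, mesh[1] + 3L)
  if (is.null(Px)) Px <- matrix(0, gdim[1], gdim[2])
  if (is.null(Py)) Py <- matrix(0, gdim[1], gdim[2])
  if (!identical(dim(Px), gdim) || !identical(dim(Py), gdim))
    stop(sprintf("control matrices must be %d x %d", gdim[1], gdim[2]))
  if (is.null(domain) || length(domain) != 2L)
    stop("'domain' must be c(height, width)")
  structure(list(mesh = mesh, Px = Px, Py = Py, domain = as.integer(domain)),
            class = "bspline_transform")
}

#' Composite transform: affine stage then B-spline stage
#'
#' Application order follows the registration: the image is first resampled
#' through the affine stage, then the B-spline displacement field is applied
#' to the affine-resampled image.
#'
#' @param affine an [affine_transform()].
#' @param bspline a [bspline_transform()] (NULL for affine-only composites).
#' @param meta optional list of working-frame metadata (`working_size`,
#'   `pad_px`, `native_size`) attached by [register_composite()].
#' @return an object of class `composite_transform`.
#' @export
composite_transform <- function(affine, bspline = NULL, meta = NULL) {
  stopifnot(inherits(affine, "affine_transform"))
  if (!is.null(bspline)) stopifnot(inherits(bspline, "bspline_transform"))
  structure(list(affine = affine, bspline = bspline, meta = meta),
            class = "composite_transform")
}

#' @export
print.composite_transform <- function(x, ...) {
  cat("<composite_transform>\n  affine A =",
      paste(sprintf("%.4f", t(x$affine$A)), collapse = " "),
      sprintf("\n  b = (%.2f, %.2f)", x$affine$b[1], x$affine$b[2]), "\n")
  if (!is.null(x$bspline))
    cat(sprintf("  bspline %dx%d mesh, max |cp| = %.2f px\n",
                x$bspline$mesh[1], x$bspline$mesh[2],
                max(abs(c(x$bspline$Px, x$bspline$Py)))))
  invisible(x)
}

#' Dense displacement field of a B-spline transform
#'
#' @param t a [bspline_transform()].
#' @return list of matrices `ux`, `uy` over the transform's domain.
#' @export
bspline_displacement <- function(t) {
  stopifnot(inherits(t, "bspline_transform"))
  bspline_displacement_cpp(t$Px, t$Py, t$mesh[1], t$mesh[2],
                           t$domain[1], t$domain[2])
}

#' Apply a transform to an image
#'
#' Resamples `image` through an affine, B-spline or composite transform.
#' Out-of-domain samples are filled with 0; `interpolation = "nearest"` is
#' mandatory for label images so no label ids are invented.
#'
#' @param image 2D numeric matrix whose extents match the transform domain.
#' @param t an [affine_transform()], [bspline_transform()] or
#'   [composite_transform()].
#' @param interpolation "linear" or "nearest".
#' @return the resampled matrix (same extents as the input).
#' @export
apply_transform <- function(image, t, interpolation = c("linear", "nearest")) {
  stopifnot_image(image)
  interpolation <- match.arg(interpolation)
  code <- if (interpolation == "nearest") 1L else 0L
  if (inherits(t, "affine_transform")) {
    return(affine_resample_cpp(image, t$A[1, 1], t$A[1, 2], t$A[2, 1], t$A[2, 2],
                               t$b[1], t$b[2], t$center[1], t$center[2],
                               code, nrow(image), ncol(image)))
  }
  if (inherits(t, "bspline_transform")) {
    if (!identical(dim(image), t$domain))
      stop(sprintf("image is %d x %d but the transform domain is %d x %d",
                   nrow(image), ncol(image), t$domain[1], t$domain[2]))
    return(bspline_resample_cpp(image, t$Px, t$Py, t$mesh[1], t$mesh[2], code))
  }
  if (inherits(t, "composite_transform")) {
    out <- apply_transform(image, t$affine, interpolation)
    if (!is.null(t$bspline)) out <- apply_transform(out, t$bspline, interpolation)
    return(out)
  }
  stop("'t' must be an affine, bspline or composite transform")
}

#' Serialize a composite transform to JSON
#'
#' Doubles are written with 17 significant digits, which round-trips IEEE
#' doubles exactly.
#'
#' @param t a [composite_transform()].
#' @param path optional output file; if NULL the JSON string is returned.
#' @return `path` (invisibly) or the JSON string.
#' @export
transform_to_json <- function(t, path = NULL) {
  stopifnot(inherits(t, "composite_transform"))
  obj <- list(
    affine = list(A = t$affine$A, b = t$affine$b, center = t$affine$center),
    bspline = if (is.null(t$bspline)) NULL else
      list(mesh = t$bspline$mesh, Px = t$bspline$Px, Py = t$bspline$Py,
           domain = t$bspline$domain),
    meta = t$meta)
  js <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = FALSE, null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Deserialize a composite transform from JSON
#'
#' @param x a file path or a JSON string produced by [transform_to_json()].
#' @return a [composite_transform()].
#' @export
transform_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x, simplifyMatrix = TRUE)
  aff <- affine_transform(A = matrix(obj$affine$A, 2, 2), b = obj$affine$b,
                          center = obj$affine$center)
  bsp <- NULL
  if (!is.null(obj$bspline))
    bsp <- bspline_transform(mesh = obj$bspline$mesh,
                             Px = matrix(obj$bspline$Px,
                                         obj$bspline$mesh[2] + 3L,
                                         obj$bspline$mesh[1] + 3L),
                             Py = matrix(obj$bspline$Py,
                                         obj$bspline$mesh[2] + 3L,
                                         obj$bspline$mesh[1] + 3L),
                             domain = obj$bspline$domain)
  meta <- obj$meta
  if (!is.null(meta)) meta <- lapply(meta, function(v) unlist(v))
  composite_transform(affine = aff, bspline = bsp, meta = meta)
}
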