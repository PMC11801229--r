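#' Optimizer configuration for the two-stage registration
#'
#' Defaults follow the pipeline's standard schedule: gradient descent with a
#' learning rate of 0.01 for up to 300 iterations per stage, declaring
#' convergence when the metric's standard deviation over a 20-iteration
#' window falls below 1e-8; a 3-level multiresolution pyramid (shrink factors
#' 4, 2, 1 with Gaussian smoothing sigmas 2, 1, 0) for the affine stage;
#' Mattes mutual information with 32 histogram bins for the affine stage and
#' neighborhood correlation (radius 3 px) on a 4x4 B-spline mesh for the
#' deformable stage. The update rule is scaled gradient descent with
#' backtracking step relaxation: parameters are scaled so a unit step moves
#' image content by about one pixel, the initial step length is
#' `learning_rate * image width` pixels, an accepted step grows the length by
#' 1.2x and a rejected (metric-increasing) step is undone and halves it.
#'
#' @param learning_rate relative initial step (fraction of image width).
#' @param max_iterations per-stage iteration cap.
#' @param convergence_min_value metric-sd convergence tolerance.
#' @param convergence_window iterations in the convergence window.
#' @param shrink_factors,smoothing_sigmas multiresolution schedule (affine
#'   stage; equal lengths).
#' @param mi_bins Mattes MI histogram bins.
#' @param ncc_radius neighborhood-correlation window radius (px).
#' @param bspline_mesh control mesh cells per axis.
#' @param bspline_metric "ncc" (neighborhood correlation) or "mi".
#' @return an object of class `optimizer_config`.
#' @export
optimizer_config <- function(learning_rate = 0.01, max_iterations = 300,
                             convergence_min_value = 1e-8,
                             convergence_window = 20,
                             shrink_factors = c(4, 2, 1),
                             smoothing_sigmas = c(2, 1, 0),
                             mi_bins = 32, ncc_radius = 3,
                             bspline_mesh = c(4, 4),
                             bspline_metric = c("ncc", "mi")) {
  if (length(shrink_factors) != length(smoothing_sigmas))
    stop("'shrink_factors' and 'smoothing_sigmas' must have equal length")
  if (learning_rate <= 0 || max_iterations < 1 || convergence_window < 2 ||
      mi_bins < 2 || ncc_radius < 1)
    stop("optimizer_config values must be positive")
  structure(list(learning_rate = learning_rate,
                 max_iterations = as.integer(max_iterations),
                 convergence_min_value = convergence_min_value,
                 convergence_window = as.integer(convergence_window),
                 shrink_factors = as.integer(shrink_factors),
                 smoothing_sigmas = as.numeric(smoothing_sigmas),
                 mi_bins = as.integer(mi_bins),
                 ncc_radius = as.integer(ncc_radius),
                 bspline_mesh = as.integer(bspline_mesh),
                 bspline_metric = match.arg(bspline_metric)),
            class = "optimizer_config")
}

#' Mattes-style mutual information (negated)
#'
#' Mutual information of the fixed/moving intensity pair estimated from a
#' joint histogram with first-order (linear) Parzen smoothing over `bins`
#' bins per axis, returned negated so that lower = better fit. Masked-out
#' pixels contribute nothing; a constant image pair carries no information
#' and returns 0.
#'
#' @param fixed,moving equal-shape numeric matrices.
#' @param bins histogram bins (>= 2, default 32).
#' @param fixed_mask optional logical matrix; TRUE = use the pixel.
#' @return scalar, `-MI` in nats.
#' @export
mattes_mi <- function(fixed, moving, bins = 32, fixed_mask = NULL) {
  stopifnot_image(fixed); stopifnot_image(moving)
  if (!identical(dim(fixed), dim(moving))) stop("images must have equal shape")
  if (bins < 2) stop("'bins' must be >= 2")
  if (!is.null(fixed_mask) && !identical(dim(fixed_mask), dim(fixed)))
    stop("'fixed_mask' must match the image shape")
  mattes_mi_cpp(fixed, moving, as.integer(bins), fixed_mask)
}

#' Mean neighborhood correlation (negated)
#'
#' Mean over pixels of the Pearson correlation between fixed and moving
#' computed in a `(2 * radius + 1)^2` window (clipped at the border); windows
#' with zero variance in either image are excluded. Negated: a perfect match
#' scores -1.
#'
#' @param fixed,moving equal-shape numeric matrices.
#' @param radius window radius in pixels (>= 1).
#' @param fixed_mask optional logical matrix; TRUE = use the pixel.
#' @return scalar in \[-1, 1\].
#' @export
neighborhood_correlation <- function(fixed, moving, radius = 3,
                                     fixed_mask = NULL) {
  stopifnot_image(fixed); stopifnot_image(moving)
  if (!identical(dim(fixed), dim(moving))) stop("images must have equal shape")
  if (radius < 1) stop("'radius' must be >= 1")
  ncc_local_cpp(fixed, moving, as.integer(radius), fixed_mask)
}

#' Centered affine initialization
#'
#' Identity matrix with a translation moving the moving image's intensity
#' centroid onto the fixed image's (push-forward sense: `b = centroid(fixed)
#' - centroid(moving)`, so a moving image shifted +10 px yields b of -10 px).
#' An all-zero image falls back to its geometric center with a warning.
#'
#' @param fixed,moving 2D numeric matrices.
#' @return an [affine_transform()] centered on the fixed image center.
#' @export
init_centered_affine <- function(fixed, moving) {
  stopifnot_image(fixed); stopifnot_image(moving)
  centroid <- function(img, what) {
    w <- img - min(img)
    s <- sum(w)
    if (s <= 0) {
      warning(sprintf("%s image is constant; using its geometric center", what))
      return(c((ncol(img) - 1) / 2, (nrow(img) - 1) / 2))
    }
    xs <- matrix(rep(seq_len(ncol(img)) - 1, each = nrow(img)), nrow(img))
    ys <- matrix(rep(seq_len(nrow(img)) - 1, ncol(img)), nrow(img))
    c(sum(w * xs), sum(w * ys)) / s
  }
  cf <- centroid(fixed, "fixed"); cm <- centroid(moving, "moving")
  affine_transform(A = diag(2), b = cf - cm,
                   center = c((ncol(fixed) - 1) / 2, (nrow(fixed) - 1) / 2))
}

# scaled gradient descent with backtracking relaxation; returns list(par,
# trace). fn(par) -> metric value; gr(par) -> gradient (or NULL to use fn-only
# steps precomputed by caller). `scales` puts parameters on a ~1 px/unit scale.
descend <- function(par, fn, gr, scales, cfg, step_init, context) {
  val <- fn(par)
  if (!is.finite(val))
    stop(sprintf("non-finite metric at start of %s", context))
  trace <- val
  step <- step_init
  iter <- 0L
  done <- FALSE
  while (!done && iter < cfg$max_iterations) {
    iter <- iter + 1L
    g <- gr(par)                      # one gradient per accepted position
    gq <- g / scales
    gn <- sqrt(sum(gq^2))
    if (!is.finite(gn))
      stop(sprintf("non-finite gradient in %s at iteration %d", context, iter))
    if (gn < 1e-14) break
    dirn <- (gq / gn) / scales
    repeat {                          # step relaxation on metric increase
      cand <- par - step * dirn
      vnew <- fn(cand)
      if (!is.finite(vnew))
        stop(sprintf("non-finite metric in %s at iteration %d", context, iter))
      if (vnew < val) {
        par <- cand; val <- vnew
        step <- step * 1.2
        trace <- c(trace, val)
        if (length(trace) >= cfg$convergence_window &&
            sd(tail(trace, cfg$convergence_window)) < cfg$convergence_min_value)
          done <- TRUE
        break
      }
      step <- step / 2
      if (step < 1e-4) { done <- TRUE; break }
    }
  }
  list(par = par, value = val, trace = trace, iterations = iter)
}

# pyramid level geometry: images resized to ceil(dim / shrink) after Gaussian
# smoothing; returns level images plus the full<->level coordinate scaling
build_pyramid <- function(img, cfg, nearest = FALSE) {
  lapply(seq_along(cfg$shrink_factors), function(k) {
    s <- cfg$shrink_factors[k]; sg <- cfg$smoothing_sigmas[k]
    base <- if (sg > 0 && !nearest) gaussian_blur_cpp(img, sg) else img
    h <- ceiling(nrow(img) / s); w <- ceiling(ncol(img) / s)
    lvl <- if (nearest) resize_nearest_cpp(base, h, w)
           else resize_image_cpp(base, h, w)
    list(img = lvl, sx = ncol(img) / w, sy = nrow(img) / h)
  })
}

#' Fit the affine stage by Mattes MI gradient descent
#'
#' Minimizes the negated Mattes mutual information of the warped moving image
#' against the fixed image over the multiresolution pyramid, by scaled
#' gradient descent with central-finite-difference gradients (6 parameters).
#' Fully deterministic: the metric uses every pixel, with no stochastic
#' sampling.
#'
#' @param fixed,moving preprocessed (gradient, matched) equal-shape matrices.
#' @param cfg an [optimizer_config()].
#' @param fixed_mask optional logical matrix, TRUE = use the pixel.
#' @param init optional initial [affine_transform()]; default
#'   [init_centered_affine()].
#' @return an [affine_transform()] with attribute `trace` (per-level metric
#'   descent logs).
#' @export
fit_affine <- function(fixed, moving, cfg = optimizer_config(),
                       fixed_mask = NULL, init = NULL) {
  stopifnot_image(fixed); stopifnot_image(moving)
  if (!identical(dim(fixed), dim(moving))) stop("images must have equal shape")
  if (is.null(init)) init <- init_centered_affine(fixed, moving)
  H <- nrow(fixed); W <- ncol(fixed)
  cen <- init$center
  pf <- build_pyramid(fixed, cfg)
  pm <- build_pyramid(moving, cfg)
  pk <- if (is.null(fixed_mask)) NULL else
    lapply(build_pyramid(fixed_mask + 0, cfg, nearest = TRUE),
           function(l) l$img > 0.5)
  D <- sqrt((W / 2)^2 + (H / 2)^2)
  scales <- c(D, D, D, D, 1, 1)
  par <- c(init$A[1, 1], init$A[1, 2], init$A[2, 1], init$A[2, 2],
           init$b[1], init$b[2])
  traces <- list()
  for (k in seq_along(pf)) {
    fl <- pf[[k]]$img; ml <- pm[[k]]$img
    sx <- pf[[k]]$sx; sy <- pf[[k]]$sy
    ox <- (sx - 1) / 2; oy <- (sy - 1) / 2
    mkl <- if (is.null(pk)) NULL else pk[[k]]
    eval_level <- function(p) {
      # full-res push-forward affine expressed in level coordinates
      A <- matrix(p[1:4], 2, 2, byrow = TRUE)
      Al <- diag(c(1 / sx, 1 / sy)) %*% A %*% diag(c(sx, sy))
      bl <- c(p[5] / sx, p[6] / sy)
      cl <- c((cen[1] - ox) / sx, (cen[2] - oy) / sy)
      mi_affine_metric_cpp(fl, ml, Al[1, 1], Al[1, 2], Al[2, 1], Al[2, 2],
                           bl[1], bl[2], cl[1], cl[2], cfg$mi_bins, mkl)
    }
    hq <- 0.1
    grad_fd <- function(p) {
      vapply(seq_along(p), function(i) {
        h <- hq / scales[i]
        pp <- p; pp[i] <- p[i] + h
        pmn <- p; pmn[i] <- p[i] - h
        (eval_level(pp) - eval_level(pmn)) / (2 * h)
      }, numeric(1))
    }
    res <- descend(par, eval_level, grad_fd, scales, cfg,
                   step_init = cfg$learning_rate * W,
                   context = sprintf("affine stage, pyramid level %d", k))
    par <- res$par
    traces[[k]] <- res$trace
  }
  out <- affine_transform(A = matrix(par[1:4], 2, 2, byrow = TRUE),
                          b = par[5:6], center = cen)
  attr(out, "trace") <- traces
  out
}

#' Fit the B-spline stage
#'
#' Minimizes the configured metric (neighborhood correlation by default, or
#' Mattes MI) over the cubic B-spline control-point displacements of a 4x4
#' mesh by scaled gradient descent with analytic gradients, at full
#' resolution. The moving image must already be affine-resampled.
#'
#' @param fixed 2D numeric matrix.
#' @param moving affine-resampled moving image, same shape.
#' @param cfg an [optimizer_config()].
#' @param fixed_mask optional logical matrix, TRUE = use the pixel.
#' @return a [bspline_transform()] with attribute `trace` (metric descent
#'   log).
#' @export
fit_bspline <- function(fixed, moving, cfg = optimizer_config(),
                        fixed_mask = NULL) {
  stopifnot_image(fixed); stopifnot_image(moving)
  if (!identical(dim(fixed), dim(moving))) stop("images must have equal shape")
  H <- nrow(fixed); W <- ncol(fixed)
  mesh <- cfg$bspline_mesh
  gdim <- c(mesh[2] + 3L, mesh[1] + 3L)
  np <- prod(gdim)
  metric_code <- if (cfg$bspline_metric == "ncc") 0L else 1L
  unpack <- function(p) list(Px = matrix(p[seq_len(np)], gdim[1], gdim[2]),
                             Py = matrix(p[np + seq_len(np)], gdim[1], gdim[2]))
  value_grad <- function(p, want_grad) {
    cp <- unpack(p)
    bspline_metric_value_grad_cpp(fixed, moving, cp$Px, cp$Py,
                                  mesh[1], mesh[2], metric_code,
                                  cfg$ncc_radius, cfg$mi_bins,
                                  fixed_mask, want_grad)
  }
  fn <- function(p) value_grad(p, FALSE)$value
  gr <- function(p) {
    vg <- value_grad(p, TRUE)
    c(as.vector(vg$gPx), as.vector(vg$gPy))
  }
  res <- descend(rep(0, 2 * np), fn, gr, scales = rep(1, 2 * np), cfg,
                 step_init = cfg$learning_rate * W,
                 context = "B-spline stage")
  cp <- unpack(res$par)
  out <- bspline_transform(mesh = mesh, Px = cp$Px, Py = cp$Py,
                           domain = c(H, W))
  attr(out, "trace") <- res$trace
  out
}

#' Register an atlas section onto an experimental section
#'
#' Runs the full composite registration: both images are resized to the
#' working size, converted to Sobel gradient images, min-max normalized,
#' zero-padded, and the moving (atlas) gradient image is histogram-matched
#' onto the fixed one; the affine stage is fitted by Mattes MI over the
#' multiresolution pyramid; the moving image is resampled through the affine
#' and the B-spline stage refines it under neighborhood correlation. The
#' composite is applied to the atlas intensity (linear) and annotation labels
#' (nearest-neighbor), the padding is cropped and outputs are resampled back
#' to the fixed section's native resolution. Damage-mask pixels are excluded
#' from both metrics and zeroed in the warped atlas.
#'
#' @param fixed_section a [section()] (or matrix): the experimental tissue.
#' @param atlas_section a [section()] with `labels`: the atlas slice.
#' @param mask optional logical matrix in the fixed frame, TRUE = damaged
#'   tissue / artifact to ignore.
#' @param pre_cfg a [preprocess_config()].
#' @param opt_cfg an [optimizer_config()].
#' @return list with `transform` (a [composite_transform()] defined on the
#'   padded working frame), `warped_atlas`, `warped_labels`,
#'   `warped_labels_affine` (affine stage only) at native fixed resolution,
#'   and `trace`.
#' @export
register_composite <- function(fixed_section, atlas_section, mask = NULL,
                               pre_cfg = preprocess_config(),
                               opt_cfg = optimizer_config()) {
  fixed_img <- if (inherits(fixed_section, "section")) fixed_section$image
               else fixed_section
  atlas_img <- if (inherits(atlas_section, "section")) atlas_section$image
               else atlas_section
  atlas_labels <- if (inherits(atlas_section, "section")) atlas_section$labels
                  else NULL
  stopifnot_image(fixed_img); stopifnot_image(atlas_img)
  H0 <- nrow(fixed_img); W0 <- ncol(fixed_img)
  ws <- pre_cfg$working_size; pad <- pre_cfg$pad_px
  if (!is.null(mask) && !identical(dim(mask), dim(fixed_img)))
    stop("'mask' must match the fixed section shape")

  run_stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }

  prep <- run_stage("preprocess", {
    fw <- resize_image(fixed_img, ws, ws)
    aw <- resize_image(atlas_img, ws, ws)
    lw <- if (is.null(atlas_labels)) NULL
          else resize_image(atlas_labels, ws, ws, method = "nearest")
    fg <- pad_image(to_gradient(fw), pad)
    mg <- pad_image(to_gradient(aw), pad)
    awp <- pad_image(aw, pad)
    lwp <- if (is.null(lw)) NULL else pad_image(lw, pad)
    incl <- NULL
    if (!is.null(mask)) {
      mw <- resize_image(mask + 0, ws, ws, method = "nearest") > 0.5
      incl <- pad_image((!mw) + 0, pad) > 0.5
      # padding margin is valid background in both frames
      incl[seq_len(pad), ] <- TRUE; incl[(ws + pad + 1):(ws + 2 * pad), ] <- TRUE
      incl[, seq_len(pad)] <- TRUE; incl[, (ws + pad + 1):(ws + 2 * pad)] <- TRUE
    }
    mg <- match_histogram(mg, fg, pre_cfg)
    list(fg = fg, mg = mg, atlas = awp, labels = lwp, incl = incl)
  })

  aff <- run_stage("affine", fit_affine(prep$fg, prep$mg, opt_cfg,
                                        fixed_mask = prep$incl))
  moving_a <- apply_transform(prep$mg, aff, "linear")
  bsp <- run_stage("bspline", fit_bspline(prep$fg, moving_a, opt_cfg,
                                          fixed_mask = prep$incl))
  meta <- list(working_size = ws, pad_px = pad, native_size = c(H0, W0))
  ct <- composite_transform(affine = aff, bspline = bsp, meta = meta)

  crop <- function(img) img[(pad + 1):(pad + ws), (pad + 1):(pad + ws), drop = FALSE]
  to_native <- function(img, nearest) {
    resize_image(crop(img), H0, W0, method = if (nearest) "nearest" else "auto")
  }
  warped_atlas <- to_native(apply_transform(prep$atlas, ct, "linear"), FALSE)
  warped_labels <- NULL
  warped_labels_affine <- NULL
  if (!is.null(prep$labels)) {
    warped_labels <- to_native(apply_transform(prep$labels, ct, "nearest"), TRUE)
    warped_labels_affine <- to_native(apply_transform(prep$labels, aff, "nearest"), TRUE)
  }
  if (!is.null(mask)) warped_atlas[mask] <- 0
  list(transform = ct,
       warped_atlas = warped_atlas,
       warped_labels = warped_labels,
       warped_labels_affine = warped_labels_affine,
       trace = list(affine = attr(aff, "trace"), bspline = attr(bsp, "trace")))
}
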