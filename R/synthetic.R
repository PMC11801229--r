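#' Phantom volume specification
#'
#' @param shape 3D extents in voxels (AP, DV, LR), each >= 32.
#' @param n_regions number of distinct nonzero region ids (>= 2): `n_regions
#'   - 1` concentric "layers" plus one bilateral deep nucleus.
#' @param smoothness_sigma Gaussian smoothing of the intensity field (voxels).
#' @param seed integer seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 96, 96), n_regions = 5,
                         smoothness_sigma = 1.5, seed = 1) {
  if (length(shape) != 3L || any(shape < 32))
    stop("'shape' must be three extents, each >= 32")
  if (n_regions < 2) stop("'n_regions' must be >= 2")
  structure(list(shape = as.integer(shape), n_regions = as.integer(n_regions),
                 smoothness_sigma = smoothness_sigma, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a brain-like phantom atlas volume
#'
#' Builds a smooth ellipsoidal "brain" foreground containing `n_regions - 1`
#' concentric layer labels plus one bilateral deep nucleus (a left/right pair
#' sharing one id, emulating paired subcortical structures). Intensity is a
#' smoothed region-dependent value field with seeded additive noise, so the
#' cross-sectional appearance changes along the AP axis the way a real
#' template volume's does. Deterministic for a given seed.
#'
#' @param spec a [phantom_spec()].
#' @return an [atlas_volume()].
#' @export
make_phantom_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  ca <- (d[1] - 1) / 2; cd <- (d[2] - 1) / 2; cl <- (d[3] - 1) / 2
  ra <- 0.44 * d[1]; rd <- 0.36 * d[2]; rl <- 0.42 * d[3]
  a <- (seq_len(d[1]) - 1 - ca) / ra
  dv <- (seq_len(d[2]) - 1 - cd) / rd
  l <- (seq_len(d[3]) - 1 - cl) / rl
  # the dorsoventral extent tapers toward the anterior pole, so coronal
  # cross-sections are not mirror images about the AP midpoint (as in a real
  # brain) and anterior/posterior positions are distinguishable
  taper <- 0.72 + 0.52 * (seq_len(d[1]) - 1) / (d[1] - 1)
  rho <- array(0, dim = d)
  for (i in seq_len(d[1]))
    rho[i, , ] <- sqrt(a[i]^2 + outer((dv / taper[i])^2, l^2, `+`))
  n_layers <- spec$n_regions - 1L
  labels <- array(0L, dim = d)
  inside <- rho <= 1
  labels[inside] <- as.integer(pmin(pmax(ceiling(rho[inside] * n_layers), 1), n_layers))
  # bilateral deep nucleus (one id for the left/right pair), anterior of the
  # AP midpoint
  nuc_id <- spec$n_regions
  for (s in c(-1, 1)) {
    na_ <- (seq_len(d[1]) - 1 - 0.40 * (d[1] - 1)) / (0.16 * d[1])
    nd_ <- (seq_len(d[2]) - 1 - (cd + 0.08 * d[2])) / (0.11 * d[2])
    nl_ <- (seq_len(d[3]) - 1 - (cl + s * 0.20 * d[3])) / (0.09 * d[3])
    nr <- outer(outer(na_^2, nd_^2, `+`), nl_^2, `+`)
    labels[nr <= 1] <- nuc_id
  }
  present <- sort(as.integer(setdiff(unique(as.vector(labels)), 0L)))
  if (!identical(present, seq_len(spec$n_regions)))
    stop("phantom shape too small to realize all requested regions")
  # region-dependent intensity, brighter toward deep structures
  base <- array(0.05, dim = d)
  vals <- 0.30 + 0.55 * seq_len(spec$n_regions) / spec$n_regions
  for (k in seq_len(spec$n_regions)) base[labels == k] <- vals[k]
  intensity <- gaussian_blur3d_cpp(base, spec$smoothness_sigma)
  intensity <- with_seed(spec$seed, {
    intensity + array(rnorm(prod(d), sd = 0.015), dim = d)
  })
  atlas_volume(intensity = intensity, labels = labels)
}

#' Deformation specification for synthetic "experimental" sections
#'
#' Models the global (mounting) and elastic (sectioning) distortions of real
#' tissue: a push-forward affine part (rotation, isotropic scale, shear,
#' translation) and a random cubic B-spline displacement field of given
#' amplitude, plus intensity-only gamma and additive Gaussian noise.
#'
#' @param rotation_deg rotation angle (degrees).
#' @param scale isotropic scale factor (> 0).
#' @param shear horizontal shear coefficient.
#' @param translation_px length-2 translation (x, y) in pixels.
#' @param bspline_amplitude_px maximum control-point displacement (>= 0).
#' @param bspline_mesh control mesh cells per axis (default c(4, 4)).
#' @param noise_sigma additive Gaussian noise SD (intensity units).
#' @param intensity_gamma gamma applied to the (clamped) intensity.
#' @param seed integer seed for the elastic field and the noise.
#' @return an object of class `deformation_spec`.
#' @export
deformation_spec <- function(rotation_deg = 0, scale = 1, shear = 0,
                             translation_px = c(0, 0),
                             bspline_amplitude_px = 0, bspline_mesh = c(4, 4),
                             noise_sigma = 0, intensity_gamma = 1, seed = 1) {
  if (scale <= 0) stop("'scale' must be > 0")
  if (bspline_amplitude_px < 0) stop("'bspline_amplitude_px' must be >= 0")
  structure(list(rotation_deg = rotation_deg, scale = scale, shear = shear,
                 translation_px = translation_px,
                 bspline_amplitude_px = bspline_amplitude_px,
                 bspline_mesh = as.integer(bspline_mesh),
                 noise_sigma = noise_sigma, intensity_gamma = intensity_gamma,
                 seed = as.integer(seed)),
            class = "deformation_spec")
}

#' Slice a phantom and deform it with a known ground-truth transform
#'
#' Slices `volume` at `pose`, applies the specified affine then a seeded
#' random B-spline displacement of the given amplitude and mesh, and finally
#' applies gamma and additive noise to the intensity only. The exact applied
#' transform is returned in the same composite representation the
#' registration emits, and the section's labels are the ground-truth-warped
#' labels (nearest-neighbor), ready for Dice scoring against a recovered
#' alignment.
#'
#' @param volume an [atlas_volume()].
#' @param pose a [slice_pose()].
#' @param d a [deformation_spec()].
#' @param section_size optional side length: the clean slice is first resized
#'   to `section_size x section_size` (bilinear; labels nearest), emulating a
#'   microscope image whose resolution exceeds the atlas's. Deformation
#'   amplitudes are then expressed in these section pixels. Default NULL
#'   keeps the atlas resolution.
#' @return list with `section` (deformed image + ground-truth labels),
#'   `transform` (the applied [composite_transform()]), and `clean` (the
#'   undeformed section).
#' @export
make_deformed_section <- function(volume, pose, d, section_size = NULL) {
  stopifnot(inherits(d, "deformation_spec"))
  sec <- slice_volume(volume, pose, with_labels = TRUE)
  if (!is.null(section_size)) {
    scale_um <- sec$pixel_size_um * nrow(sec$image) / section_size
    sec <- section(image = resize_image(sec$image, section_size, section_size),
                   labels = resize_image(sec$labels, section_size, section_size,
                                         method = "nearest"),
                   pose = sec$pose, pixel_size_um = scale_um,
                   channel = sec$channel)
  }
  H <- nrow(sec$image); W <- ncol(sec$image)
  th <- d$rotation_deg * pi / 180
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  Sh <- matrix(c(1, d$shear, 0, 1), 2, 2, byrow = TRUE)
  A <- R %*% (d$scale * Sh)
  aff <- affine_transform(A = A, b = as.numeric(d$translation_px),
                          center = c((W - 1) / 2, (H - 1) / 2))
  mesh <- d$bspline_mesh
  gdim <- c(mesh[2] + 3L, mesh[1] + 3L)
  cps <- with_seed(d$seed, {
    list(Px = matrix(runif(prod(gdim), -1, 1) * d$bspline_amplitude_px, gdim[1], gdim[2]),
         Py = matrix(runif(prod(gdim), -1, 1) * d$bspline_amplitude_px, gdim[1], gdim[2]))
  })
  bsp <- bspline_transform(mesh = mesh, Px = cps$Px, Py = cps$Py,
                           domain = c(H, W))
  ct <- composite_transform(affine = aff, bspline = bsp)
  img <- apply_transform(sec$image, ct, interpolation = "linear")
  labs <- apply_transform(sec$labels, ct, interpolation = "nearest")
  if (d$intensity_gamma != 1) img <- clamp(img, 0, Inf)^d$intensity_gamma
  if (d$noise_sigma > 0)
    img <- img + with_seed(d$seed + 1L, matrix(rnorm(H * W, sd = d$noise_sigma), H, W))
  out <- section(image = img, labels = labs, pose = pose,
                 pixel_size_um = sec$pixel_size_um, channel = "counterstain")
  list(section = out, transform = ct, clean = sec)
}

#' Scatter synthetic fluorescent cells on a canvas
#'
#' Renders `n` Gaussian blobs (peak intensity and radius sampled uniformly in
#' the given ranges) at centers drawn inside `region_mask` with an enforced
#' minimum center spacing, over a constant background with additive Gaussian
#' noise. A blob of radius `r` has Gaussian sigma `r / 2`, and its
#' ground-truth box is the center +/- 2 sigma (= +/- r). Deterministic for a
#' given seed.
#'
#' @param canvas_shape c(height, width) in pixels.
#' @param n number of cells (>= 0).
#' @param region_mask logical matrix of allowed center positions (default:
#'   everywhere at least `max(radius_range_px)` from the border).
#' @param radius_range_px range of blob radii (pixels).
#' @param intensity_range range of blob peak amplitudes.
#' @param seed integer seed.
#' @param background constant background level.
#' @param noise_sigma additive Gaussian noise SD.
#' @param min_spacing_px minimum distance between centers (default
#'   `2 * max(radius_range_px)`).
#' @return list with `image` and `boxes` (data.frame `x_min, y_min, x_max,
#'   y_max, confidence` in 1-based pixel-center coordinates).
#' @export
scatter_synthetic_cells <- function(canvas_shape, n, region_mask = NULL,
                                    radius_range_px = c(4, 7),
                                    intensity_range = c(0.5, 1),
                                    seed = 1, background = 0.1,
                                    noise_sigma = 0.05,
                                    min_spacing_px = NULL) {
  H <- canvas_shape[1]; W <- canvas_shape[2]
  if (n < 0) stop("'n' must be >= 0")
  if (is.null(region_mask)) {
    m <- ceiling(max(radius_range_px))
    region_mask <- matrix(FALSE, H, W)
    if (H > 2 * m && W > 2 * m)
      region_mask[(m + 1):(H - m), (m + 1):(W - m)] <- TRUE
  }
  if (!identical(dim(region_mask), as.integer(c(H, W))))
    stop("'region_mask' must match 'canvas_shape'")
  if (n > 0 && !any(region_mask)) stop("'region_mask' is empty but n > 0")
  if (is.null(min_spacing_px)) min_spacing_px <- 2 * max(radius_range_px)
  allowed <- which(region_mask, arr.ind = TRUE)
  with_seed(seed, {
    img <- matrix(background, H, W) + matrix(rnorm(H * W, sd = noise_sigma), H, W)
    cx <- cy <- rad <- amp <- numeric(0)
    attempts <- 0L
    while (length(cx) < n) {
      attempts <- attempts + 1L
      if (attempts > 2000L * max(n, 1L))
        stop("could not place all cells with the requested minimum spacing")
      k <- sample.int(nrow(allowed), 1L)
      py <- allowed[k, 1]; px <- allowed[k, 2]
      if (length(cx) > 0 &&
          min((cx - px)^2 + (cy - py)^2) < min_spacing_px^2) next
      cx <- c(cx, px); cy <- c(cy, py)
      rad <- c(rad, runif(1, radius_range_px[1], radius_range_px[2]))
      amp <- c(amp, runif(1, intensity_range[1], intensity_range[2]))
    }
    if (n > 0) {
      xs <- matrix(rep(seq_len(W), each = H), H, W)
      ys <- matrix(rep(seq_len(H), W), H, W)
      for (k in seq_len(n)) {
        s <- rad[k] / 2
        img <- img + amp[k] * exp(-((xs - cx[k])^2 + (ys - cy[k])^2) / (2 * s^2))
      }
    }
    boxes <- data.frame(x_min = cx - rad, y_min = cy - rad,
                        x_max = cx + rad, y_max = cy + rad,
                        confidence = rep(1, length(cx)))
    list(image = img, boxes = boxes)
  })
}
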