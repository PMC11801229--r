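# Shared fixtures, built once per test run.

# small phantom volume used across modules
test_volume <- local({
  vol <- NULL
  function() {
    if (is.null(vol)) vol <<- make_phantom_volume(
      phantom_spec(shape = c(48, 72, 72), n_regions = 5, seed = 3))
    vol
  }
})

# a reduced working geometry keeps registration tests quick while preserving
# the full preprocessing chain
fast_pre_cfg <- function() preprocess_config(working_size = 180, pad_px = 25)
fast_opt_cfg <- function(max_iterations = 150, ...)
  optimizer_config(max_iterations = max_iterations, ...)

# toy 3-level ontology: root(1) -> {ctx(2), mb(5)}; ctx -> {L23(3), L5(4)}
toy_ontology <- function() {
  ontology(data.frame(
    id = c(1, 2, 3, 4, 5),
    acronym = c("root", "CTX", "L23", "L5", "MB"),
    name = c("root", "cortex", "layer 2/3", "layer 5", "midbrain"),
    parent_id = c(NA, 1, 2, 2, 1)))
}

# brute-force oracles ------------------------------------------------------

# direct 3x3 Sobel magnitude with replicated borders
oracle_sobel <- function(img) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  at <- function(i, j) img[min(max(i, 1), h), min(max(j, 1), w)]
  for (i in seq_len(h)) for (j in seq_len(w)) {
    gx <- 0; gy <- 0
    for (di in -1:1) for (dj in -1:1) {
      v <- at(i + di, j + dj)
      gx <- gx + kx[di + 2, dj + 2] * v
      gy <- gy + ky[di + 2, dj + 2] * v
    }
    out[i, j] <- sqrt(gx^2 + gy^2)
  }
  out
}

# joint-histogram MI with linear Parzen windows (independent of the C++ path)
oracle_mi <- function(f, m, bins = 32) {
  f <- as.vector(f); m <- as.vector(m)
  if (max(f) == min(f) || max(m) == min(m)) return(0)
  xf <- (f - min(f)) / (max(f) - min(f)) * (bins - 1)
  xm <- (m - min(m)) / (max(m) - min(m)) * (bins - 1)
  J <- matrix(0, bins, bins)
  for (k in seq_along(xf)) {
    bf <- min(floor(xf[k]), bins - 2); bm <- min(floor(xm[k]), bins - 2)
    wf <- xf[k] - bf; wm <- xm[k] - bm
    for (da in 0:1) for (db in 0:1) {
      J[bf + da + 1, bm + db + 1] <- J[bf + da + 1, bm + db + 1] +
        (if (da) wf else 1 - wf) * (if (db) wm else 1 - wm)
    }
  }
  J <- J / sum(J)
  pf <- rowSums(J); pm <- colSums(J)
  mi <- 0
  for (a in seq_len(bins)) for (b in seq_len(bins)) {
    if (J[a, b] > 0) mi <- mi + J[a, b] * log(J[a, b] / (pf[a] * pm[b]))
  }
  -mi
}

# mean windowed Pearson correlation, clipped windows, zero-variance excluded
oracle_ncc <- function(f, m, radius) {
  h <- nrow(f); w <- ncol(f)
  vals <- c()
  for (i in seq_len(h)) for (j in seq_len(w)) {
    ii <- max(1, i - radius):min(h, i + radius)
    jj <- max(1, j - radius):min(w, j + radius)
    fv <- as.vector(f[ii, jj]); mv <- as.vector(m[ii, jj])
    if (sd(fv) < 1e-6 || sd(mv) < 1e-6) next
    vals <- c(vals, cor(fv, mv))
  }
  if (length(vals) == 0) return(0)
  -mean(vals)
}

# O(n^2) greedy NMS
oracle_nms <- function(d, thr) {
  ord <- order(-d$confidence, seq_len(nrow(d)))
  d <- d[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(d))
  for (i in seq_len(nrow(d))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(d))) {
      if (j <= i || !keep[j]) next
      ix <- max(0, min(d$x_max[i], d$x_max[j]) - max(d$x_min[i], d$x_min[j]))
      iy <- max(0, min(d$y_max[i], d$y_max[j]) - max(d$y_min[i], d$y_min[j]))
      inter <- ix * iy
      un <- (d$x_max[i] - d$x_min[i]) * (d$y_max[i] - d$y_min[i]) +
            (d$x_max[j] - d$x_min[j]) * (d$y_max[j] - d$y_min[j]) - inter
      if (un > 0 && inter / un > thr) keep[j] <- FALSE
    }
  }
  out <- d[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force oblique plane sampler at sub-pixel supersampling; returns the
# fraction of supersamples carrying the given label
oracle_slab_fraction <- function(volume, pose, label_id, supersample = 4) {
  d <- dim(volume$labels)
  H <- d[2]; W <- d[3]
  b <- historeg:::pose_basis(pose)
  c1 <- pose$ap_index; c2 <- (d[2] - 1) / 2; c3 <- (d[3] - 1) / 2
  hits <- 0; tot <- 0
  offs <- (seq_len(supersample) - (supersample + 1) / 2) / supersample
  for (i in seq_len(H)) for (j in seq_len(W)) {
    for (oy in offs) for (ox in offs) {
      du <- (j - 1) + ox - (W - 1) / 2
      dv <- (i - 1) + oy - (H - 1) / 2
      p1 <- c1 + du * b$u[1] + dv * b$v[1]
      p2 <- c2 + du * b$u[2] + dv * b$v[2]
      p3 <- c3 + du * b$u[3] + dv * b$v[3]
      i1 <- round(p1); i2 <- round(p2); i3 <- round(p3)
      tot <- tot + 1
      if (i1 >= 0 && i1 <= d[1] - 1 && i2 >= 0 && i2 <= d[2] - 1 &&
          i3 >= 0 && i3 <= d[3] - 1) {
        if (volume$labels[i1 + 1, i2 + 1, i3 + 1] == label_id) hits <- hits + 1
      }
    }
  }
  hits / tot
}
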