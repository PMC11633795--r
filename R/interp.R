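# Interpolation and smoothing primitives shared by the deformation,
# registration and resampling code. All physical positions are mm in the
# package axis convention (LR, AP, SI); continuous lattice indices are
# zero-based.

# Convert physical points (n x 3 mm) to zero-based continuous indices,
# snapping indices within 1e-9 voxel of an integer so that on-grid sampling
# is bit-exact.
phys_to_index <- function(pts, origin, spacing) {
  ci <- cbind((pts[, 1] - origin[1]) / spacing[1],
              (pts[, 2] - origin[2]) / spacing[2],
              (pts[, 3] - origin[3]) / spacing[3])
  r <- round(ci)
  snap <- abs(ci - r) < 1e-9
  ci[snap] <- r[snap]
  ci
}

# Precompute trilinear gather indices and weights for a set of physical
# points. Returns base 1-based linear indices, the three per-axis linear
# strides towards the upper corner (0 at the lattice edge), the fractional
# weights and the inside flag.
trilinear_prep <- function(d, origin, spacing, pts, outside = c("fill", "clamp")) {
  outside <- match.arg(outside)
  ci <- phys_to_index(pts, origin, spacing)
  if (outside == "clamp") {
    ci[, 1] <- pmin(pmax(ci[, 1], 0), d[1] - 1)
    ci[, 2] <- pmin(pmax(ci[, 2], 0), d[2] - 1)
    ci[, 3] <- pmin(pmax(ci[, 3], 0), d[3] - 1)
    inside <- TRUE
  } else {
    inside <- ci[, 1] >= 0 & ci[, 1] <= d[1] - 1 &
              ci[, 2] >= 0 & ci[, 2] <= d[2] - 1 &
              ci[, 3] >= 0 & ci[, 3] <= d[3] - 1
    if (any(!inside)) ci[!inside, ] <- 0
  }
  i1 <- floor(ci[, 1]); i2 <- floor(ci[, 2]); i3 <- floor(ci[, 3])
  w1 <- ci[, 1] - i1; w2 <- ci[, 2] - i2; w3 <- ci[, 3] - i3
  s2 <- d[1]; s3 <- d[1] * d[2]
  list(base = 1 + i1 + s2 * i2 + s3 * i3,
       dx = (i1 < d[1] - 1) * 1,
       dy = (i2 < d[2] - 1) * s2,
       dz = (i3 < d[3] - 1) * s3,
       w1 = w1, w2 = w2, w3 = w3, inside = inside)
}

# Apply precomputed trilinear weights to one 3-D array.
trilinear_apply <- function(arr, p) {
  b <- p$base
  c00 <- arr[b];               c00 <- c00 + p$w1 * (arr[b + p$dx] - c00)
  b2 <- b + p$dy
  c10 <- arr[b2];              c10 <- c10 + p$w1 * (arr[b2 + p$dx] - c10)
  c0 <- c00 + p$w2 * (c10 - c00)
  b3 <- b + p$dz
  c01 <- arr[b3];              c01 <- c01 + p$w1 * (arr[b3 + p$dx] - c01)
  b4 <- b3 + p$dy
  c11 <- arr[b4];              c11 <- c11 + p$w1 * (arr[b4 + p$dx] - c11)
  c1 <- c01 + p$w2 * (c11 - c01)
  c0 + p$w3 * (c1 - c0)
}

# Trilinear interpolation of a 3-D array at physical points.
# outside = "fill": points outside the lattice get `fill`;
# outside = "clamp": indices are clamped to the lattice (edge extension).
interp_trilinear <- function(arr, origin, spacing, pts,
                             fill = 0, outside = c("fill", "clamp")) {
  outside <- match.arg(outside)
  p <- trilinear_prep(dim(arr), origin, spacing, pts, outside)
  v <- trilinear_apply(arr, p)
  if (outside == "fill" && !isTRUE(p$inside) && any(!p$inside))
    v[!p$inside] <- fill
  v
}

# Nearest-neighbour interpolation (used for masks: values stay binary).
interp_nearest <- function(arr, origin, spacing, pts, fill = 0) {
  d <- dim(arr)
  ci <- phys_to_index(pts, origin, spacing)
  ri <- round(ci)
  inside <- ri[, 1] >= 0 & ri[, 1] <= d[1] - 1 &
            ri[, 2] >= 0 & ri[, 2] <= d[2] - 1 &
            ri[, 3] >= 0 & ri[, 3] <= d[3] - 1
  ri[!inside, ] <- 0
  v <- arr[1 + ri[, 1] + d[1] * ri[, 2] + d[1] * d[2] * ri[, 3]]
  if (any(!inside)) v[!inside] <- fill
  v
}

# Sample a 3-component field (4-D array) at physical points -> n x 3 matrix.
# One shared index/weight computation serves all three components.
sample_field <- function(u, origin, spacing, pts, outside = "clamp", fill = 0) {
  d <- dim(u)[1:3]
  p <- trilinear_prep(d, origin, spacing, pts, outside)
  n <- prod(d)
  out <- cbind(trilinear_apply_offset(u, 0L, p),
               trilinear_apply_offset(u, n, p),
               trilinear_apply_offset(u, 2L * n, p))
  if (outside == "fill" && !isTRUE(p$inside) && any(!p$inside))
    out[!p$inside, ] <- fill
  out
}

# trilinear_apply against component `off` of a flattened 4-D array
trilinear_apply_offset <- function(u, off, p) {
  q <- p
  q$base <- p$base + off
  trilinear_apply(u, q)
}

# Gaussian smoothing of a 3-D array by FFT-based circular convolution with a
# separable, normalised Gaussian kernel. sigma_mm may be scalar or length 3;
# sigma of 0 disables smoothing along that axis. Wrap-around across the
# volume boundary is accepted: smoothed quantities (demons forces and
# displacement fields) are small near the boundary in all intended uses.
gaussian_smooth <- function(arr, sigma_mm, spacing) {
  d <- dim(arr)
  sigma_mm <- rep(sigma_mm, length.out = 3)
  if (all(sigma_mm <= 0)) return(arr)
  kf <- vector("list", 3)
  for (a in 1:3) {
    s <- sigma_mm[a] / spacing[a]
    if (s <= 0) {
      kf[[a]] <- rep(1 + 0i, d[a])
    } else {
      x <- 0:(d[a] - 1)
      xd <- pmin(x, d[a] - x)
      k <- exp(-xd^2 / (2 * s^2))
      kf[[a]] <- stats::fft(k / sum(k))
    }
  }
  K <- array(outer(outer(kf[[1]], kf[[2]]), kf[[3]]), dim = d)
  Re(stats::fft(stats::fft(arr) * K, inverse = TRUE)) / prod(d)
}

# Central-difference gradient of a 3-D array, per mm (one-sided at borders).
gradient3d <- function(arr, spacing) {
  d <- dim(arr)
  g <- vector("list", 3)
  for (a in 1:3) {
    ga <- array(0, d)
    idx_hi <- slice_index(d, a, c(2:d[a], d[a]))
    idx_lo <- slice_index(d, a, c(1, 1:(d[a] - 1)))
    denom <- c(spacing[a], rep(2 * spacing[a], d[a] - 2), spacing[a])
    ga[] <- (arr[idx_hi] - arr[idx_lo])
    ga <- sweep_axis(ga, a, 1 / denom)
    g[[a]] <- ga
  }
  g
}

# linear indices of arr[(all), ..., ord along axis a, ..., (all)]
slice_index <- function(d, a, ord) {
  idx <- switch(a,
    `1` = outer(ord, (seq_len(d[2] * d[3]) - 1) * d[1], "+"),
    `2` = {
      base <- outer((ord - 1) * d[1], seq_len(d[1]), "+")
      outer(as.vector(t(base)), (seq_len(d[3]) - 1) * d[1] * d[2], "+")
    },
    `3` = outer(seq_len(d[1] * d[2]), (ord - 1) * d[1] * d[2], "+"))
  as.vector(idx)
}

# multiply each slab of arr along axis a by w[slab]
sweep_axis <- function(arr, a, w) {
  d <- dim(arr)
  wfull <- switch(a,
    `1` = rep(w, times = d[2] * d[3]),
    `2` = rep(rep(w, each = d[1]), times = d[3]),
    `3` = rep(w, each = d[1] * d[2]))
  array(as.vector(arr) * wfull, d)
}
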