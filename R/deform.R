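#' Respiratory motion presets
#'
#' Named superior-inferior motion magnitudes used to construct ground-truth
#' respiratory deformations: low (10 mm), medium (20 mm) and high (38 mm)
#' peak SI amplitude.
#'
#' @param name one of `"low"`, `"medium"`, `"high"`.
#' @return list with `name` and `amplitude_mm`.
#' @export
respiratory_preset <- function(name = c("low", "medium", "high")) {
  name <- match.arg(name)
  amp <- c(low = 10, medium = 20, high = 38)[[name]]
  list(name = name, amplitude_mm = amp)
}

#' Ground-truth respiratory displacement field
#'
#' Builds a smooth, SI-dominant displacement field standing in for a
#' biomechanically simulated breathing motion: motion originates in the lung
#' and is propagated to the abdomen, so the SI amplitude peaks at the
#' diaphragm plane (the inferior extent of the lung mask), decays smoothly
#' along SI away from it with length `sigma_si_mm`, and decays from anterior
#' to posterior with a logistic profile of width `ap_width_mm` so that the
#' spine region is nearly static. The AP and LR components of this field are
#' identically zero; displacement is toward inferior (negative SI), as for
#' exhale-to-inhale motion.
#'
#' The construction keeps every finite-difference displacement gradient
#' below 1, which guarantees the field is invertible by fixed-point
#' iteration; amplitudes too large for the chosen decay lengths are
#' rejected.
#'
#' @param geom planning lattice geometry.
#' @param preset a [respiratory_preset()], or `NULL` to use `amplitude_mm`.
#' @param structures a [structure_set()] providing `lung` and `spine` masks.
#' @param amplitude_mm explicit peak SI amplitude (overrides `preset`).
#' @param sigma_si_mm Gaussian decay length of the SI profile (default 30).
#' @param ap_width_mm logistic width of the anterior-to-posterior decay
#'   (default 12).
#' @return A push-forward `vector_field`.
#' @export
respiratory_field <- function(geom, preset = respiratory_preset("high"),
                              structures, amplitude_mm = NULL,
                              sigma_si_mm = 30, ap_width_mm = 12) {
  if (!is.list(geom) || is.null(geom$dim)) geom <- geometry(geom)
  A <- if (is.null(amplitude_mm)) preset$amplitude_mm else amplitude_mm
  if (A == 0) return(zero_field(geom))
  lung <- as_mask_array(structures$masks$lung)
  spine <- as_mask_array(structures$masks$spine)
  if (!any(lung)) stop("lung mask is empty")
  if (!any(spine)) stop("spine mask is empty")
  # the analytic gradient bounds: d/dz <= A*exp(-1/2)/sigma, d/dy <= A/(4w)
  if (A * exp(-0.5) / sigma_si_mm >= 1 || A / (4 * ap_width_mm) >= 1)
    stop("respiratory amplitude too large for the decay lengths: ",
         "the displacement gradient would reach 1 and the field would fold")
  d <- geom$dim
  # diaphragm plane: inferior (lowest SI) extent of the lung mask
  kz <- which(apply(lung, 3, any))
  z_d <- geom$origin[3] + (min(kz) - 1) * geom$spacing[3]
  zs <- geom$origin[3] + (seq_len(d[3]) - 1) * geom$spacing[3]
  prof_z <- exp(-(zs - z_d)^2 / (2 * sigma_si_mm^2))
  # AP decay centred between anterior tissue and the spine
  ij <- which(spine, arr.ind = TRUE)
  y_spine <- geom$origin[2] + (mean(ij[, 2]) - 1) * geom$spacing[2]
  y_c <- y_spine - 40
  ys <- geom$origin[2] + (seq_len(d[2]) - 1) * geom$spacing[2]
  prof_y <- 1 / (1 + exp((ys - y_c) / ap_width_mm))
  usi <- -A * outer(rep(1, d[1]), outer(prof_y, prof_z))
  dim(usi) <- d
  u <- array(0, c(d, 3L))
  u[, , , 3] <- usi
  f <- vector_field(u, geom$origin, geom$spacing)
  # enforce the invertibility invariant numerically
  gmax <- max_field_gradient(f)
  if (gmax >= 1)
    stop(sprintf("respiratory field gradient %.2f >= 1; reduce amplitude", gmax))
  f
}

# largest finite-difference |du_c/dx_a| over components and axes
max_field_gradient <- function(f) {
  gmax <- 0
  for (comp in 1:3) {
    g <- gradient3d(array(f$u[, , , comp], dim(f$u)[1:3]), f$spacing)
    gmax <- max(gmax, vapply(g, function(x) max(abs(x)), numeric(1)))
  }
  gmax
}

#' Uniform digestive shift of an organ
#'
#' Applies a rigid translational displacement to every voxel inside an organ
#' mask, exactly zero outside: the simplified digestive-motion model in
#' which stomach+duodenum and small bowel receive 5 mm shifts in the AP and
#' lateral directions. An optional cosine feather over `feather_mm` softens
#' the field discontinuity at the mask boundary; the default (0, hard edge)
#' applies the shift uniformly to all in-mask voxels.
#'
#' @param geom lattice geometry shared with the mask.
#' @param mask logical array or mask `image_volume` on `geom`.
#' @param shift_ap_mm,shift_lr_mm translation in mm along AP and LR.
#' @param feather_mm boundary feathering length (default 0 = hard edge).
#' @return A push-forward `vector_field`, supported exactly on the mask.
#' @export
digestive_shift <- function(geom, mask, shift_ap_mm = 5, shift_lr_mm = 5,
                            feather_mm = 0) {
  if (!is.list(geom) || is.null(geom$dim)) geom <- geometry(geom)
  m <- as_mask_array(mask)
  if (!identical(dim(m), as.integer(geom$dim)) &&
      !identical(dim(m), geom$dim))
    stop("mask dimensions do not match the geometry")
  if (!any(m)) {
    warning("digestive_shift: empty mask, returning zero field")
    return(zero_field(geom))
  }
  w <- array(0, geom$dim)
  w[m] <- 1
  if (feather_mm > 0)
    w <- gaussian_smooth(w, feather_mm / 2, geom$spacing)
  u <- array(0, c(geom$dim, 3L))
  u[, , , 1] <- shift_lr_mm * w
  u[, , , 2] <- shift_ap_mm * w
  vector_field(u, geom$origin, geom$spacing)
}

#' Combine displacement fields by voxelwise vector addition
#'
#' The ground-truth deformation is the sum of the respiratory field and the
#' per-organ digestive shifts.
#'
#' @param ... `vector_field`s sharing one geometry (or a single list of them).
#' @return Their voxelwise sum as a `vector_field`.
#' @export
combine_fields <- function(...) {
  fields <- list(...)
  if (length(fields) == 1L && !inherits(fields[[1]], "vector_field"))
    fields <- fields[[1]]
  stopifnot(length(fields) >= 1L)
  ref <- fields[[1]]
  u <- ref$u
  for (f in fields[-1]) {
    if (!same_geometry(ref, f)) stop("fields do not share a geometry")
    u <- u + f$u
  }
  vector_field(u, ref$origin, ref$spacing)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds the inverse displacement `v` with `u(p + v(p)) + v(p) = 0` via the
#' iteration `v <- -u(p + v(p))`, which converges whenever the displacement
#' gradients of the smooth part of `u` stay below 1. Residuals are expected
#' (and reported, not fatal) near hard digestive-shift discontinuities; the
#' QA correspondence analysis never requires inverting the ground truth
#' there.
#'
#' @param f a `vector_field`.
#' @param iters maximum iterations.
#' @param tol stop when the largest update falls below this (mm).
#' @return A `vector_field` holding the inverse displacement, with
#'   attributes `residual_max` and `residual_mean` (mm, the composition
#'   residual `|u(p+v(p)) + v(p)|`) and the opposite convention label.
#' @export
invert_dvf <- function(f, iters = 50L, tol = 0.01) {
  stopifnot(inherits(f, "vector_field"))
  geom <- geometry(f)
  pts <- voxel_centers(geom)
  v <- -matrix(f$u, ncol = 3L)
  for (it in seq_len(iters)) {
    us <- sample_field(f$u, f$origin, f$spacing, pts + v, outside = "clamp")
    vnew <- -us
    delta <- max(abs(vnew - v))
    v <- vnew
    if (delta < tol) break
  }
  res <- sample_field(f$u, f$origin, f$spacing, pts + v, outside = "clamp") + v
  rmag <- sqrt(rowSums(res^2))
  out <- vector_field(array(v, c(geom$dim, 3L)), f$origin, f$spacing,
                      convention = if (f$convention == "pushforward")
                        "pullback" else "pushforward")
  attr(out, "residual_max") <- max(rmag)
  attr(out, "residual_mean") <- mean(rmag)
  out
}

#' Warp an image with a push-forward displacement field
#'
#' Resamples `img` so that material carried by the field lands where the
#' field sends it: the output at position `x` is the input at `x + v(x)`,
#' where `v` is the inverse of the push-forward displacement (computed here
#' with [invert_dvf()] unless supplied). Scalar images and dose use
#' trilinear interpolation; masks use nearest-neighbour so values stay
#' binary. Out-of-field samples take -1000 HU for intensity images and 0
#' for masks and dose.
#'
#' @param img an `image_volume` on the field's geometry.
#' @param f push-forward `vector_field`.
#' @param mode `"intensity"`, `"mask"` or `"dose"` (sets interpolation and
#'   the fill value).
#' @param inverse optional precomputed inverse field (saves re-inversion
#'   when several images are warped with the same deformation).
#' @return The warped `image_volume`.
#' @export
warp_image <- function(img, f, mode = c("intensity", "mask", "dose"),
                       inverse = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "image_volume"), inherits(f, "vector_field"))
  if (!same_geometry(img, f)) stop("image and field geometries differ")
  if (is.null(inverse)) inverse <- invert_dvf(f)
  geom <- geometry(img)
  pts <- voxel_centers(geom) + matrix(inverse$u, ncol = 3L)
  fill <- switch(mode, intensity = -1000, mask = 0, dose = 0)
  vals <- if (mode == "mask") {
    interp_nearest(img$data, img$origin, img$spacing, pts, fill = fill)
  } else {
    interp_trilinear(img$data, img$origin, img$spacing, pts,
                     fill = fill, outside = "fill")
  }
  image_volume(array(vals, geom$dim), img$origin, img$spacing)
}
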