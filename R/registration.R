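#' Demons registration parameters
#'
#' Parameterisation of the built-in multi-resolution intensity-based demons
#' registration used as the candidate DIR under test. `sigma_update_mm`
#' smooths the per-iteration force (fluid-like regularisation),
#' `sigma_field_mm` smooths the accumulated field (diffusion-like
#' regularisation); both are Gaussian sigmas in mm. Iterations run
#' coarse-to-fine over `levels` pyramid levels (each level halves the
#' resolution) and stop early when the mean update falls below `tol_mm`.
#'
#' @param levels number of pyramid levels (>= 1).
#' @param iterations iterations per level, recycled to `levels`
#'   (coarsest first).
#' @param sigma_update_mm Gaussian sigma for force smoothing (mm, >= 0).
#' @param sigma_field_mm Gaussian sigma for field smoothing (mm, >= 0).
#' @param sigma_image_mm Gaussian pre-smoothing of both images at each
#'   level (mm); suppresses noise-driven drift in featureless regions
#'   while preserving edge and texture gradients.
#' @param tol_mm early-stopping threshold on the mean voxel update (mm).
#' @export
registration_params <- function(levels = 3L, iterations = c(100L, 60L, 30L),
                                sigma_update_mm = 2, sigma_field_mm = 4,
                                sigma_image_mm = 2, tol_mm = 0.02) {
  if (levels < 1L) stop("at least one pyramid level")
  if (sigma_update_mm < 0 || sigma_field_mm < 0 || sigma_image_mm < 0)
    stop("sigmas must be >= 0")
  structure(list(levels = as.integer(levels),
                 iterations = rep(as.integer(iterations), length.out = levels),
                 sigma_update_mm = sigma_update_mm,
                 sigma_field_mm = sigma_field_mm,
                 sigma_image_mm = sigma_image_mm, tol_mm = tol_mm),
            class = "registration_params")
}

# block-mean downsample a volume by 2 along every axis (dims must be even;
# odd trailing slabs are dropped)
downsample2 <- function(vol) {
  d <- dim(vol$data)
  d2 <- d %/% 2L
  a <- vol$data[seq_len(2 * d2[1]), seq_len(2 * d2[2]), seq_len(2 * d2[3])]
  dim(a) <- c(2, d2[1], 2, d2[2], 2, d2[3])
  a <- apply(a, c(2, 4, 6), mean)
  image_volume(a, origin = vol$origin + vol$spacing / 2,
               spacing = vol$spacing * 2)
}

#' Rigid spine pre-alignment (translation only)
#'
#' Estimates the translation aligning the bony anatomy of `moving` to
#' `fixed` before deformable registration, by maximising the normalised
#' cross-correlation of intensities over the spine mask across an
#' integer-voxel search window, refined per axis by a quadratic fit to the
#' correlation profile. Translation-only is adequate for same-patient scans
#' where spine rotation is negligible, and keeps the search exhaustive.
#'
#' @param fixed,moving `image_volume`s on one geometry.
#' @param spine_mask logical array or mask volume on the fixed geometry.
#' @param search_mm half-width of the search window per axis (mm).
#' @return length-3 translation in mm (add to moving-space positions to
#'   reach fixed-space positions: `moving(x + t) ~ fixed(x)`).
#' @export
rigid_prealign <- function(fixed, moving, spine_mask, search_mm = 16) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  if (!same_geometry(fixed, moving)) stop("fixed/moving geometries differ")
  m <- as_mask_array(spine_mask)
  if (!any(m)) stop("spine mask is empty")
  d <- dim(fixed$data)
  idx <- which(m, arr.ind = TRUE)
  fvals <- fixed$data[m]
  fc <- fvals - mean(fvals)
  fnorm <- sqrt(sum(fc^2))
  steps <- lapply(1:3, function(a) {
    r <- min(floor(search_mm / fixed$spacing[a]), d[a] - 1)
    (-r):r
  })
  score <- array(-Inf, dim = lengths(steps))
  for (i1 in seq_along(steps[[1]])) for (i2 in seq_along(steps[[2]]))
    for (i3 in seq_along(steps[[3]])) {
      s <- c(steps[[1]][i1], steps[[2]][i2], steps[[3]][i3])
      ii <- sweep(idx, 2, s, "+")
      ok <- ii[, 1] >= 1 & ii[, 1] <= d[1] & ii[, 2] >= 1 & ii[, 2] <= d[2] &
            ii[, 3] >= 1 & ii[, 3] <= d[3]
      if (sum(ok) < 0.5 * nrow(idx)) next
      mv <- moving$data[cbind(ii[ok, 1], ii[ok, 2], ii[ok, 3])]
      fv <- fvals[ok] - mean(fvals[ok])
      mvc <- mv - mean(mv)
      den <- sqrt(sum(fv^2)) * sqrt(sum(mvc^2))
      if (den > 0) score[i1, i2, i3] <- sum(fv * mvc) / den
    }
  best <- which(score == max(score), arr.ind = TRUE)[1, ]
  t_vox <- numeric(3)
  for (a in 1:3) {
    b <- best[a]
    t_vox[a] <- steps[[a]][b]
    if (b > 1 && b < length(steps[[a]])) {
      ix <- lapply(seq_len(3), function(k) if (k == a) (b - 1):(b + 1) else best[k])
      y <- score[ix[[1]], ix[[2]], ix[[3]]]
      if (all(is.finite(y)) && (y[1] - 2 * y[2] + y[3]) < 0)
        t_vox[a] <- t_vox[a] + 0.5 * (y[1] - y[3]) / (y[1] - 2 * y[2] + y[3])
    }
  }
  t_vox * fixed$spacing
}

# one demons level: returns the updated pull-back field (4-D array, mm) on
# the level geometry
demons_level <- function(fixed, moving, s, params, iters) {
  geom <- geometry(fixed)
  d <- geom$dim
  sp <- geom$spacing
  pts <- voxel_centers(geom)
  msp2 <- mean(sp)^2
  farr <- fixed$data
  marr <- moving$data
  if (params$sigma_image_mm > 0) {
    farr <- gaussian_smooth(farr, params$sigma_image_mm, sp)
    marr <- gaussian_smooth(marr, params$sigma_image_mm, sp)
  }
  for (it in seq_len(iters)) {
    disp <- matrix(s, ncol = 3L)
    mw <- interp_trilinear(marr, moving$origin, moving$spacing,
                           pts + disp, outside = "clamp")
    mw <- array(mw, d)
    diffI <- mw - farr
    g <- gradient3d((mw + farr) / 2, sp)
    g2 <- g[[1]]^2 + g[[2]]^2 + g[[3]]^2
    den <- g2 + diffI^2 / msp2
    scale <- ifelse(den > 1e-9, -diffI / den, 0)
    upd <- array(0, c(d, 3L))
    for (c in 1:3) {
      uc <- scale * g[[c]]
      if (params$sigma_update_mm > 0)
        uc <- gaussian_smooth(uc, params$sigma_update_mm, sp)
      upd[, , , c] <- uc
    }
    s <- s + upd
    if (params$sigma_field_mm > 0)
      for (c in 1:3)
        s[, , , c] <- gaussian_smooth(array(s[, , , c], d),
                                      params$sigma_field_mm, sp)
    mean_upd <- mean(sqrt(upd[, , , 1]^2 + upd[, , , 2]^2 + upd[, , , 3]^2))
    if (mean_upd < params$tol_mm) break
  }
  s
}

#' Multi-resolution demons deformable registration
#'
#' Classical intensity-based demons with Gaussian fluid/diffusion
#' regularisation, run coarse-to-fine, standing in for a commercial DIR
#' engine as the candidate registration under QA. Internally the algorithm
#' estimates the pull-back field `s` with `moving(x + s(x)) ~ fixed(x)`;
#' the returned field is converted to the canonical push-forward convention
#' with [invert_dvf()], so that with `fixed` = deformed image and `moving` =
#' planning image the result maps planning positions to deformed positions,
#' directly comparable to a ground-truth field. Fully deterministic: no
#' randomness is involved.
#'
#' @param fixed,moving `image_volume`s sharing one geometry.
#' @param params a [registration_params()].
#' @param init_translation_mm optional rigid pre-alignment (from
#'   [rigid_prealign()]) used to initialise the field.
#' @param keep_levels if `TRUE`, attach the per-level pull-back fields (at
#'   their own resolutions) as attribute `"levels"`.
#' @return Push-forward `vector_field` on the fixed geometry; attribute
#'   `"pullback"` carries the raw pull-back field.
#' @export
demons_register <- function(fixed, moving, params = registration_params(),
                            init_translation_mm = c(0, 0, 0),
                            keep_levels = FALSE) {
  stopifnot(inherits(fixed, "image_volume"), inherits(moving, "image_volume"))
  if (!same_geometry(fixed, moving)) stop("fixed/moving geometries differ")
  if (any(!is.finite(fixed$data)) || any(!is.finite(moving$data)))
    stop("non-finite intensities")
  pyr_f <- list(fixed); pyr_m <- list(moving)
  for (l in seq_len(params$levels - 1L)) {
    pyr_f <- c(pyr_f, list(downsample2(pyr_f[[length(pyr_f)]])))
    pyr_m <- c(pyr_m, list(downsample2(pyr_m[[length(pyr_m)]])))
  }
  pyr_f <- rev(pyr_f); pyr_m <- rev(pyr_m)  # coarsest first
  s <- NULL
  level_fields <- list()
  for (l in seq_len(params$levels)) {
    geom <- geometry(pyr_f[[l]])
    if (is.null(s)) {
      s <- array(rep(init_translation_mm, each = prod(geom$dim)),
                 c(geom$dim, 3L))
    } else {
      # upsample the coarse field: resample each component onto this level
      coarse <- level_fields[[l - 1L]]
      pts <- voxel_centers(geom)
      s <- array(sample_field(coarse$u, coarse$origin, coarse$spacing, pts,
                              outside = "clamp"), c(geom$dim, 3L))
    }
    s <- demons_level(pyr_f[[l]], pyr_m[[l]], s, params,
                      params$iterations[l])
    level_fields[[l]] <- vector_field(s, geom$origin, geom$spacing,
                                      convention = "pullback")
  }
  pull <- level_fields[[params$levels]]
  push <- invert_dvf(pull)
  push$convention <- "pushforward"
  attr(push, "pullback") <- pull
  if (keep_levels) attr(push, "levels") <- level_fields
  push
}
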