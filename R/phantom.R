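#' Phantom generator configuration
#'
#' Parameters of the synthetic abdominal CT phantom. The anatomy is
#' deliberately stylised (ellipsoids and tubes): the QA mathematics depends
#' only on masks, intensities and geometry, never on anatomical realism.
#' Defaults give a 96^3 lattice at 2 mm isotropic spacing (a 192 mm cube)
#' containing a body cylinder of soft tissue (~40 HU), lungs (~-700 HU)
#' above a diaphragm, a dense spine (~700 HU), a GTV close to the spine, a
#' stomach+duodenum and a small-bowel region. Gaussian noise (sigma 20 HU)
#' and a smooth soft-tissue texture give intensity-based registration
#' realistic gradients to work with.
#'
#' @param n lattice size per axis (>= 32).
#' @param spacing_mm isotropic voxel spacing in mm (> 0).
#' @param noise_sd_hu additive Gaussian noise sigma in HU.
#' @param texture_sd_hu amplitude of the smooth soft-tissue texture in HU.
#' @param texture_scale_mm correlation length of the texture in mm.
#' @param gtv_spine_max_dist_mm maximum allowed distance from the GTV
#'   centroid to the spine surface (the phantom places the tumour near the
#'   spine, as in pancreatic targets).
#' @param stomach_volume_range_cc acceptance range for the generated
#'   stomach+duodenum volume in cm^3.
#' @return list of class `phantom_config`.
#' @export
phantom_config <- function(n = 96L, spacing_mm = 2, noise_sd_hu = 20,
                           texture_sd_hu = 40, texture_scale_mm = 8,
                           gtv_spine_max_dist_mm = 30,
                           stomach_volume_range_cc = c(30, 70)) {
  if (n < 32L) stop("phantom grid must be at least 32^3 for multi-resolution registration")
  if (spacing_mm <= 0) stop("voxel spacing must be positive")
  structure(list(n = as.integer(n), spacing_mm = spacing_mm,
                 noise_sd_hu = noise_sd_hu, texture_sd_hu = texture_sd_hu,
                 texture_scale_mm = texture_scale_mm,
                 gtv_spine_max_dist_mm = gtv_spine_max_dist_mm,
                 stomach_volume_range_cc = stomach_volume_range_cc),
            class = "phantom_config")
}

#' Named set of binary organ masks on a shared lattice
#'
#' @param masks named list of logical 3-D arrays (required names: `body`,
#'   `lung`, `spine`, `gtv`, `stomach_duodenum`, `small_bowel`).
#' @param origin,spacing shared geometry in mm.
#' @return object of class `structure_set`.
#' @export
structure_set <- function(masks, origin, spacing) {
  required <- c("body", "lung", "spine", "gtv", "stomach_duodenum", "small_bowel")
  if (!all(required %in% names(masks)))
    stop("missing masks: ", paste(setdiff(required, names(masks)), collapse = ", "))
  d <- dim(masks[[1]])
  for (nm in names(masks)) {
    masks[[nm]] <- as_mask_array(masks[[nm]])
    if (!identical(dim(masks[[nm]]), d)) stop("masks do not share a lattice")
  }
  structure(list(masks = masks, origin = as.numeric(origin),
                 spacing = as.numeric(spacing)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  vv <- prod(x$spacing) / 1000
  cat("<structure_set>\n")
  for (nm in names(x$masks))
    cat(sprintf("  %-16s %8d voxels  %8.1f cm^3\n", nm,
                sum(x$masks[[nm]]), sum(x$masks[[nm]]) * vv))
  invisible(x)
}

# check the structure-set invariants; used by the generator and tests
validate_structures <- function(structs, gtv_spine_max_dist_mm = 30) {
  m <- structs$masks
  organs <- setdiff(names(m), "body")
  for (nm in organs)
    if (any(m[[nm]] & !m$body)) stop(nm, " extends outside the body")
  pairs <- utils::combn(c("gtv", "stomach_duodenum", "small_bowel"), 2)
  for (i in seq_len(ncol(pairs)))
    if (any(m[[pairs[1, i]]] & m[[pairs[2, i]]]))
      stop(pairs[1, i], " and ", pairs[2, i], " overlap")
  # GTV centroid must sit near the spine
  gi <- which(m$gtv, arr.ind = TRUE)
  centroid <- structs$origin + (colMeans(gi) - 1) * structs$spacing
  si <- which(m$spine, arr.ind = TRUE)
  sp <- sweep(sweep(si - 1, 2, structs$spacing, "*"), 2, structs$origin, "+")
  dmin <- sqrt(min(rowSums(sweep(sp, 2, centroid, "-")^2)))
  if (dmin > gtv_spine_max_dist_mm)
    stop(sprintf("GTV centroid is %.1f mm from the spine (limit %.1f)",
                 dmin, gtv_spine_max_dist_mm))
  invisible(TRUE)
}

ellipsoid_mask <- function(X, Y, Z, center, semi) {
  ((X - center[1]) / semi[1])^2 + ((Y - center[2]) / semi[2])^2 +
    ((Z - center[3]) / semi[3])^2 <= 1
}

#' Generate the synthetic abdominal phantom
#'
#' Builds the CT-like planning volume and its structure set. Deterministic:
#' the same `(config, seed)` always produces a bit-identical phantom.
#'
#' @param config a [phantom_config()].
#' @param seed integer random seed for noise and texture.
#' @return list with elements `ct` (an `image_volume`, HU) and `structures`
#'   (a `structure_set`).
#' @export
generate_phantom <- function(config = phantom_config(), seed = 7L) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$n
  sp <- rep(config$spacing_mm, 3)
  origin <- c(0, 0, 0)
  ext <- (n - 1) * sp
  cx <- ext / 2                         # cube centre, mm
  ax_v <- function(a) origin[a] + (seq_len(n) - 1) * sp[a]
  X <- array(rep(ax_v(1), times = n * n), c(n, n, n))
  Y <- array(rep(rep(ax_v(2), each = n), times = n), c(n, n, n))
  Z <- array(rep(ax_v(3), each = n * n), c(n, n, n))
  s <- ext[1] / 190                     # scale anatomy with the grid extent

  # torso: elliptical cylinder through the full SI extent
  body <- ((X - cx[1]) / (78 * s))^2 + ((Y - cx[2]) / (65 * s))^2 <= 1
  # lungs: ellipsoid in the superior part; its inferior extent is the
  # diaphragm plane that anchors the respiratory field
  lung <- ellipsoid_mask(X, Y, Z, c(cx[1], cx[2] - 8 * s, ext[3] * 0.80),
                         c(58, 45, 42) * s) & body
  # spine: posterior cylinder, full SI extent
  spine <- ((X - cx[1]) / (12 * s))^2 + ((Y - (cx[2] + 46 * s)) / (12 * s))^2 <= 1
  spine <- spine & body
  # GTV: sphere anterior to the spine, inferior to the lungs (pancreatic bed)
  gtv_center <- c(cx[1], cx[2] + 24 * s, ext[3] * 0.50)
  gtv <- ellipsoid_mask(X, Y, Z, gtv_center, rep(12 * s, 3)) & body & !spine
  # stomach + duodenum: left-anterior ellipsoid below the diaphragm
  stomach <- ellipsoid_mask(X, Y, Z, c(cx[1] - 32 * s, cx[2] - 12 * s, ext[3] * 0.47),
                            c(28, 18, 22) * s) & body
  # small bowel: broad inferior-anterior ellipsoid
  bowel <- ellipsoid_mask(X, Y, Z, c(cx[1] + 10 * s, cx[2] - 14 * s, ext[3] * 0.24),
                          c(36, 22, 26) * s) & body
  stomach <- stomach & !gtv & !spine
  bowel <- bowel & !gtv & !stomach & !spine

  hu <- array(-1000, dim = c(n, n, n))
  hu[body] <- 40
  hu[stomach] <- -40
  hu[bowel] <- -20
  hu[gtv] <- 60
  hu[lung] <- -700
  # vertebral bodies alternating with discs: axial banding gives bony
  # anatomy a superior-inferior intensity structure
  hu[spine] <- 700 - 250 * (0.5 + 0.5 * cos(2 * pi * Z[spine] / (24 * s)))

  set.seed(as.integer(seed))
  if (config$texture_sd_hu > 0) {
    tex <- array(stats::rnorm(n^3), c(n, n, n))
    tex <- gaussian_smooth(tex, config$texture_scale_mm, sp)
    tex <- tex / stats::sd(tex) * config$texture_sd_hu
    soft <- body & !lung & !spine
    hu[soft] <- hu[soft] + tex[soft]
  }
  if (config$noise_sd_hu > 0)
    hu <- hu + array(stats::rnorm(n^3, sd = config$noise_sd_hu), c(n, n, n))

  structs <- structure_set(
    list(body = body, lung = lung, spine = spine, gtv = gtv,
         stomach_duodenum = stomach, small_bowel = bowel),
    origin = origin, spacing = sp)
  validate_structures(structs, config$gtv_spine_max_dist_mm)
  vol_cc <- sum(stomach) * prod(sp) / 1000
  # anatomy scales with the grid extent, so the acceptance window (stated
  # for the default 190 mm extent) scales with the cube of the scale factor
  rng <- config$stomach_volume_range_cc * s^3
  if (vol_cc < rng[1] || vol_cc > rng[2])
    stop(sprintf("stomach+duodenum volume %.1f cm^3 outside [%g, %g]",
                 vol_cc, rng[1], rng[2]))
  list(ct = image_volume(hu, origin, sp), structures = structs)
}

#' Prescription record with one or more dose levels
#'
#' Simultaneous-integrated-boost prescriptions carry several dose levels
#' (e.g. 4500 cGy to a large volume and 7500 cGy to a boost volume); all
#' percentage dose errors are normalised to the highest level.
#'
#' @param levels_cgy dose levels in cGy (any order; stored ascending).
#' @return list of class `plan_prescription` with `levels` (ascending) and
#'   `highest_level`.
#' @export
plan_prescription <- function(levels_cgy = c(4500, 7500)) {
  levels <- sort(as.numeric(levels_cgy))
  if (length(levels) < 1L || any(levels <= 0))
    stop("at least one positive dose level is required")
  structure(list(levels = levels, highest_level = max(levels)),
            class = "plan_prescription")
}

#' Analytic dose model (static dose cloud)
#'
#' The planned dose is modelled as a smooth non-negative function of
#' physical coordinates only: a low-dose bath plus one flat-topped
#' super-Gaussian kernel per prescription level, all centred on the GTV,
#' with a wide kernel carrying the lowest level and progressively narrower
#' kernels adding the boost levels. Because the cloud is anatomy-invariant,
#' evaluating it at ground-truth-corresponding and candidate-corresponding
#' points isolates exactly the dose error introduced by registration error.
#'
#' @param structures a [structure_set()] (provides the GTV).
#' @param rx a [plan_prescription()].
#' @param scales_mm kernel half-widths in mm, one per level, widest first;
#'   defaults shrink from 45 mm towards the boost.
#' @param bath_frac uniform bath dose as a fraction of the highest level.
#' @return object of class `dose_model`.
#' @export
build_dose_model <- function(structures, rx, scales_mm = NULL,
                             bath_frac = 0.02) {
  stopifnot(inherits(rx, "plan_prescription"))
  if (is.null(structures$masks$gtv) || !any(structures$masks$gtv))
    stop("a non-empty gtv mask is required")
  gi <- which(structures$masks$gtv, arr.ind = TRUE)
  center <- structures$origin + (colMeans(gi) - 1) * structures$spacing
  nl <- length(rx$levels)
  if (is.null(scales_mm))
    scales_mm <- seq(45, 22, length.out = max(nl, 2))[seq_len(nl)]
  if (length(scales_mm) != nl) stop("one kernel scale per prescription level")
  # kernel peak increments so the cumulative dose at the centre reaches
  # 1.05 x each level inside that level's kernel
  target <- 1.05 * rx$levels
  peaks <- diff(c(0, target))
  comps <- data.frame(cx = center[1], cy = center[2], cz = center[3],
                      scale = scales_mm, peak = peaks, exponent = 4,
                      row.names = NULL)
  structure(list(type = "kernels", components = comps,
                 bath_dose = bath_frac * rx$highest_level, rx = rx),
            class = "dose_model")
}

#' Linear dose ramp (for analytic verification)
#'
#' A dose model whose dose is `offset + g . p`, clipped at zero: on such a
#' ramp the signed dose error of a uniformly offset candidate field has the
#' closed form `-g . t`, which makes it the canonical analytic check of the
#' correspondence-based dose-error computation.
#'
#' @param gradient_cgy_per_mm length-3 dose gradient in cGy/mm.
#' @param offset_cgy dose at the physical origin.
#' @param rx prescription used for normalisation.
#' @export
linear_dose_model <- function(gradient_cgy_per_mm, offset_cgy,
                              rx = plan_prescription(7500)) {
  structure(list(type = "linear",
                 gradient = as.numeric(gradient_cgy_per_mm),
                 offset = as.numeric(offset_cgy), rx = rx),
            class = "dose_model")
}

#' Evaluate a dose model at arbitrary physical points
#'
#' @param model a `dose_model`.
#' @param pts n x 3 matrix of physical mm coordinates.
#' @return numeric vector of doses in cGy (>= 0).
#' @export
dose_at_points <- function(model, pts) {
  stopifnot(inherits(model, "dose_model"))
  if (model$type == "linear") {
    d <- model$offset + pts %*% model$gradient
    return(pmax(as.numeric(d), 0))
  }
  d <- rep(model$bath_dose, nrow(pts))
  for (i in seq_len(nrow(model$components))) {
    k <- model$components[i, ]
    r2 <- (pts[, 1] - k$cx)^2 + (pts[, 2] - k$cy)^2 + (pts[, 3] - k$cz)^2
    d <- d + k$peak * exp(-(sqrt(r2) / k$scale)^k$exponent)
  }
  d
}

#' Sample a dose model on a lattice
#'
#' Evaluates the static dose cloud at every voxel centre of `geom`. Because
#' the cloud is a function of physical position only, evaluations on
#' different lattices agree exactly at shared physical points.
#'
#' @param model a `dose_model`.
#' @param geom lattice geometry (or object carrying one).
#' @return An `image_volume` of dose in cGy.
#' @export
evaluate_dose <- function(model, geom) {
  if (!is.list(geom) || is.null(geom$dim)) geom <- geometry(geom)
  vals <- dose_at_points(model, voxel_centers(geom))
  image_volume(array(vals, geom$dim), geom$origin, geom$spacing)
}
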