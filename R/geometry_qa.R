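#' The common 1 mm isotropic analysis grid
#'
#' All candidate/ground-truth field comparisons are performed on a shared
#' 1 mm x 1 mm x 1 mm lattice whose origin is aligned across inputs. The
#' grid covers the intersection of the physical extents of the supplied
#' geometries, snapped to whole millimetres inside the intersection so
#' every analysis voxel can be interpolated from every source without
#' extrapolation.
#'
#' @param ... geometries (or objects carrying one) whose common extent
#'   defines the grid.
#' @param spacing_mm analysis spacing (default 1 mm isotropic).
#' @return a geometry list.
#' @export
analysis_grid <- function(..., spacing_mm = 1) {
  geoms <- lapply(list(...), function(g)
    if (is.list(g) && !is.null(g$dim)) g else geometry(g))
  ext <- lapply(geoms, extent_mm)
  lo <- ceiling(apply(vapply(ext, function(e) e["lo", ], numeric(3)), 1, max))
  hi <- floor(apply(vapply(ext, function(e) e["hi", ], numeric(3)), 1, min))
  if (any(hi < lo)) stop("geometries have no common physical extent")
  dims <- floor((hi - lo) / spacing_mm) + 1
  make_geometry(dims, origin = lo, spacing = rep(spacing_mm, 3))
}

#' Resample a displacement field onto the analysis grid
#'
#' Linearly interpolates each displacement component onto a 1 mm isotropic,
#' origin-aligned lattice. Displacement vectors are values in mm along the
#' fixed anatomical axes and are not re-oriented by resampling. When the
#' field already lives on the requested grid it is returned unchanged, so
#' an aligned resample is bit-exact.
#'
#' @param f a `vector_field`.
#' @param reference the target geometry, typically from [analysis_grid()];
#'   defaults to the analysis grid of `f` itself.
#' @return A `vector_field` on the analysis grid.
#' @export
resample_to_analysis_grid <- function(f, reference = NULL) {
  stopifnot(inherits(f, "vector_field"))
  if (is.null(reference)) reference <- analysis_grid(f)
  if (!is.list(reference) || is.null(reference$dim))
    reference <- geometry(reference)
  if (same_geometry(f, reference)) return(f)
  ef <- extent_mm(f); er <- extent_mm(reference)
  if (any(er["lo", ] > ef["hi", ]) || any(er["hi", ] < ef["lo", ]))
    stop("reference grid does not overlap the field extent")
  pts <- voxel_centers(reference)
  u <- array(sample_field(f$u, f$origin, f$spacing, pts, outside = "clamp"),
             c(reference$dim, 3L))
  vector_field(u, reference$origin, reference$spacing, f$convention)
}

# nearest-neighbour resample of one mask onto a geometry
resample_mask <- function(mask, from_geom, to_geom) {
  m <- as_mask_array(mask)
  vals <- interp_nearest(m * 1L, from_geom$origin, from_geom$spacing,
                         voxel_centers(to_geom), fill = 0)
  array(vals != 0, to_geom$dim)
}

#' Resample a structure set onto the analysis grid
#' @param structures a [structure_set()].
#' @param reference target geometry.
#' @return A `structure_set` on `reference`.
#' @export
resample_structures <- function(structures, reference) {
  from <- make_geometry(dim(structures$masks[[1]]), structures$origin,
                        structures$spacing)
  masks <- lapply(structures$masks, resample_mask, from_geom = from,
                  to_geom = reference)
  structure_set(masks, reference$origin, reference$spacing)
}

#' Voxelwise DIR magnitude-error map
#'
#' The magnitude error at a voxel is the Euclidean norm of the difference
#' between candidate and ground-truth displacement components, components
#' matched by anatomical direction (AP, LR, SI). Both fields must already
#' live on the shared analysis grid.
#'
#' @param candidate,truth `vector_field`s on the same analysis grid.
#' @return An `image_volume` of errors in mm (class also `error_map`),
#'   with attribute `"provenance"`.
#' @export
magnitude_error_map <- function(candidate, truth) {
  stopifnot(inherits(candidate, "vector_field"), inherits(truth, "vector_field"))
  if (!same_geometry(candidate, truth))
    stop("candidate and truth must share the analysis grid; resample first")
  du <- candidate$u - truth$u
  err <- sqrt(du[, , , 1]^2 + du[, , , 2]^2 + du[, , , 3]^2)
  out <- image_volume(err, candidate$origin, candidate$spacing)
  class(out) <- c("error_map", class(out))
  attr(out, "provenance") <- list(candidate = deparse(substitute(candidate)),
                                  truth = deparse(substitute(truth)))
  out
}

#' Per-ROI statistics of a scalar error map
#'
#' Computes, for each requested ROI and optionally the whole body, the
#' in-mask mean, 90th percentile (linear interpolation between order
#' statistics, `quantile` type 7), maximum, voxel count and a histogram.
#'
#' @param err an `image_volume`/`error_map` on the analysis grid.
#' @param structures a [structure_set()] on the same grid.
#' @param rois ROI names to analyse (default GTV, the two digestive organs
#'   and body).
#' @param hist_breaks histogram bin edges (mm); default 0.5 mm bins
#'   covering the data range.
#' @return data.frame with one row per ROI (`roi`, `n_voxels`, `mean_mm`,
#'   `p90_mm`, `max_mm`) and an attached list attribute `"histograms"`.
#' @export
roi_error_stats <- function(err, structures,
                            rois = c("gtv", "stomach_duodenum",
                                     "small_bowel", "body"),
                            hist_breaks = NULL) {
  stopifnot(inherits(err, "image_volume"))
  if (!same_geometry(err, make_geometry(dim(structures$masks[[1]]),
                                        structures$origin, structures$spacing)))
    stop("error map and structures are on different grids")
  res <- list(); hists <- list()
  for (roi in rois) {
    m <- structures$masks[[roi]]
    if (is.null(m)) stop("unknown ROI: ", roi)
    v <- err$data[m]
    if (length(v) == 0L) stop("ROI ", roi, " is empty on the analysis grid")
    if (is.null(hist_breaks)) {
      top <- max(v, 0.5)
      breaks <- seq(0, ceiling(top / 0.5) * 0.5, by = 0.5)
    } else breaks <- hist_breaks
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    res[[roi]] <- data.frame(
      roi = roi, n_voxels = length(v), mean_mm = mean(v),
      p90_mm = unname(stats::quantile(v, 0.90, type = 7)),
      max_mm = max(v))
    hists[[roi]] <- data.frame(bin_lo_mm = utils::head(h$breaks, -1),
                               bin_hi_mm = h$breaks[-1], count = h$counts)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "histograms") <- hists
  out
}

#' Per-ROI motion-range summary of a field
#'
#' Maximum and mean displacement magnitude per ROI (motion-range table for
#' a ground-truth field).
#'
#' @param f `vector_field` on the analysis grid.
#' @param structures structures on the same grid.
#' @param rois ROI names.
#' @return data.frame with `roi`, `n_voxels`, `max_mm`, `mean_mm`.
#' @export
roi_magnitude_summary <- function(f, structures,
                                  rois = c("gtv", "stomach_duodenum",
                                           "small_bowel", "body")) {
  mag <- magnitude_map(f)
  res <- lapply(rois, function(roi) {
    m <- structures$masks[[roi]]
    if (is.null(m)) stop("unknown ROI: ", roi)
    v <- mag$data[m]
    data.frame(roi = roi, n_voxels = length(v),
               max_mm = max(v), mean_mm = mean(v))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
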