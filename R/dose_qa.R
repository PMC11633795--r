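#' Corresponding physical points under a push-forward field
#'
#' For every planning-grid voxel centre `p`, the corresponding point in the
#' deformed anatomy is `p + u(p)`: the first step of the voxel-to-voxel
#' dose-error correspondence.
#'
#' @param geom planning lattice geometry (or object carrying one).
#' @param f push-forward `vector_field` on that geometry.
#' @return n x 3 matrix of physical mm points (voxels in lattice order),
#'   with logical attribute `"outside"` flagging points mapped outside the
#'   field's physical extent.
#' @export
correspondence_points <- function(geom, f) {
  if (!is.list(geom) || is.null(geom$dim)) geom <- geometry(geom)
  stopifnot(inherits(f, "vector_field"))
  if (!same_geometry(geom, f)) stop("field is not on the planning geometry")
  pts <- voxel_centers(geom) + matrix(f$u, ncol = 3L)
  ext <- extent_mm(geom)
  outside <- pts[, 1] < ext["lo", 1] | pts[, 1] > ext["hi", 1] |
             pts[, 2] < ext["lo", 2] | pts[, 2] > ext["hi", 2] |
             pts[, 3] < ext["lo", 3] | pts[, 3] > ext["hi", 3]
  attr(pts, "outside") <- outside
  pts
}

#' Signed voxelwise dose-error map of a candidate registration
#'
#' Three-step correspondence: for each planning voxel A inside the body
#' contour, (1) find its corresponding physical points under the
#' ground-truth field (A') and under the candidate field (A''); (2) obtain
#' the dose at both points from the recalculated dose distribution (here
#' the analytic static dose cloud evaluated at physical coordinates);
#' (3) the signed dose error at A is dose(A') minus dose(A''), in cGy.
#' Signs are preserved throughout; a perfect registration gives an exactly
#' zero map, and a spatially flat dose hides any geometric error.
#'
#' @param model a `dose_model`.
#' @param f_truth,f_cand push-forward `vector_field`s on the planning grid.
#' @param region logical body mask on the planning grid; the error is
#'   computed for every voxel inside it (`NA` elsewhere).
#' @return An `image_volume` (class also `dose_error_map`) of signed errors
#'   in cGy, `NA` outside `region`; attribute `"rx"` records the
#'   prescription of `model` when present.
#' @export
dose_error_map <- function(model, f_truth, f_cand, region) {
  stopifnot(inherits(model, "dose_model"))
  if (!same_geometry(f_truth, f_cand))
    stop("truth and candidate fields are on different grids")
  geom <- geometry(f_truth)
  m <- as_mask_array(region)
  if (!any(m)) stop("region mask is empty")
  sel <- which(as.vector(m))
  pts <- voxel_centers(geom)[sel, , drop = FALSE]
  ut <- matrix(f_truth$u, ncol = 3L)[sel, , drop = FALSE]
  uc <- matrix(f_cand$u, ncol = 3L)[sel, , drop = FALSE]
  e <- dose_at_points(model, pts + ut) - dose_at_points(model, pts + uc)
  arr <- array(NA_real_, geom$dim)
  arr[sel] <- e
  out <- structure(list(data = arr, origin = geom$origin,
                        spacing = geom$spacing),
                   class = c("dose_error_map", "image_volume"))
  attr(out, "rx") <- model$rx
  out
}

#' DVH metrics of a dose distribution over an ROI
#'
#' Dmax, Dmin, mean dose, V100% (percentage of the ROI volume receiving at
#' least 100% of the highest prescription level) and D95% (dose received by
#' 95% of the ROI volume, i.e. the 5th percentile of the in-ROI dose, by
#' linear interpolation between order statistics).
#'
#' @param dose an `image_volume` in cGy, or a numeric vector of in-ROI
#'   doses (then `mask` is ignored).
#' @param mask logical ROI mask on the dose grid (ignored for vector input).
#' @param rx a [plan_prescription()].
#' @return list of class `dvh_metrics` with `Dmax`, `Dmin`, `mean`, `V100`
#'   (percent) and `D95` (cGy).
#' @export
dvh_metrics <- function(dose, mask = NULL, rx) {
  stopifnot(inherits(rx, "plan_prescription"))
  v <- if (inherits(dose, "image_volume")) {
    if (is.null(mask)) stop("a mask is required with an image input")
    dose$data[as_mask_array(mask)]
  } else as.numeric(dose)
  if (length(v) == 0L) stop("empty ROI")
  structure(list(
    Dmax = max(v), Dmin = min(v), mean = mean(v),
    V100 = 100 * mean(v >= rx$highest_level),
    D95 = unname(stats::quantile(v, 0.05, type = 7))),
    class = "dvh_metrics")
}

#' Dose-error metric panel for one ROI
#'
#' The six-summary panel of DIR-introduced dose error for an ROI, every
#' entry a signed percentage of the highest prescription level:
#' \itemize{
#'   \item `Dmax_err_pct`, `Dmin_err_pct`: candidate-side minus truth-side
#'     DVH metric (metric-level differences);
#'   \item `mean_err_pct`: mean signed voxel error over the ROI;
#'   \item `max_err_pct`: the signed voxel error of largest absolute value;
#'   \item `p95_err_pct`: 95th percentile of the signed voxel errors;
#'   \item `top1cc_err_pct`: mean signed error over the ~1 cm^3 of ROI
#'     voxels with the largest absolute errors.
#' }
#'
#' @param e a `dose_error_map` (signed cGy, planning grid).
#' @param metrics_truth,metrics_cand [dvh_metrics()] of the ROI dose under
#'   the ground-truth and candidate correspondences.
#' @param roi_mask logical ROI mask on the planning grid.
#' @param rx a [plan_prescription()] (normalisation reference).
#' @param voxel_volume_mm3 volume of one planning voxel; defaults to the
#'   map's voxel volume.
#' @return one-row data.frame with the six panel entries.
#' @export
error_panel <- function(e, metrics_truth, metrics_cand, roi_mask, rx,
                        voxel_volume_mm3 = NULL) {
  stopifnot(inherits(e, "image_volume"), inherits(rx, "plan_prescription"))
  if (rx$highest_level <= 0) stop("prescription reference must be positive")
  if (is.null(voxel_volume_mm3)) voxel_volume_mm3 <- prod(e$spacing)
  v <- e$data[as_mask_array(roi_mask)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) stop("ROI has no dose-error voxels")
  n1cc <- ceiling(1000 / voxel_volume_mm3)
  if (n1cc > length(v)) {
    warning("ROI smaller than 1 cc; top-1cc statistic uses the whole ROI")
    n1cc <- length(v)
  }
  topv <- v[order(abs(v), decreasing = TRUE)[seq_len(n1cc)]]
  pct <- function(x) 100 * x / rx$highest_level
  data.frame(
    Dmax_err_pct = pct(metrics_cand$Dmax - metrics_truth$Dmax),
    Dmin_err_pct = pct(metrics_cand$Dmin - metrics_truth$Dmin),
    mean_err_pct = pct(mean(v)),
    max_err_pct = pct(v[which.max(abs(v))]),
    p95_err_pct = pct(unname(stats::quantile(v, 0.95, type = 7))),
    top1cc_err_pct = pct(mean(topv)))
}

#' Full dosimetric QA for a set of ROIs
#'
#' Runs the correspondence-based dose-error analysis on the planning grid
#' for each ROI: DVH metrics of the ROI dose under ground-truth and
#' candidate correspondence (the dose the ROI actually receives versus the
#' dose the candidate registration would accumulate), their signed
#' differences, and the six-entry dose-error panel.
#'
#' @param model a `dose_model`.
#' @param f_truth,f_cand push-forward fields on the planning grid.
#' @param structures planning-grid [structure_set()].
#' @param rx a [plan_prescription()].
#' @param rois ROI names (default GTV, digestive organs, body).
#' @return list with `panel` (data.frame, one row per ROI), `dvh`
#'   (data.frame of per-ROI DVH metrics and their errors) and `error_map`
#'   (the body-region `dose_error_map`).
#' @export
dose_qa <- function(model, f_truth, f_cand, structures, rx,
                    rois = c("gtv", "stomach_duodenum", "small_bowel", "body")) {
  geom <- geometry(f_truth)
  emap <- dose_error_map(model, f_truth, f_cand, structures$masks$body)
  pts <- voxel_centers(geom)
  ut <- matrix(f_truth$u, ncol = 3L)
  uc <- matrix(f_cand$u, ncol = 3L)
  panel <- list(); dvh <- list()
  for (roi in rois) {
    m <- structures$masks[[roi]]
    if (is.null(m)) stop("unknown ROI: ", roi)
    sel <- which(as.vector(m))
    d_t <- dose_at_points(model, pts[sel, , drop = FALSE] + ut[sel, , drop = FALSE])
    d_c <- dose_at_points(model, pts[sel, , drop = FALSE] + uc[sel, , drop = FALSE])
    mt <- dvh_metrics(d_t, rx = rx)
    mc <- dvh_metrics(d_c, rx = rx)
    panel[[roi]] <- cbind(data.frame(roi = roi),
                          error_panel(emap, mt, mc, m, rx))
    dvh[[roi]] <- data.frame(
      roi = roi,
      Dmax_truth = mt$Dmax, Dmax_cand = mc$Dmax,
      Dmin_truth = mt$Dmin, Dmin_cand = mc$Dmin,
      mean_truth = mt$mean, mean_cand = mc$mean,
      D95_truth = mt$D95, D95_cand = mc$D95,
      V100_truth = mt$V100, V100_cand = mc$V100,
      Dmax_err_pct = 100 * (mc$Dmax - mt$Dmax) / rx$highest_level,
      Dmin_err_pct = 100 * (mc$Dmin - mt$Dmin) / rx$highest_level,
      D95_err_pct = 100 * (mc$D95 - mt$D95) / rx$highest_level,
      V100_err_pct = mc$V100 - mt$V100)
  }
  list(panel = do.call(rbind, c(panel, list(make.row.names = FALSE))),
       dvh = do.call(rbind, c(dvh, list(make.row.names = FALSE))),
       error_map = emap)
}
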