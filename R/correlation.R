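#' Bin voxels by a key value and summarise a statistic per bin
#'
#' Voxels are grouped into equal-width bins over the observed range of the
#' key (e.g. ground-truth displacement magnitude, or DIR magnitude error);
#' within each bin the mean, 25th and 75th percentiles and their span
#' ("range") of the tracked statistic are computed. Binning stabilises the
#' voxelwise scatter against noise and outliers. Bins holding fewer voxels
#' than `min_count` are retained in the table but flagged and excluded from
#' correlation.
#'
#' @param key numeric per-voxel key values.
#' @param stat numeric per-voxel statistic (same length).
#' @param n_bins number of equal-width bins (default 75; the useful range
#'   is roughly 50-100, or choose `bin_width_mm`).
#' @param bin_width_mm optional fixed bin width overriding `n_bins`.
#' @param min_count bins with fewer voxels are flagged `retained = FALSE`.
#' @return data.frame of class `binned_stats` with one row per non-empty
#'   bin: `center` (nominal key magnitude = bin centre), `count`, `mean`,
#'   `p25`, `p75`, `range`, `retained`. Attribute `"degenerate"` is `TRUE`
#'   when all key values coincide (single-bin result, no correlation
#'   possible).
#' @export
bin_voxels <- function(key, stat, n_bins = 75L, bin_width_mm = NULL,
                       min_count = 10L) {
  if (length(key) != length(stat)) stop("key and stat lengths differ")
  if (length(key) == 0L) stop("no voxels to bin")
  lo <- min(key); hi <- max(key)
  degenerate <- hi <= lo
  if (degenerate) {
    out <- data.frame(center = lo, count = length(key), mean = mean(stat),
                      p25 = unname(stats::quantile(stat, 0.25, type = 7)),
                      p75 = unname(stats::quantile(stat, 0.75, type = 7)))
    out$range <- out$p75 - out$p25
    out$retained <- out$count >= min_count
    class(out) <- c("binned_stats", class(out))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (!is.null(bin_width_mm)) n_bins <- max(1L, ceiling((hi - lo) / bin_width_mm))
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  idx <- findInterval(key, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  centers <- (utils::head(breaks, -1) + breaks[-1]) / 2
  groups <- split(stat, factor(idx, levels = seq_len(n_bins)))
  counts <- lengths(groups)
  keep <- counts > 0L
  q <- vapply(groups[keep], stats::quantile, numeric(2),
              probs = c(0.25, 0.75), type = 7)
  out <- data.frame(center = centers[keep], count = as.integer(counts[keep]),
                    mean = vapply(groups[keep], mean, numeric(1)),
                    p25 = q[1, ], p75 = q[2, ])
  out$range <- out$p75 - out$p25
  out$retained <- out$count >= min_count
  rownames(out) <- NULL
  class(out) <- c("binned_stats", class(out))
  attr(out, "degenerate") <- FALSE
  out
}

#' Correlate bin centres with a per-bin statistic
#'
#' Pearson product-moment correlation between the nominal bin magnitudes
#' and either the per-bin mean or the per-bin 25th-75th percentile range of
#' the tracked statistic, over retained bins only. When the per-bin
#' statistic has zero variance the coefficient is undefined; it is reported
#' as 0 with `degenerate = TRUE`.
#'
#' @param b a [bin_voxels()] result.
#' @param against `"mean"` or `"range"`.
#' @return list of class `correlation_result` with `coefficient`,
#'   `against`, `n_bins`, `degenerate`.
#' @export
correlate_bins <- function(b, against = c("mean", "range")) {
  against <- match.arg(against)
  stopifnot(inherits(b, "binned_stats"))
  keep <- b$retained
  if (isTRUE(attr(b, "degenerate")) || sum(keep) < 3L)
    stop("need at least 3 retained bins for a correlation")
  x <- b$center[keep]
  y <- b[[against]][keep]
  degenerate <- stats::sd(y) == 0 || stats::sd(x) == 0
  coef <- if (degenerate) 0 else stats::cor(x, y)
  structure(list(coefficient = coef, against = against,
                 n_bins = sum(keep), degenerate = degenerate),
            class = "correlation_result")
}

#' Binned correlation suite relating motion, DIR error and dose error
#'
#' Runs, per ROI, the three binned analyses linking the QA quantities:
#' \itemize{
#'   \item (a) ground-truth displacement magnitude vs. DIR magnitude error;
#'   \item (b) ground-truth displacement magnitude vs. signed dose error;
#'   \item (c) DIR magnitude error vs. signed dose error;
#' }
#' each correlated against both the per-bin mean and the per-bin
#' 25th-75th-percentile range of the tracked statistic.
#'
#' @param truth,candidate push-forward `vector_field`s on the analysis grid.
#' @param dose_err an `image_volume` of signed dose error on the same grid
#'   (`NA` allowed outside the body).
#' @param structures [structure_set()] on the same grid.
#' @param rois ROI names (default whole body, GTV, small bowel,
#'   stomach+duodenum).
#' @param n_bins,min_count passed to [bin_voxels()].
#' @return data.frame with one row per ROI x analysis x variant:
#'   `roi`, `analysis`, `against`, `coefficient`, `n_bins`, `degenerate`.
#' @export
run_correlation_suite <- function(truth, candidate, dose_err, structures,
                                  rois = c("body", "gtv", "small_bowel",
                                           "stomach_duodenum"),
                                  n_bins = 75L, min_count = 10L) {
  if (!same_geometry(truth, candidate) || !same_geometry(truth, dose_err))
    stop("all inputs must share the analysis grid")
  gt_mag <- magnitude_map(truth)$data
  err_mag <- magnitude_error_map(candidate, truth)$data
  de <- dose_err$data
  analyses <- list(
    c(key = "gt_magnitude", stat = "magnitude_error"),
    c(key = "gt_magnitude", stat = "dose_error"),
    c(key = "magnitude_error", stat = "dose_error"))
  grab <- function(what, m) switch(what,
    gt_magnitude = gt_mag[m], magnitude_error = err_mag[m], dose_error = de[m])
  rows <- list()
  for (roi in rois) {
    m <- structures$masks[[roi]]
    if (is.null(m)) stop("unknown ROI: ", roi)
    if (!any(m)) stop("ROI ", roi, " is empty")
    for (an in analyses) {
      key <- grab(an[["key"]], m)
      st <- grab(an[["stat"]], m)
      ok <- is.finite(key) & is.finite(st)
      id <- sprintf("%s->%s", an[["key"]], an[["stat"]])
      b <- if (sum(ok) > 0L)
        bin_voxels(key[ok], st[ok], n_bins = n_bins, min_count = min_count)
      for (against in c("mean", "range")) {
        row <- data.frame(roi = roi, analysis = id, against = against,
                          coefficient = NA_real_, n_bins = NA_integer_,
                          degenerate = TRUE)
        if (!is.null(b) && !isTRUE(attr(b, "degenerate")) &&
            sum(b$retained) >= 3L) {
          cr <- correlate_bins(b, against)
          row$coefficient <- cr$coefficient
          row$n_bins <- cr$n_bins
          row$degenerate <- cr$degenerate
        }
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
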