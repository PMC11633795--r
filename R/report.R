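#' Configuration of an end-to-end QA run
#'
#' One configuration record drives the whole workflow: phantom generation,
#' ground-truth deformation construction, the candidate registration, and
#' the geometric, dosimetric and correlation analyses. Can be read from a
#' YAML file with [read_qa_config()].
#'
#' @param phantom a [phantom_config()].
#' @param seed integer seed for all stochastic stages (phantom noise).
#' @param respiratory_preset `"low"`, `"medium"` or `"high"`.
#' @param digestive_shift_ap_mm,digestive_shift_lr_mm uniform digestive
#'   translation applied to stomach+duodenum and small bowel (mm; signs
#'   configurable, default +5/+5).
#' @param candidate candidate DIR source: `"demons"` (built-in
#'   registration), `"truth"` (perfect-DIR null), `"zero"` (no-registration
#'   baseline) or a path to a DVF importable with [import_dvf()].
#' @param registration a [registration_params()].
#' @param rx_levels_cgy prescription dose levels in cGy.
#' @param n_bins,min_count correlation binning controls.
#' @param rois ROI names analysed throughout.
#' @return list of class `qa_config`.
#' @export
qa_config <- function(phantom = phantom_config(), seed = 7L,
                      respiratory_preset = "high",
                      digestive_shift_ap_mm = 5, digestive_shift_lr_mm = 5,
                      candidate = "demons",
                      registration = registration_params(),
                      rx_levels_cgy = c(4500, 7500),
                      n_bins = 75L, min_count = 10L,
                      rois = c("gtv", "stomach_duodenum", "small_bowel", "body")) {
  structure(list(phantom = phantom, seed = as.integer(seed),
                 respiratory_preset = respiratory_preset,
                 digestive_shift_ap_mm = digestive_shift_ap_mm,
                 digestive_shift_lr_mm = digestive_shift_lr_mm,
                 candidate = candidate, registration = registration,
                 rx_levels_cgy = rx_levels_cgy, n_bins = as.integer(n_bins),
                 min_count = as.integer(min_count), rois = rois),
            class = "qa_config")
}

#' Read a QA configuration from a YAML file
#'
#' Keys mirror the arguments of [qa_config()]; nested `phantom:` and
#' `registration:` blocks mirror [phantom_config()] and
#' [registration_params()]. Missing keys take the package defaults.
#'
#' @param path YAML file path.
#' @return a `qa_config`.
#' @export
read_qa_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("phantom", "registration"))]
  if (!is.null(y$phantom)) {
    # YAML 1.1 reads the bare key `n` as the boolean FALSE; restore it
    names(y$phantom)[names(y$phantom) == "FALSE"] <- "n"
    args$phantom <- do.call(phantom_config, y$phantom)
  }
  if (!is.null(y$registration))
    args$registration <- do.call(registration_params, y$registration)
  do.call(qa_config, args)
}

#' Run the full patient-specific DIR QA workflow
#'
#' Executes the pipeline end to end: generate the phantom and dose model,
#' build the ground-truth deformation (respiratory field plus digestive
#' shifts), create the deformed CT, produce the candidate DVF (built-in
#' demons after rigid spine pre-alignment, an imported field, or one of the
#' reference candidates), then run the geometric QA on the 1 mm analysis
#' grid, the dosimetric QA on the planning grid, and the binned correlation
#' suite. Fully deterministic given the configuration seed.
#'
#' @param config a [qa_config()].
#' @param verbose print stage progress.
#' @return list of class `qa_report`; see [render_report()] for output.
#' @export
run_workflow <- function(config = qa_config(), verbose = FALSE) {
  stopifnot(inherits(config, "qa_config"))
  say <- function(...) if (verbose) message(...)

  say("phantom: generating anatomy and structures")
  ph <- generate_phantom(config$phantom, seed = config$seed)
  geom <- geometry(ph$ct)
  rx <- plan_prescription(config$rx_levels_cgy)
  model <- build_dose_model(ph$structures, rx)

  say("deform: building ground-truth field")
  resp <- respiratory_field(geom, respiratory_preset(config$respiratory_preset),
                            ph$structures)
  dig_st <- digestive_shift(geom, ph$structures$masks$stomach_duodenum,
                            config$digestive_shift_ap_mm,
                            config$digestive_shift_lr_mm)
  dig_sb <- digestive_shift(geom, ph$structures$masks$small_bowel,
                            config$digestive_shift_ap_mm,
                            config$digestive_shift_lr_mm)
  f_truth <- combine_fields(resp, dig_st, dig_sb)

  say("deform: warping planning CT")
  inv_truth <- invert_dvf(f_truth)
  deformed_ct <- warp_image(ph$ct, f_truth, mode = "intensity",
                            inverse = inv_truth)

  say("registration: producing candidate DVF (", config$candidate, ")")
  prealign <- c(0, 0, 0)
  f_cand <- if (identical(config$candidate, "truth")) {
    f_truth
  } else if (identical(config$candidate, "zero")) {
    zero_field(geom)
  } else if (identical(config$candidate, "demons")) {
    prealign <- rigid_prealign(deformed_ct, ph$ct, ph$structures$masks$spine)
    demons_register(deformed_ct, ph$ct, config$registration,
                    init_translation_mm = prealign)
  } else {
    import_dvf(config$candidate)
  }

  say("geometry_qa: 1 mm analysis grid")
  agrid <- analysis_grid(f_truth, f_cand)
  truth_a <- resample_to_analysis_grid(f_truth, agrid)
  cand_a <- resample_to_analysis_grid(f_cand, agrid)
  structs_a <- resample_structures(ph$structures, agrid)
  emap <- magnitude_error_map(cand_a, truth_a)
  magnitude_summary <- roi_magnitude_summary(truth_a, structs_a, config$rois)
  error_summary <- roi_error_stats(emap, structs_a, config$rois)

  say("dose_qa: correspondence-based dose errors")
  dq <- dose_qa(model, f_truth, f_cand, ph$structures, rx, config$rois)

  say("correlation: binned suite")
  dose_err_a <- image_volume(
    array(interp_trilinear(
      ifelse(is.na(dq$error_map$data), 0, dq$error_map$data),
      geom$origin, geom$spacing, voxel_centers(agrid), outside = "clamp"),
      agrid$dim),
    agrid$origin, agrid$spacing)
  corr <- run_correlation_suite(truth_a, cand_a, dose_err_a, structs_a,
                                rois = intersect(c("body", config$rois),
                                                 names(structs_a$masks)),
                                n_bins = config$n_bins,
                                min_count = config$min_count)

  structure(list(
    metadata = list(
      package_version = as.character(utils::packageVersion("dirqa")),
      schema_version = "1.0",
      seed = config$seed,
      candidate = config$candidate,
      respiratory_preset = config$respiratory_preset,
      rigid_prealign_mm = prealign,
      conventions = list(
        dvf = "pushforward; components LR, AP, SI in mm",
        dose_error_sign = "truth-corresponding dose minus candidate-corresponding dose",
        percentile = "linear interpolation between order statistics (type 7)",
        top1cc = "mean signed error over the 1 cm^3 of ROI voxels with largest absolute error",
        body_statistics = "all voxels inside the body mask")),
    magnitude_summary = magnitude_summary,
    error_summary = error_summary,
    histograms = attr(error_summary, "histograms"),
    dose_panel = dq$panel,
    dvh = dq$dvh,
    correlations = corr,
    inversion_residual_mm = attr(inv_truth, "residual_mean")),
    class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> candidate:", x$metadata$candidate, "\n\n")
  cat("Ground-truth motion range (mm):\n")
  print(x$magnitude_summary, digits = 3)
  cat("\nDIR magnitude error (mm):\n")
  print(x$error_summary, digits = 3)
  cat("\nDose-error panel (% of highest prescription):\n")
  print(x$dose_panel, digits = 3)
  invisible(x)
}

#' Render a QA report to files
#'
#' Always writes the full report as JSON (the machine-readable QA record,
#' embedding all conventions); optionally writes the summary tables and
#' per-ROI histograms as CSV. Degenerate correlation entries are rendered
#' as nulls with their flag, never as numbers.
#'
#' @param report a `qa_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("json", "csv")`.
#' @return invisibly, the paths written.
#' @export
render_report <- function(report, dir, formats = c("json", "csv")) {
  stopifnot(inherits(report, "qa_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  if ("json" %in% formats) {
    p <- file.path(dir, "qa_report.json")
    out <- report
    class(out) <- NULL
    out$correlations$coefficient[out$correlations$degenerate] <- NA_real_
    jsonlite::write_json(out, p, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null", pretty = TRUE)
    paths <- c(paths, p)
  }
  if ("csv" %in% formats) {
    tabs <- list(magnitude_summary = report$magnitude_summary,
                 error_summary = report$error_summary,
                 dose_panel = report$dose_panel,
                 dvh = report$dvh,
                 correlations = report$correlations)
    for (nm in names(tabs)) {
      p <- file.path(dir, paste0(nm, ".csv"))
      utils::write.csv(tabs[[nm]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
    for (roi in names(report$histograms)) {
      p <- file.path(dir, sprintf("histogram_%s.csv", roi))
      utils::write.csv(report$histograms[[roi]], p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
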