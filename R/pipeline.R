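#' Pipeline run configuration
#'
#' Collects every tunable parameter of the quantification pipeline with its
#' default. The effective configuration of a run is written next to its
#' outputs, so config + inputs fully determine the results.
#'
#' @param pixel_size micrometers per pixel.
#' @param background_radius rolling-ball style background radius, px.
#' @param thresholds `"auto"` for per-channel Otsu, or a named list/vector of
#'   manual threshold values (the workflow's primary mode).
#' @param exclusion_min_fraction tissue-mask exclusion rule (fraction of the
#'   outline area; default 0.0005 = 0.05%).
#' @param close_radius_um islet closing radius, um.
#' @param min_area_um2 smallest islet kept, um^2.
#' @param ring_width_px perinuclear ring width, px.
#' @param min_separation_um watershed seed separation, um.
#' @param priority hormone tie-break order (`NULL` = channel order).
#' @param bin_width log10 size-histogram bin width.
#' @param single_cell_area_um2 cell-equivalent constant (178 um^2).
#' @param grid_spacing_um point-counting grid spacing, um.
#' @param panel_um optical panel size `c(w, h)`, um.
#' @param seed seed for any stochastic simulation step.
#' @return list of class `run_config`.
#' @export
run_config <- function(pixel_size = 1, background_radius = 50,
                       thresholds = "auto", exclusion_min_fraction = 0.0005,
                       close_radius_um = 5, min_area_um2 = 0,
                       ring_width_px = 1, min_separation_um = 4.9,
                       priority = NULL, bin_width = 0.25,
                       single_cell_area_um2 = 178, grid_spacing_um = 25,
                       panel_um = c(868, 662), seed = 1) {
  cfg <- list(pixel_size = pixel_size, background_radius = background_radius,
              thresholds = thresholds,
              exclusion_min_fraction = exclusion_min_fraction,
              close_radius_um = close_radius_um, min_area_um2 = min_area_um2,
              ring_width_px = ring_width_px,
              min_separation_um = min_separation_um, priority = priority,
              bin_width = bin_width,
              single_cell_area_um2 = single_cell_area_um2,
              grid_spacing_um = grid_spacing_um, panel_um = panel_um,
              seed = seed)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param cfg a [run_config()].
#' @param path YAML file.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  cfg <- do.call(run_config, vals[names(vals) %in% names(formals(run_config))])
  cfg
}

#' Quantify one section end to end
#'
#' Runs the full pipeline: background subtraction on every channel, tissue
#' mask with the exclusion rule, per-channel thresholding and binarization,
#' composite endocrine mask, islet segmentation and morphometry, nucleus
#' watershed and perinuclear-ring cell typing, islet assignment, and the size
#' distribution analytics.
#'
#' @param section a [section_image].
#' @param contours a [contour_set].
#' @param config a [run_config()].
#' @return list of class `pipeline_result`: `summary` ([section_summary]),
#'   `islets`, `nuclei`, `size_histogram`, `tissue`, `thresholds`, `masks`,
#'   `islet_labels`, `nucleus_labels`, `config`.
#' @export
quantify_section <- function(section, contours, config = run_config()) {
  stopifnot(inherits(section, "section_image"),
            inherits(contours, "contour_set"))
  px <- section$pixel_size
  chans <- lapply(section$channels, subtract_background,
                  radius = config$background_radius)
  tissue <- build_tissue_mask(section, contours,
                              exclusion_min_fraction = config$exclusion_min_fraction)
  thr <- lapply(names(chans), function(nm) {
    if (identical(config$thresholds, "auto")) auto_threshold(chans[[nm]])
    else threshold_spec(config$thresholds[[nm]], "manual")
  })
  names(thr) <- names(chans)
  masks <- lapply(names(chans), function(nm)
    binarize(chans[[nm]], thr[[nm]], tissue, semantic = nm))
  names(masks) <- names(chans)
  hormone_masks <- masks[section$hormones]
  endo <- composite_endocrine_mask(hormone_masks)
  seg <- segment_islets(endo, px, close_radius_um = config$close_radius_um,
                        min_area_um2 = config$min_area_um2)
  nuc_labels <- segment_nuclei(masks$nuclei, px,
                               min_separation_um = config$min_separation_um)
  priority <- if (is.null(config$priority)) names(hormone_masks) else config$priority
  nuclei <- classify_nuclei(nuc_labels, hormone_masks, px,
                            width_px = config$ring_width_px,
                            priority = priority)
  asg <- assign_to_islets(nuclei, seg$labels, px, islets = seg$islets,
                          types = section$hormones)
  seg$islets <- asg$islets
  summary <- section_summary(tissue, hormone_masks, seg, px)
  hist <- if (nrow(seg$islets))
    log_size_histogram(seg$islets, bin_width = config$bin_width,
                       single_cell_area_um2 = config$single_cell_area_um2,
                       types = section$hormones)
  else NULL
  structure(list(summary = summary, islets = seg$islets,
                 nuclei = asg$nuclei, size_histogram = hist,
                 tissue = tissue, thresholds = thr, masks = masks,
                 islet_labels = seg$labels, nucleus_labels = nuc_labels,
                 config = config), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$summary)
  cat(sprintf("  nuclei: %d (%d classified)\n", nrow(x$nuclei),
              sum(x$nuclei$cell_type != "unclassified")))
  invisible(x)
}

#' Run the pipeline and write all result tables
#'
#' Executes [quantify_section()] and writes the islet table, nucleus table,
#' section summary, size histogram, thresholds, the effective configuration
#' and a timestamped log into `out_dir` as CSV/text files.
#'
#' @param section a [section_image].
#' @param contours a [contour_set].
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @return the [quantify_section()] result, invisibly.
#' @export
run_pipeline <- function(section, contours, config = run_config(),
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "),
                               sprintf(...), "\n", sep = "",
                               file = log_path, append = TRUE)
  cat("", file = log_path)
  logline("pipeline start; pixel_size=%g um; channels=%s",
          section$pixel_size, paste(names(section$channels), collapse = ","))
  res <- quantify_section(section, contours, config)
  write_run_config(config, file.path(out_dir, "config.yaml"))
  write_threshold_spec(res$thresholds, file.path(out_dir, "thresholds.txt"))
  utils::write.csv(res$islets, file.path(out_dir, "islets.csv"),
                   row.names = FALSE)
  utils::write.csv(res$nuclei, file.path(out_dir, "nuclei.csv"),
                   row.names = FALSE)
  if (!is.null(res$size_histogram))
    utils::write.csv(res$size_histogram,
                     file.path(out_dir, "size_histogram.csv"),
                     row.names = FALSE)
  s <- res$summary
  summary_df <- data.frame(
    pancreas_area_um2 = s$pancreas_area_um2,
    endocrine_area_um2 = s$endocrine_area_um2,
    total_islet_area_um2 = s$total_islet_area_um2,
    percent_endocrine = s$percent_endocrine,
    islet_count = s$islet_count)
  for (h in names(s$hormone_area_um2))
    summary_df[[paste0("area_", h, "_um2")]] <- s$hormone_area_um2[[h]]
  utils::write.csv(summary_df, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  logline("pipeline done; %d islets, %.4f%% endocrine; seed=%d",
          s$islet_count, s$percent_endocrine, config$seed)
  invisible(res)
}
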