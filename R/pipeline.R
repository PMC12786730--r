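# End-to-end orchestration: quantify tiles -> counts; counts -> report.

log_msg <- function(level, ..., threshold = getOption("evocquant.log_level",
                                                      "info")) {
  levels <- c(debug = 1, info = 2, warn = 3)
  if (levels[[level]] >= levels[[threshold]])
    message(sprintf("[%s] %s", level, paste0(...)))
}

#' Quantify a set of IHC tiles into a counts table
#'
#' Runs stain separation, nucleus detection, positivity calling and
#' ROI-restricted counting on each listed image, then aggregates one counts
#' row per (sample, day, marker). Images without a usable ROI are skipped
#' with a warning; if every image is skipped the run fails.
#'
#' @param images data.frame with one row per tile: `path` (TIFF),
#'   `roi_path` (GeoJSON; `NA` allowed but the tile is then skipped),
#'   `marker` (`"Ki67"`/`"PLAP"`), `sample_id`, `day`, and optionally
#'   `pixel_size_um` (fallback when the TIFF has no resolution tags) and
#'   `roi_pixel_size_um` (set when the GeoJSON is in pixel units).
#' @param config configuration list from [load_config()].
#' @param out_dir output directory; created if missing. Writes
#'   `counts.csv`, per-tile `detections_<n>.csv` and `manifest.json`.
#' @return The counts data.frame, invisibly; files on disk.
#' @export
run_quantify <- function(images, config = load_config(), out_dir = ".") {
  stopifnot(is.data.frame(images), nrow(images) > 0)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- config_detection_params(config)
  vectors <- config_stain_vectors(config)
  t0 <- proc.time()[["elapsed"]]
  warnings_log <- character(0)
  rows <- list()
  det_files <- character(0)
  for (i in seq_len(nrow(images))) {
    img <- images[i, ]
    if (is.null(img$roi_path) || is.na(img$roi_path) ||
        !file.exists(img$roi_path)) {
      w <- paste0("skipping ", img$path, ": missing ROI")
      warnings_log <- c(warnings_log, w)
      log_msg("warn", w)
      next
    }
    tile <- read_tiff_rgb(img$path)
    psz <- tile$pixel_size_um
    if (is.null(psz) && "pixel_size_um" %in% names(img))
      psz <- img$pixel_size_um
    if (is.null(psz) || is.na(psz))
      stop("no pixel size for ", img$path,
           " (neither TIFF resolution tags nor images$pixel_size_um)")
    od <- rgb_to_od(tile$rgb, i0 = config$white_point, pixel_size_um = psz)
    channels <- unmix(od, vectors)
    nuc <- detect_nuclei(channels, params, marker = img$marker)
    roi_psz <- if ("roi_pixel_size_um" %in% names(img) &&
                   !is.na(img$roi_pixel_size_um)) img$roi_pixel_size_um
               else NULL
    region <- read_roi_geojson(img$roi_path, pixel_size_um = roi_psz)
    in_roi <- apply_roi(nuc, region)
    det_path <- file.path(out_dir, sprintf("detections_%03d.csv", i))
    write_detections_csv(in_roi, det_path)
    det_files <- c(det_files, det_path)
    rows[[length(rows) + 1]] <-
      count_cells(in_roi, marker = img$marker,
                  sample_id = img$sample_id, day = img$day)
    log_msg("info", sprintf("%s: %d nuclei in ROI (%s day %s)",
                            basename(img$path), nrow(in_roi),
                            img$sample_id, img$day))
  }
  if (length(rows) == 0)
    stop("all images skipped (no usable ROI); nothing quantified")
  counts <- do.call(rbind, rows)
  counts_path <- file.path(out_dir, "counts.csv")
  write_counts_csv(counts, counts_path)
  write_manifest(out_dir, config, inputs = images$path,
                 outputs = c(counts_path, det_files),
                 timings = c(quantify = proc.time()[["elapsed"]] - t0),
                 warnings = warnings_log)
  invisible(counts)
}

#' Summaries, statistics and viability scores from a counts table
#'
#' Emits per-day cohort summaries with median-decrease blocks for every
#' available quantity, the repeated-measures statistical battery, and
#' per-sample PI AUCs; when a second (experimental) counts table is given,
#' the mean-curve EVOC score between the arms is computed. With fewer than
#' two time points the AUC/statistics blocks are skipped with a notice.
#'
#' @param counts counts data.frame (or CSV path) in the
#'   [write_counts_csv()] schema.
#' @param config configuration list.
#' @param out_dir output directory; writes `report.json` and `report.txt`.
#' @param experimental_counts optional second arm (data.frame or CSV path)
#'   for the EVOC score; `counts` is then the control arm.
#' @return The report list, invisibly.
#' @export
run_report <- function(counts, config = load_config(), out_dir = ".",
                       experimental_counts = NULL) {
  if (is.character(counts)) counts <- read_counts_csv(counts)
  if (is.character(experimental_counts))
    experimental_counts <- read_counts_csv(experimental_counts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  schedule <- as.integer(config$days)
  counts <- assemble_timecourse(counts, schedule = schedule)

  quantities <- c("OCN", "TCN", "stromal", "PI")
  have_marker <- unique(counts$marker)
  if (!"PLAP" %in% have_marker)
    quantities <- setdiff(quantities, c("TCN", "stromal"))
  if (!"Ki67" %in% have_marker) quantities <- setdiff(quantities, "PI")
  if (!"PLAP" %in% have_marker && "Ki67" %in% have_marker)
    quantities <- union(quantities, "OCN")

  report <- list(quantities = list(), notices = character(0))
  txt <- character(0)
  for (q in quantities) {
    mat <- quantity_matrix(counts, q, schedule = schedule)
    mat_cc <- mat[apply(is.finite(mat), 1, all), , drop = FALSE]
    block <- if (nrow(mat) >= 2)
      list(summary = summarize_cohort(mat, quantity = q)) else list()
    if (ncol(mat_cc) >= 2 && nrow(mat_cc) >= 1)
      block$auc <- auc_table(mat, quantity = q)
    else
      report$notices <- c(report$notices,
                          paste0(q, ": single time point; AUC skipped"))
    if (ncol(mat_cc) >= 2 && nrow(mat_cc) >= 3)
      block$stats <- stats_battery(
        mat_cc, quantity = q,
        posthoc_method = config$statistics$posthoc_method,
        sphericity_alpha = config$statistics$sphericity_alpha)
    else
      report$notices <- c(report$notices, paste0(
        q, ": fewer than 2 time points or 3 complete samples; ",
        "statistics skipped"))
    report$quantities[[q]] <- block
    txt <- c(txt, utils::capture.output({
      if (!is.null(block$summary)) print(block$summary)
      if (!is.null(block$stats)) print(block$stats)
    }), "")
  }

  if (!is.null(experimental_counts) && "PI" %in% quantities) {
    experimental_counts <- assemble_timecourse(experimental_counts,
                                               schedule = schedule)
    pi_c <- quantity_matrix(counts, "PI", schedule = schedule)
    pi_e <- quantity_matrix(experimental_counts, "PI", schedule = schedule)
    ctrl <- trajectory_series("control_mean", "PI", schedule,
                              colMeans(pi_c, na.rm = TRUE))
    expt <- trajectory_series("experimental_mean", "PI", schedule,
                              colMeans(pi_e, na.rm = TRUE))
    sc <- evoc_score(ctrl, expt)
    report$evoc <- list(auc_control = sc$auc_control,
                        auc_experimental = sc$auc_experimental,
                        evoc_score = sc$score,
                        orientation = sc$orientation)
    txt <- c(txt, utils::capture.output(print(sc)))
  }

  json <- report_to_json(report)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  writeLines(txt, file.path(out_dir, "report.txt"))
  write_manifest(out_dir, config, inputs = character(0),
                 outputs = file.path(out_dir, c("report.json", "report.txt")),
                 timings = c(report = proc.time()[["elapsed"]] - t0),
                 warnings = report$notices)
  invisible(report)
}

# flatten S3 bits into plain lists for serialization
report_to_json <- function(report) {
  qs <- lapply(report$quantities, function(b) {
    out <- if (is.null(b$summary)) list() else
      list(per_day = b$summary$per_day, decrease = b$summary$decrease)
    if (!is.null(b$stats)) {
      a <- b$stats$anova
      out$anova <- a[c("f_stat", "df_time", "df_error",
                       "df_time_corrected", "df_error_corrected",
                       "epsilon_gg", "epsilon_hf", "mauchly_w", "mauchly_p",
                       "p_uncorrected", "p_corrected", "correction_applied",
                       "eta_p2", "degenerate")]
      out$normality <- b$stats$normality
      out$posthoc <- b$stats$posthoc
      if (!is.null(b$stats$friedman)) out$friedman <- b$stats$friedman
    }
    if (!is.null(b$auc)) out$auc <- b$auc
    out
  })
  list(quantities = qs, evoc = report$evoc, notices = report$notices)
}

write_manifest <- function(out_dir, config, inputs, outputs, timings,
                           warnings = character(0)) {
  outputs <- outputs[file.exists(outputs)]
  manifest <- list(
    software = paste0("evocquant ",
                      as.character(utils::packageVersion("evocquant"))),
    config_hash = attr(config, "config_hash"),
    inputs = as.character(inputs),
    outputs = lapply(outputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    timings_sec = as.list(round(timings, 3)),
    warnings = warnings)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
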