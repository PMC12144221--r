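.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full consistency-testing pipeline
#'
#' Chains every stage end to end: (optional) study simulation, heatmap
#' quantification, lesion matching and triage, consistency metrics, reader
#' analysis, and statistical comparisons. All intermediate tables are
#' persisted under `out_dir` as CSV (each carrying the configuration hash
#' and seed on a comment line) and the consolidated report as
#' `report.json`. Given the same configuration and seed the outputs are
#' byte-identical.
#'
#' @param config configuration list (see [read_config()]) or a path to a
#'   YAML/JSON config file. With `simulate = TRUE` (default) a synthetic
#'   study is generated; otherwise `input_manifest` must point at an
#'   existing study manifest and `reader_responses` (optional) at a reader
#'   CSV.
#' @param out_dir output directory.
#' @param seed top-level seed; overrides `config$seed`.
#' @param quiet suppress stage log messages.
#' @return the consolidated report (list), invisibly; side effect: all
#'   stage outputs written under `out_dir`.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL,
                         quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  seed <- as.integer(seed %||% config$seed %||% 1L)
  blue_threshold <- config$blue_threshold %||% 100
  connectivity <- config$connectivity %||% 26
  tolerance_mm <- config$tolerance_mm %||% 10
  simulate <- config$simulate %||% TRUE
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_sorted <- if (length(config)) config[order(names(config))] else config
  cfg_hash <- fnv1a32_hex(fnv1a32(as.character(jsonlite::toJSON(
    cfg_sorted, auto_unbox = TRUE, force = TRUE, digits = NA))))
  prov <- list(config_hash = cfg_hash, seed = seed)
  log_msg <- function(...) if (!quiet) message("[phantomqc] ", ...)

  design <- config_to_design(config)
  lesions <- config_to_lesions(config, design)

  # --- stage: simulate (or load) -------------------------------------------
  if (simulate) {
    log_msg("simulate: ", n_scans(design), " scans")
    study <- .stage("simulate", simulate_study(
      design, lesions, config$params %||% default_detection_params(),
      seed = seed, render = TRUE,
      output_dir = file.path(out_dir, "heatmaps")))
    manifest <- study$manifest
    manifest$root <- file.path(out_dir, "heatmaps")
    write_qc_table(study$truth, file.path(out_dir, "truth.csv"), prov)
    responses <- .stage("simulate", simulate_readers(
      design, lesions, config$reader_params %||% reader_params(),
      seed = seed))
    write_qc_table(responses, file.path(out_dir, "reader_responses.csv"),
                   prov)
  } else {
    if (is.null(config$input_manifest))
      stop("pipeline stage 'load' failed: simulate = FALSE requires ",
           "config$input_manifest", call. = FALSE)
    manifest <- .stage("load", read_manifest(config$input_manifest))
    responses <- if (!is.null(config$reader_responses))
      .stage("load", read_qc_table(config$reader_responses))
  }
  scans <- manifest$scans

  # --- stage: quantify ------------------------------------------------------
  log_msg("quantify: segmenting ", nrow(scans), " heatmap series")
  comp_list <- vector("list", nrow(scans))
  for (k in seq_len(nrow(scans))) {
    sc <- scans[k, ]
    comp <- .stage("quantify", {
      ser <- read_heatmap_series(
        file.path(manifest$root, sc$path), "png-stack",
        pixel_size_mm = manifest$geometry$pixel_size_mm,
        slice_thickness_mm = manifest$geometry$slice_thickness_mm,
        acquisition = as.list(sc))
      q <- quantify_series(ser, blue_threshold, connectivity)
      if (nrow(q)) cbind(scan_id = sc$scan_id, q, stringsAsFactors = FALSE)
      else NULL
    })
    comp_list[[k]] <- comp
  }
  components <- do.call(rbind, comp_list)
  if (is.null(components))
    components <- data.frame(scan_id = character(), component_id = integer(),
                             n_pixels = integer(), size = numeric(),
                             size_linear = numeric(), intensity = numeric(),
                             centroid_slice = numeric(),
                             centroid_row = numeric(),
                             centroid_col = numeric())
  write_qc_table(components, file.path(out_dir, "components.csv"), prov)

  # --- stage: match ---------------------------------------------------------
  log_msg("match: tolerance ", tolerance_mm, " mm")
  matched <- .stage("match", match_study(
    components, scans, lesions, tolerance_mm,
    manifest$geometry$pixel_size_mm, manifest$geometry$slice_thickness_mm))
  write_qc_table(matched$detections, file.path(out_dir, "detections.csv"),
                 prov)
  write_qc_table(matched$triage, file.path(out_dir, "triage.csv"), prov)
  n_unmatched <- sum(matched$triage$n_unmatched)
  if (n_unmatched > 0)
    warning(n_unmatched, " unmatched label component(s): candidate false ",
            "positives recorded in triage.csv", call. = FALSE)

  # --- stage: consistency ---------------------------------------------------
  log_msg("consistency: detection counts, rates, CVs")
  report <- .stage("consistency", consistency_report(
    matched$detections, matched$triage, design))
  write_qc_table(report$detection_table,
                 file.path(out_dir, "detection_table.csv"), prov)
  write_qc_table(report$label_summary,
                 file.path(out_dir, "label_summary.csv"), prov)
  write_qc_table(rbind(report$cv_size, report$cv_intensity),
                 file.path(out_dir, "cv.csv"), prov)

  # --- stage: readers -------------------------------------------------------
  readers <- NULL
  if (!is.null(responses)) {
    log_msg("readers: ", length(unique(responses$reader_id)), " readers")
    readers <- .stage("readers", reader_summary(responses, design))
    write_qc_table(readers$visibility,
                   file.path(out_dir, "reader_visibility.csv"), prov)
    write_qc_table(readers$quality,
                   file.path(out_dir, "reader_quality.csv"), prov)
  }

  # --- stage: stats ---------------------------------------------------------
  log_msg("stats: Mann-Whitney U with Bonferroni correction")
  tag <- function(df, col, val) {
    df[[col]] <- rep(val, nrow(df))
    df[, c(col, setdiff(names(df), col))]
  }
  stats_ai <- .stage("stats", rbind(
    tag(compare_family(report$label_summary, "mean_size", "lesion_id",
                       "reconstruction", drop_empty = TRUE),
        "measure", "size"),
    tag(compare_family(report$label_summary, "mean_intensity",
                       "lesion_id", "reconstruction", drop_empty = TRUE),
        "measure", "intensity")))
  write_qc_table(stats_ai, file.path(out_dir, "stats_ai.csv"), prov)
  stats_readers <- NULL
  if (!is.null(readers)) {
    stats_readers <- .stage("stats", rbind(
      cbind(family = "lesion_within_reconstruction",
            compare_family(readers$quality, "mean_quality", "lesion_id",
                           "reconstruction")),
      cbind(family = "reconstruction_within_lesion",
            compare_family(readers$quality, "mean_quality",
                           "reconstruction", "lesion_id"))))
    write_qc_table(stats_readers, file.path(out_dir, "stats_readers.csv"),
                   prov)
  }

  # --- stage: report --------------------------------------------------------
  out <- list(
    provenance = c(prov, list(
      tool = "phantomqc",
      version = as.character(packageVersion("phantomqc")),
      blue_threshold = blue_threshold, connectivity = connectivity,
      tolerance_mm = tolerance_mm)),
    lesion_totals = report$lesion_totals,
    lesion_totals_by_reconstruction = report$lesion_totals_by_reconstruction,
    total_labels = report$total_labels,
    triage = report$triage,
    detection_table = report$detection_table,
    cv_size = report$cv_size,
    cv_intensity = report$cv_intensity,
    reader_visibility = readers$visibility,
    stats_ai = stats_ai,
    stats_readers = stats_readers)
  jsonlite::write_json(out, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  log_msg("report written to ", file.path(out_dir, "report.json"))
  invisible(out)
}

#' Plot detection counts per dose and reconstruction
#'
#' One panel per lesion; absolute number of matched labels (0..repetitions)
#' against CTDIvol, one line per reconstruction.
#'
#' @param detection_tab output of [detection_table()].
#' @export
plot_detection_counts <- function(detection_tab) {
  lesions <- unique(detection_tab$lesion_id)
  recons <- unique(detection_tab$reconstruction)
  old <- graphics::par(mfrow = c(1, length(lesions)))
  on.exit(graphics::par(old))
  for (l in lesions) {
    sub <- detection_tab[detection_tab$lesion_id == l, ]
    graphics::plot(NULL, xlim = range(sub$dose_mGy),
                   ylim = c(0, max(sub$n_repetitions)),
                   xlab = "CTDIvol (mGy)", ylab = "true positive labels",
                   main = l)
    for (i in seq_along(recons)) {
      s <- sub[sub$reconstruction == recons[i], ]
      s <- s[order(s$dose_mGy), ]
      graphics::lines(s$dose_mGy, s$n_detected, type = "b", pch = i,
                      lty = i)
    }
    graphics::legend("bottomright", legend = recons, pch = seq_along(recons),
                     lty = seq_along(recons), bty = "n")
  }
  invisible(NULL)
}

#' Plot mean image-quality ratings per dose and reconstruction
#'
#' One panel per lesion; mean recoded quality across readers with SEM error
#' bars, against CTDIvol.
#'
#' @param quality_grid output of [aggregate_quality()].
#' @export
plot_quality_vs_dose <- function(quality_grid) {
  lesions <- unique(quality_grid$lesion_id)
  recons <- unique(quality_grid$reconstruction)
  old <- graphics::par(mfrow = c(1, length(lesions)))
  on.exit(graphics::par(old))
  for (l in lesions) {
    sub <- quality_grid[quality_grid$lesion_id == l, ]
    graphics::plot(NULL, xlim = range(sub$dose_mGy), ylim = c(0, 3),
                   xlab = "CTDIvol (mGy)", ylab = "mean quality rating",
                   main = l)
    for (i in seq_along(recons)) {
      s <- sub[sub$reconstruction == recons[i], ]
      s <- s[order(s$dose_mGy), ]
      graphics::lines(s$dose_mGy, s$mean_quality, type = "b", pch = i,
                      lty = i)
      graphics::arrows(s$dose_mGy, s$mean_quality - s$sem_quality,
                       s$dose_mGy, s$mean_quality + s$sem_quality,
                       angle = 90, code = 3, length = 0.02)
    }
    graphics::legend("bottomright", legend = recons, pch = seq_along(recons),
                     lty = seq_along(recons), bty = "n")
  }
  invisible(NULL)
}
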