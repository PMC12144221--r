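#' Write a heatmap series as a per-slice PNG stack
#'
#' Slices are written as 8-bit RGB `slice_<k>.png` files (0-based index) in
#' the given directory.
#'
#' @param series a [heatmap_series()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_heatmap_series <- function(series, dir) {
  stopifnot(inherits(series, "heatmap_series"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(series$pixels)
  for (k in seq_len(d[1])) {
    sl <- series$pixels[k, , , , drop = TRUE]
    png::writePNG(sl / 255, file.path(dir, sprintf("slice_%03d.png", k - 1L)))
  }
  invisible(dir)
}

#' Read a heatmap series
#'
#' Reads an 8-bit RGB overlay stack. The reference dialect is
#' `"png-stack"`: per-slice files `slice_<k>.png` with contiguous 0-based
#' indices, ordered by index. Slice geometry comes from the caller (usually
#' the study manifest). A missing slice index or mixed slice dimensions is a
#' format error; grayscale or RGBA slices are rejected as non-RGB.
#'
#' @param path directory containing the slice files.
#' @param dialect only `"png-stack"` is supported; `"dicom-rgb"` is not
#'   available in this implementation and raises an informative error.
#' @param pixel_size_mm,slice_thickness_mm voxel spacing in mm.
#' @param acquisition optional acquisition metadata list.
#' @return a [heatmap_series()].
#' @export
read_heatmap_series <- function(path, dialect = c("png-stack", "dicom-rgb"),
                                pixel_size_mm, slice_thickness_mm,
                                acquisition = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "dicom-rgb")
    stop("the dicom-rgb dialect is not supported by this implementation; ",
         "use the png-stack dialect")
  files <- list.files(path, pattern = "^slice_\\d+\\.png$")
  if (length(files) == 0) stop("no slice_<k>.png files found in ", path)
  idx <- as.integer(sub("^slice_(\\d+)\\.png$", "\\1", files))
  files <- files[order(idx)]; idx <- sort(idx)
  expected <- seq(0L, max(idx))
  gap <- setdiff(expected, idx)
  if (length(gap))
    stop("slice stack in ", path, " has missing slice index(es): ",
         paste(gap, collapse = ", "))
  slices <- lapply(file.path(path, files), png::readPNG)
  dims <- lapply(slices, dim)
  if (any(vapply(dims, length, 0L) != 3L) ||
      any(vapply(dims, function(d) d[3], 0L) != 3L))
    stop("non-RGB slice(s) in ", path,
         " (expected 3-channel 8-bit RGB PNG)")
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("mixed slice dimensions in ", path, ": ",
         paste(unique(vapply(dims, paste, "", collapse = "x")),
               collapse = " vs "))
  d <- dims[[1]]
  px <- array(0L, dim = c(length(slices), d[1], d[2], 3L))
  for (k in seq_along(slices)) {
    px[k, , , ] <- as.integer(round(slices[[k]] * 255))
  }
  heatmap_series(px, pixel_size_mm, slice_thickness_mm, acquisition)
}

#' Write / read a study manifest
#'
#' The manifest (JSON) records the geometry, one entry per scan (scan id,
#' dose, reconstruction, repetition, relative heatmap path) and provenance
#' (seed, tool version). Scan paths are checked for existence at load time;
#' scan ids must be unique.
#'
#' @param manifest manifest list (as produced by [simulate_study()]).
#' @param path JSON file path.
#' @return `write_manifest` the path; `read_manifest` the manifest list.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  man <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  root <- dirname(path)
  if (anyDuplicated(man$scans$scan_id))
    stop("manifest contains duplicate scan ids")
  missing <- !dir.exists(file.path(root, man$scans$path))
  if (any(missing))
    stop("manifest scan path(s) missing on disk: ",
         paste(utils::head(man$scans$path[missing], 5), collapse = ", "))
  man$root <- root
  man
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (decided by extension). The configuration mirrors the
#' [run_pipeline()] arguments: `simulate`, `seed`, `blue_threshold`,
#' `connectivity`, `tolerance_mm`, optional `design` overrides
#' (`doses_mGy`, `reconstructions`, `repetitions`, `matrix_size`,
#' `pixel_size_mm`, `slice_thickness_mm`, `n_slices`), optional `lesions`
#' (list of lesion records) and `input_manifest` / `reader_responses` paths
#' for analysing existing data.
#'
#' @param path config file path.
#' @return a named list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext, " (use YAML or JSON)")
}

config_to_design <- function(config) {
  d <- config$design
  if (is.null(d)) return(make_default_design())
  base <- make_default_design()
  study_design(
    doses_mGy = d$doses_mGy %||% base$doses_mGy,
    reconstructions = d$reconstructions %||% base$reconstructions,
    repetitions = d$repetitions %||% base$repetitions,
    matrix_size = d$matrix_size %||% base$geometry$matrix_size,
    pixel_size_mm = d$pixel_size_mm %||% base$geometry$pixel_size_mm,
    slice_thickness_mm = d$slice_thickness_mm %||%
      base$geometry$slice_thickness_mm,
    n_slices = d$n_slices %||% base$geometry$n_slices)
}

config_to_lesions <- function(config, design) {
  if (is.null(config$lesions)) return(default_lesions(design))
  l <- config$lesions
  if (is.data.frame(l))
    les <- lesion_spec(l$lesion_id, l$slice, l$row, l$col, l$max_diameter_mm)
  else les <- lesion_spec(
    vapply(l, `[[`, "", "lesion_id"),
    vapply(l, `[[`, 0, "slice"), vapply(l, `[[`, 0, "row"),
    vapply(l, `[[`, 0, "col"), vapply(l, `[[`, 0, "max_diameter_mm"))
  check_lesion_bounds(les, design)
  les
}
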