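#' Match label components to ground-truth lesions
#'
#' Greedy nearest-distance one-to-one assignment between component centroids
#' and lesion centroids in physical (mm) coordinates, accepting a pair only
#' if the distance is at most `tolerance_mm`. Each lesion receives at most
#' one component and vice versa; components left over are flagged as
#' candidate false positives. Ties in distance are broken by lexicographic
#' lesion id, then by component id, so the assignment is deterministic and
#' independent of input order.
#'
#' Distances use anisotropic voxel spacing: in-plane coordinates are scaled
#' by the pixel size, the through-plane coordinate by the slice thickness.
#'
#' @param components data.frame from [quantify_series()] (needs
#'   `component_id`, `centroid_slice`, `centroid_row`, `centroid_col`).
#' @param lesions a `lesion_spec` table.
#' @param tolerance_mm maximum accepted centroid distance; default 10.
#' @param pixel_size_mm,slice_thickness_mm voxel spacing in mm.
#' @return list with `detections` (one row per lesion: `lesion_id`,
#'   `matched`, `component_id`, `offset_mm`) and `unmatched` (component ids
#'   not assigned to any lesion).
#' @export
match_labels <- function(components, lesions, tolerance_mm = 10,
                         pixel_size_mm, slice_thickness_mm) {
  stopifnot(tolerance_mm >= 0, pixel_size_mm > 0, slice_thickness_mm > 0)
  nL <- nrow(lesions); nC <- nrow(components)
  det <- data.frame(lesion_id = lesions$lesion_id, matched = FALSE,
                    component_id = NA_integer_, offset_mm = NA_real_,
                    stringsAsFactors = FALSE)
  if (nC == 0L) return(list(detections = det, unmatched = integer()))
  # pairwise lesion x component distances in mm
  lmm <- cbind(lesions$slice * slice_thickness_mm,
               lesions$row * pixel_size_mm,
               lesions$col * pixel_size_mm)
  cmm <- cbind(components$centroid_slice * slice_thickness_mm,
               components$centroid_row * pixel_size_mm,
               components$centroid_col * pixel_size_mm)
  dist <- outer(seq_len(nL), seq_len(nC), Vectorize(function(i, j)
    sqrt(sum((lmm[i, ] - cmm[j, ])^2))))
  lesion_free <- rep(TRUE, nL); comp_free <- rep(TRUE, nC)
  repeat {
    d <- dist
    d[!lesion_free, ] <- Inf
    d[, !comp_free] <- Inf
    if (all(!is.finite(d)) || min(d) > tolerance_mm) break
    best <- min(d)
    cand <- which(d == best, arr.ind = TRUE)
    # deterministic tie-break: lesion id lexicographic, then component id
    cand <- cand[order(lesions$lesion_id[cand[, 1]],
                       components$component_id[cand[, 2]]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    det$matched[i] <- TRUE
    det$component_id[i] <- components$component_id[j]
    det$offset_mm[i] <- dist[i, j]
    lesion_free[i] <- FALSE; comp_free[j] <- FALSE
  }
  list(detections = det,
       unmatched = components$component_id[comp_free])
}

#' Scan-level triage decision
#'
#' A scan is triage-positive iff its heatmap contains at least one label
#' component (matched to a lesion or not); a heatmap with no components is
#' the negative summary report.
#'
#' @param components data.frame of components for one scan (possibly with
#'   zero rows).
#' @param unmatched integer vector of unmatched component ids (from
#'   [match_labels()]); optional, recorded in the result.
#' @return list with `decision` ("positive"/"negative"), `n_components`,
#'   `unmatched_component_ids`.
#' @export
triage_decision <- function(components, unmatched = integer()) {
  n <- if (is.data.frame(components)) nrow(components)
  else length(components)
  list(decision = if (n >= 1) "positive" else "negative",
       n_components = n,
       unmatched_component_ids = unmatched)
}

#' Match components and derive triage decisions for a whole study
#'
#' Applies [match_labels()] and [triage_decision()] per scan over a full
#' component table. Scans present in `scans` but absent from `components`
#' count as zero-component (triage-negative) scans.
#'
#' @param components data.frame of per-scan components with a `scan_id`
#'   column plus the [quantify_series()] columns.
#' @param scans data.frame from [design_scans()].
#' @param lesions a `lesion_spec` table.
#' @param tolerance_mm matching tolerance in mm.
#' @param pixel_size_mm,slice_thickness_mm voxel spacing in mm.
#' @return list with `detections` (scan x lesion rows, including size and
#'   intensity of the matched component) and `triage` (one row per scan).
#' @export
match_study <- function(components, scans, lesions, tolerance_mm = 10,
                        pixel_size_mm, slice_thickness_mm) {
  if (is.null(components) || nrow(components) == 0L) {
    components <- data.frame(scan_id = character(), component_id = integer(),
                             n_pixels = integer(), size = numeric(),
                             size_linear = numeric(), intensity = numeric(),
                             centroid_slice = numeric(),
                             centroid_row = numeric(),
                             centroid_col = numeric(),
                             stringsAsFactors = FALSE)
  }
  det_list <- vector("list", nrow(scans))
  tri_list <- vector("list", nrow(scans))
  for (k in seq_len(nrow(scans))) {
    sc <- scans[k, ]
    comp <- components[components$scan_id == sc$scan_id, , drop = FALSE]
    m <- match_labels(comp, lesions, tolerance_mm,
                      pixel_size_mm, slice_thickness_mm)
    d <- m$detections
    d$scan_id <- sc$scan_id
    d$dose_mGy <- sc$dose_mGy
    d$reconstruction <- sc$reconstruction
    d$repetition <- sc$repetition
    mi <- match(d$component_id, comp$component_id)
    d$size <- comp$size[mi]
    d$size_linear <- comp$size_linear[mi]
    d$intensity <- comp$intensity[mi]
    d$n_pixels <- comp$n_pixels[mi]
    det_list[[k]] <- d[, c("scan_id", "dose_mGy", "reconstruction",
                           "repetition", "lesion_id", "matched",
                           "component_id", "offset_mm", "n_pixels",
                           "size", "size_linear", "intensity")]
    td <- triage_decision(comp, m$unmatched)
    tri_list[[k]] <- data.frame(
      scan_id = sc$scan_id, dose_mGy = sc$dose_mGy,
      reconstruction = sc$reconstruction, repetition = sc$repetition,
      decision = td$decision, n_components = td$n_components,
      n_unmatched = length(td$unmatched_component_ids),
      unmatched_component_ids =
        paste(td$unmatched_component_ids, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  detections <- do.call(rbind, det_list)
  triage <- do.call(rbind, tri_list)
  rownames(detections) <- rownames(triage) <- NULL
  list(detections = detections, triage = triage)
}
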