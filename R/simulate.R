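#' Construct a heatmap series
#'
#' An 8-bit RGB overlay stack tied to one acquisition. Pixels are stored as
#' an integer array with dimensions (slice, row, col, channel), values in
#' 0..255.
#'
#' @param pixels integer array (slice, row, col, 3).
#' @param pixel_size_mm,slice_thickness_mm voxel spacing in mm.
#' @param acquisition named list describing the scan (scan_id, dose_mGy,
#'   reconstruction, repetition); may be NULL.
#' @return an object of class `heatmap_series`.
#' @export
heatmap_series <- function(pixels, pixel_size_mm, slice_thickness_mm,
                           acquisition = NULL) {
  d <- dim(pixels)
  if (length(d) != 4L || d[4] != 3L)
    stop("pixels must be a (slice, row, col, 3) array")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  if (pixel_size_mm <= 0 || slice_thickness_mm <= 0)
    stop("voxel spacing must be positive")
  structure(list(pixels = pixels, pixel_size_mm = pixel_size_mm,
                 slice_thickness_mm = slice_thickness_mm,
                 acquisition = acquisition),
            class = "heatmap_series")
}

#' @export
print.heatmap_series <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<heatmap_series> %d slices of %dx%d RGB, %.2f/%.2f mm spacing",
              d[1], d[2], d[3], x$pixel_size_mm, x$slice_thickness_mm))
  if (!is.null(x$acquisition))
    cat(sprintf(" [%s]", x$acquisition$scan_id %||% ""))
  cat("\n")
  invisible(x)
}

# Background grey and label colour constants. Background is neutral with all
# channels well above the blue segmentation threshold; labels are "hot"
# (red 255, blue 60 <= 100) with the green channel solved so the rendered
# BT.601 inverted-grayscale intensity hits a requested target.
.BG_LEVEL <- 230L
.LABEL_RED <- 255L
.LABEL_BLUE <- 60L

# green channel achieving inverted-grayscale intensity t for (255, g, 60)
.green_for_intensity <- function(t) {
  g <- (255 * (1 - t) - (0.299 * .LABEL_RED + 0.114 * .LABEL_BLUE)) / 0.587
  as.integer(pmin(255, pmax(0, round(g))))
}

# intensity targets must stay inside what the fixed red/blue channels allow
.intensity_range <- function() {
  c((255 - (0.299 * .LABEL_RED + 0.587 * 255 + 0.114 * .LABEL_BLUE)) / 255,
    (255 - (0.299 * .LABEL_RED + 0.114 * .LABEL_BLUE)) / 255)
}

# Deterministic renderer: no RNG. spec is a data.frame with one row per
# blob: lesion_id, slice, row, col (0-based, possibly fractional),
# radius_px, intensity_target.
.render_scan <- function(geometry, spec, acquisition = NULL) {
  ns <- geometry$n_slices; m <- geometry$matrix_size
  px <- array(.BG_LEVEL, dim = c(ns, m, m, 3L))
  rendered <- list()
  if (nrow(spec) > 0) {
    for (i in seq_len(nrow(spec))) {
      sl <- as.integer(round(spec$slice[i]))
      if (sl < 0 || sl >= ns)
        stop("label blob for ", spec$lesion_id[i],
             " falls entirely outside image bounds (slice ", sl, ")")
      r0 <- spec$row[i]; c0 <- spec$col[i]; rad <- spec$radius_px[i]
      rr <- max(0, floor(r0 - rad)):min(m - 1, ceiling(r0 + rad))
      cc <- max(0, floor(c0 - rad)):min(m - 1, ceiling(c0 + rad))
      if (r0 + rad < 0 || r0 - rad > m - 1 || c0 + rad < 0 || c0 - rad > m - 1)
        stop("label blob for ", spec$lesion_id[i],
             " falls entirely outside image bounds")
      grid <- expand.grid(row = rr, col = cc, KEEP.OUT.ATTRS = FALSE)
      inside <- (grid$row - r0)^2 + (grid$col - c0)^2 <= rad^2
      # guarantee at least the centre pixel so tiny low-dose blobs survive
      ctr <- c(round(r0), round(c0))
      if (!any(inside) && ctr[1] >= 0 && ctr[1] < m && ctr[2] >= 0 &&
          ctr[2] < m) {
        grid <- data.frame(row = ctr[1], col = ctr[2])
        inside <- TRUE
      }
      pixp <- grid[inside, , drop = FALSE]
      if (nrow(pixp) == 0)
        stop("label blob for ", spec$lesion_id[i],
             " falls entirely outside image bounds")
      g <- .green_for_intensity(spec$intensity_target[i])
      idx_r <- cbind(sl + 1L, pixp$row + 1L, pixp$col + 1L)
      px[cbind(idx_r, 1L)] <- .LABEL_RED
      px[cbind(idx_r, 2L)] <- g
      px[cbind(idx_r, 3L)] <- .LABEL_BLUE
      rendered[[spec$lesion_id[i]]] <-
        cbind(slice = rep(sl, nrow(pixp)), row = pixp$row, col = pixp$col)
    }
  }
  out <- heatmap_series(px, geometry$pixel_size_mm,
                        geometry$slice_thickness_mm, acquisition)
  attr(out, "rendered_pixels") <- rendered
  out
}

# Draw per-lesion rendering randomness from the current RNG stream.
# Always consumes the same number of draws per lesion (detection draw
# included) so per-scan streams have fixed layout.
.draw_scan <- function(dose_mGy, reconstruction, lesions, params) {
  n <- nrow(lesions)
  if (n == 0L) {
    return(data.frame(lesion_id = character(), p_label = numeric(),
                      u = numeric(), offset_row_mm = numeric(),
                      offset_col_mm = numeric(), radius_mm = numeric(),
                      intensity_target = numeric(), detected = logical(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(lesion_id = lesions$lesion_id,
                    p_label = NA_real_, u = NA_real_,
                    offset_row_mm = NA_real_, offset_col_mm = NA_real_,
                    radius_mm = NA_real_, intensity_target = NA_real_,
                    stringsAsFactors = FALSE)
  irange <- .intensity_range()
  for (i in seq_len(n)) {
    out$p_label[i] <- label_probability(dose_mGy, reconstruction,
                                        lesions$lesion_id[i], params)
    out$u[i] <- runif(1)
    off <- rnorm(2, 0, params$offset_scale_mm)
    out$offset_row_mm[i] <- off[1]
    out$offset_col_mm[i] <- off[2]
    out$radius_mm[i] <- lesions$max_diameter_mm[i] / 2 *
      size_scale(dose_mGy, params) * exp(rnorm(1, 0, params$size_jitter_sd))
    t <- intensity_scale(dose_mGy, params) +
      rnorm(1, 0, params$intensity_jitter_sd)
    out$intensity_target[i] <- min(irange[2] - 0.005,
                                   max(irange[1] + 0.005, t))
  }
  out$detected <- out$u < out$p_label
  out
}

.draws_to_spec <- function(draws, lesions, geometry) {
  keep <- draws[draws$detected, , drop = FALSE]
  les <- lesions[match(keep$lesion_id, lesions$lesion_id), , drop = FALSE]
  data.frame(lesion_id = keep$lesion_id,
             slice = les$slice,
             row = les$row + keep$offset_row_mm / geometry$pixel_size_mm,
             col = les$col + keep$offset_col_mm / geometry$pixel_size_mm,
             radius_px = keep$radius_mm / geometry$pixel_size_mm,
             intensity_target = keep$intensity_target,
             stringsAsFactors = FALSE)
}

#' Render one synthetic heatmap series
#'
#' Renders each detected lesion as a filled in-plane disc in a hot colour
#' (red 255, blue 60) on a neutral grey background (all channels 230), so a
#' blue-channel threshold of 100 separates label from background exactly.
#' Disc centre is the lesion centroid plus a random isotropic in-plane
#' offset; disc radius is the lesion radius scaled by a dose-dependent
#' factor that saturates at 1; the label colour's green channel is solved so
#' the inverted-grayscale intensity matches a dose-dependent target.
#'
#' @param design a [study_design()] providing the geometry.
#' @param dose_mGy,reconstruction acquisition condition of the scan.
#' @param detected_lesions a `lesion_spec` table (subset of the ground
#'   truth) of lesions that received a label.
#' @param params a [detection_params()] object.
#' @param seed integer seed; rendering is reproducible given the seed.
#' @return a `heatmap_series`; attribute `"rendered_pixels"` holds, per
#'   lesion, the 0-based (slice, row, col) coordinates of the rendered blob.
#' @export
render_heatmap <- function(design, dose_mGy, reconstruction, detected_lesions,
                           params = default_detection_params(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  check_lesion_bounds(detected_lesions, design)
  with_substream(seed, "render", {
    draws <- .draw_scan(dose_mGy, reconstruction, detected_lesions, params)
    draws$detected <- rep(TRUE, nrow(draws))  # caller states detection
    spec <- .draws_to_spec(draws, detected_lesions, design$geometry)
    .render_scan(design$geometry, spec,
                 acquisition = list(dose_mGy = dose_mGy,
                                    reconstruction = reconstruction))
  })
}

#' Simulate a complete phantom study
#'
#' Draws, for every scan of the design and every ground-truth lesion, a
#' Bernoulli "label produced" outcome from [label_probability()], renders
#' the corresponding heatmap overlays, and records every draw in a truth
#' table. Each scan consumes its own named random substream derived from
#' `seed`, so results are reproducible and adding scans to a design does not
#' perturb existing ones.
#'
#' @param design a [study_design()].
#' @param lesions a `lesion_spec` table; defaults to [default_lesions()].
#' @param params a [detection_params()] object.
#' @param seed top-level integer seed.
#' @param render if FALSE only the truth table is produced (fast path for
#'   calibration experiments).
#' @param output_dir if non-NULL, heatmaps are written as per-slice PNG
#'   files under `<dose>/<reconstruction>/<repetition>/slice_<k>.png` and a
#'   study manifest is returned instead of in-memory stacks. Required for
#'   large designs; in-memory return is intended for small test geometries.
#' @return a list of class `phantom_study` with elements `truth` (one row
#'   per scan x lesion), `design`, `lesions`, `seed`, and either `series`
#'   (named list of `heatmap_series`) or `manifest` (see [write_manifest()]).
#' @export
simulate_study <- function(design, lesions = default_lesions(design),
                           params = default_detection_params(), seed = 1L,
                           render = TRUE, output_dir = NULL) {
  stopifnot(inherits(design, "study_design"),
            inherits(params, "detection_params"))
  check_lesion_bounds(lesions, design)
  scans <- design_scans(design)
  truth <- vector("list", nrow(scans))
  series <- if (render && is.null(output_dir)) vector("list", nrow(scans))
  manifest_scans <- vector("list", nrow(scans))
  for (k in seq_len(nrow(scans))) {
    sc <- scans[k, ]
    res <- with_substream(seed, sc$scan_id, {
      draws <- .draw_scan(sc$dose_mGy, sc$reconstruction, lesions, params)
      ser <- NULL
      if (render) {
        spec <- .draws_to_spec(draws, lesions, design$geometry)
        ser <- .render_scan(design$geometry, spec,
                            acquisition = as.list(sc))
      }
      list(draws = draws, series = ser)
    })
    tr <- res$draws
    tr$scan_id <- sc$scan_id
    tr$dose_mGy <- sc$dose_mGy
    tr$reconstruction <- sc$reconstruction
    tr$repetition <- sc$repetition
    truth[[k]] <- tr[, c("scan_id", "dose_mGy", "reconstruction",
                         "repetition", "lesion_id", "p_label", "detected",
                         "offset_row_mm", "offset_col_mm", "radius_mm",
                         "intensity_target")]
    if (render && is.null(output_dir)) {
      series[[k]] <- res$series
    } else if (render) {
      rel <- file.path(sprintf("%05.2f", sc$dose_mGy), sc$reconstruction,
                       sc$repetition)
      write_heatmap_series(res$series, file.path(output_dir, rel))
      manifest_scans[[k]] <- data.frame(sc, path = rel,
                                        stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  out <- list(truth = truth, design = design, lesions = lesions, seed = seed)
  if (render && is.null(output_dir)) {
    names(series) <- scans$scan_id
    out$series <- series
  } else if (render) {
    man <- list(geometry = design$geometry,
                scans = do.call(rbind, manifest_scans),
                provenance = list(seed = seed,
                                  tool = "phantomqc",
                                  version =
                                    as.character(packageVersion("phantomqc"))))
    write_manifest(man, file.path(output_dir, "manifest.json"))
    out$manifest <- man
    out$output_dir <- output_dir
  }
  class(out) <- "phantom_study"
  out
}

#' Reader-model parameters for the simulated visual-grading arm
#'
#' Visibility of each lesion is Bernoulli with probability
#' `plogis(intercept + reader_shift + slope * log(dose))`; image quality is
#' an ordinal cut of a logistic latent score that rises with log-dose,
#' shifted down when the lesion was rated invisible (a reader who cannot see
#' the lesion tends to call the image poor for that task).
#'
#' @param n_readers number of simulated readers.
#' @param visibility named list per lesion of `c(intercept, slope)` on the
#'   logit scale with log-dose covariate.
#' @param reader_shift per-reader intercept shifts (length `n_readers`).
#' @param quality list with `slope`, per-lesion `lesion_shift`, cutpoints
#'   `cut12`, `cut23`, and `invisible_penalty` subtracted from the latent
#'   score when the lesion is invisible.
#' @return an object of class `reader_params`.
#' @export
reader_params <- function(n_readers = 5,
                          visibility = list(
                            MCA = c(intercept = 8.9, slope = 7.2),
                            ACoA = c(intercept = 4.8, slope = 5),
                            BA = c(intercept = 1.8, slope = 5)),
                          reader_shift = seq(-0.4, 0.4,
                                             length.out = n_readers),
                          quality = list(slope = 1.8,
                                         lesion_shift = c(MCA = 1.2,
                                                          ACoA = 0,
                                                          BA = -0.3),
                                         cut12 = 0, cut23 = 2.2,
                                         invisible_penalty = 1.5)) {
  stopifnot(n_readers >= 1, length(reader_shift) == n_readers)
  structure(list(n_readers = as.integer(n_readers), visibility = visibility,
                 reader_shift = reader_shift, quality = quality),
            class = "reader_params")
}

#' Simulate the reader visual-grading experiment
#'
#' One response per reader x scan x lesion: visibility (yes/no) and an image
#' quality rating on the ordinal 1 (poor) / 2 (intermediate) / 3 (good)
#' scale. Each reader x scan pair draws from its own named substream.
#'
#' @param design a [study_design()].
#' @param lesions a `lesion_spec` table.
#' @param rparams a [reader_params()] object.
#' @param seed top-level integer seed.
#' @return data.frame with columns `reader_id`, `scan_id`, `dose_mGy`,
#'   `reconstruction`, `repetition`, `lesion_id`, `visible` ("yes"/"no"),
#'   `quality` (1:3).
#' @export
simulate_readers <- function(design, lesions = default_lesions(design),
                             rparams = reader_params(), seed = 1L) {
  stopifnot(inherits(design, "study_design"),
            inherits(rparams, "reader_params"))
  miss <- setdiff(lesions$lesion_id, names(rparams$visibility))
  if (length(miss)) stop("no visibility model for lesion(s): ",
                         paste(miss, collapse = ", "))
  scans <- design_scans(design)
  q <- rparams$quality
  out <- vector("list", rparams$n_readers * nrow(scans))
  k <- 0L
  for (r in seq_len(rparams$n_readers)) {
    rid <- sprintf("R%d", r)
    for (s in seq_len(nrow(scans))) {
      sc <- scans[s, ]
      resp <- with_substream(seed, paste(rid, sc$scan_id), {
        vis <- logical(nrow(lesions))
        qual <- integer(nrow(lesions))
        for (i in seq_len(nrow(lesions))) {
          vp <- rparams$visibility[[lesions$lesion_id[i]]]
          p <- plogis(vp[["intercept"]] + rparams$reader_shift[r] +
                        vp[["slope"]] * log(sc$dose_mGy))
          vis[i] <- runif(1) < p
          lshift <- if (lesions$lesion_id[i] %in% names(q$lesion_shift))
            q$lesion_shift[[lesions$lesion_id[i]]] else 0
          z <- lshift + q$slope * log(sc$dose_mGy) + stats::rlogis(1)
          if (!vis[i]) z <- z - q$invisible_penalty
          qual[i] <- 1L + (z >= q$cut12) + (z >= q$cut23)
        }
        data.frame(reader_id = rid, scan_id = sc$scan_id,
                   dose_mGy = sc$dose_mGy,
                   reconstruction = sc$reconstruction,
                   repetition = sc$repetition,
                   lesion_id = lesions$lesion_id,
                   visible = ifelse(vis, "yes", "no"),
                   quality = qual, stringsAsFactors = FALSE)
      })
      k <- k + 1L
      out[[k]] <- resp
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
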