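#' Lesion specifications
#'
#' A lesion specification table holds one row per ground-truth lesion with
#' its identifier, centroid in 0-based voxel coordinates (slice, row, col)
#' and maximum diameter in mm.
#'
#' @param lesion_id character identifiers, e.g. `"MCA"`.
#' @param slice,row,col 0-based voxel coordinates of the lesion centroid.
#' @param max_diameter_mm maximum lesion diameter in mm; must be > 0.
#' @return a data.frame of class `lesion_spec`.
#' @export
lesion_spec <- function(lesion_id, slice, row, col, max_diameter_mm) {
  stopifnot(length(lesion_id) == length(slice),
            length(slice) == length(row),
            length(row) == length(col),
            length(col) == length(max_diameter_mm))
  if (any(max_diameter_mm <= 0)) stop("max_diameter_mm must be > 0")
  if (anyDuplicated(lesion_id)) stop("lesion_id values must be unique")
  out <- data.frame(lesion_id = as.character(lesion_id),
                    slice = as.numeric(slice), row = as.numeric(row),
                    col = as.numeric(col),
                    max_diameter_mm = as.numeric(max_diameter_mm),
                    stringsAsFactors = FALSE)
  class(out) <- c("lesion_spec", "data.frame")
  out
}

#' Default three-aneurysm phantom ground truth
#'
#' Three saccular aneurysms as in the anthropomorphic head phantom: middle
#' cerebral artery (MCA, 4 mm), anterior communicating artery (ACoA, 4 mm)
#' and basilar artery (BA, 2 mm). Centroid placement is the package's own
#' choice; in-plane separations are tens of mm so a matching tolerance of
#' 10 mm can never cross-assign labels.
#'
#' @param design optionally, a [study_design()] whose geometry the centroids
#'   must respect (used for bounds checking only).
#' @return a `lesion_spec` table with rows MCA, ACoA, BA.
#' @export
default_lesions <- function(design = NULL) {
  les <- lesion_spec(lesion_id = c("MCA", "ACoA", "BA"),
                     slice = c(2, 3, 4),
                     row = c(200, 170, 260),
                     col = c(160, 300, 230),
                     max_diameter_mm = c(4, 4, 2))
  if (!is.null(design)) check_lesion_bounds(les, design)
  les
}

check_lesion_bounds <- function(lesions, design) {
  g <- design$geometry
  ok <- lesions$slice >= 0 & lesions$slice < g$n_slices &
    lesions$row >= 0 & lesions$row < g$matrix_size &
    lesions$col >= 0 & lesions$col < g$matrix_size
  if (!all(ok)) stop("lesion centroid(s) outside image bounds: ",
                     paste(lesions$lesion_id[!ok], collapse = ", "))
  invisible(TRUE)
}

#' Construct a factorial acquisition design
#'
#' Describes a dose x reconstruction x repetition phantom study together with
#' its image geometry and per-dose tube parameters.
#'
#' @param doses_mGy strictly increasing CTDIvol values in mGy (all > 0).
#' @param reconstructions character vector of reconstruction method names.
#' @param repetitions repeated acquisitions per dose x reconstruction cell.
#' @param matrix_size in-plane image matrix size (square).
#' @param pixel_size_mm in-plane pixel size in mm.
#' @param slice_thickness_mm reconstructed slice thickness in mm.
#' @param n_slices number of slices per reconstructed stack.
#' @param tube data.frame with one row per dose: `kVp`, `mAs`, `rotation_s`.
#'   If NULL a constant 120 kVp / NA mAs / 0.5 s table is used.
#' @return an object of class `study_design`.
#' @export
study_design <- function(doses_mGy, reconstructions, repetitions,
                         matrix_size = 512L, pixel_size_mm = 0.41,
                         slice_thickness_mm = 0.75, n_slices = 6L,
                         tube = NULL) {
  doses_mGy <- as.numeric(doses_mGy)
  if (any(doses_mGy <= 0)) stop("all doses must be > 0")
  if (is.unsorted(doses_mGy, strictly = TRUE))
    stop("doses must be strictly increasing")
  if (repetitions < 1) stop("repetitions must be >= 1")
  if (pixel_size_mm <= 0 || slice_thickness_mm <= 0)
    stop("voxel spacing must be positive")
  reconstructions <- as.character(reconstructions)
  if (anyDuplicated(reconstructions)) stop("duplicate reconstruction names")
  if (is.null(tube)) {
    tube <- data.frame(dose_mGy = doses_mGy, kVp = 120, mAs = NA_real_,
                       rotation_s = 0.5)
  }
  stopifnot(nrow(tube) == length(doses_mGy))
  structure(list(
    doses_mGy = doses_mGy,
    reconstructions = reconstructions,
    repetitions = as.integer(repetitions),
    geometry = list(matrix_size = as.integer(matrix_size),
                    pixel_size_mm = pixel_size_mm,
                    slice_thickness_mm = slice_thickness_mm,
                    n_slices = as.integer(n_slices)),
    tube = tube
  ), class = "study_design")
}

#' The default 126-scan acquisition design
#'
#' 21 CTDIvol levels from 0.47 to 20.09 mGy, iterative reconstruction (IR)
#' and filtered back projection (FBP), three repetitions per cell: 126 scans
#' in total. Tube voltage is 120 kVp throughout; the lowest dose uses a
#' 0.3 s rotation, all others 0.5 s; tube current-time products rise with
#' dose. Geometry: 512 x 512 matrix, 0.41 mm pixels, 0.75 mm slices.
#'
#' @return a `study_design`.
#' @export
#' @examples
#' d <- make_default_design()
#' n_scans(d)  # 126
make_default_design <- function() {
  doses <- c(0.47, 1.01, 2.02, 3.00, 4.01, 5.02, 6.03, 7.05, 8.06, 9.07,
             10.08, 11.09, 12.11, 13.04, 14.06, 15.07, 16.04, 17.05, 18.07,
             19.08, 20.09)
  mas <- c(7, 15, 30, 44, 59, 74, 89, 104, 119, 134, 149, 164, 179, 193,
           208, 223, 238, 253, 268, 283, 298)
  tube <- data.frame(dose_mGy = doses, kVp = 120, mAs = mas,
                     rotation_s = c(0.3, rep(0.5, 20)))
  study_design(doses_mGy = doses, reconstructions = c("IR", "FBP"),
               repetitions = 3L, matrix_size = 512L, pixel_size_mm = 0.41,
               slice_thickness_mm = 0.75, n_slices = 6L, tube = tube)
}

#' Total number of scans in a design
#' @param design a `study_design`.
#' @return integer scan count (doses x reconstructions x repetitions).
#' @export
n_scans <- function(design) {
  length(design$doses_mGy) * length(design$reconstructions) *
    design$repetitions
}

#' Enumerate the scans of a design
#'
#' @param design a `study_design`.
#' @return data.frame with one row per scan: `scan_id`, `dose_mGy`,
#'   `reconstruction`, `repetition`. Scan ids look like `"d05.02_IR_r2"` and
#'   are unique within a design.
#' @export
design_scans <- function(design) {
  grid <- expand.grid(repetition = seq_len(design$repetitions),
                      reconstruction = design$reconstructions,
                      dose_mGy = design$doses_mGy,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("dose_mGy", "reconstruction", "repetition")]
  grid <- grid[order(grid$dose_mGy, grid$reconstruction, grid$repetition), ]
  rownames(grid) <- NULL
  grid$scan_id <- sprintf("d%05.2f_%s_r%d", grid$dose_mGy,
                          grid$reconstruction, grid$repetition)
  grid[, c("scan_id", "dose_mGy", "reconstruction", "repetition")]
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(paste0("<study_design> %d doses (%.2f-%.2f mGy) x %d ",
                     "reconstructions (%s) x %d repetitions = %d scans\n"),
              length(x$doses_mGy), min(x$doses_mGy), max(x$doses_mGy),
              length(x$reconstructions),
              paste(x$reconstructions, collapse = ", "),
              x$repetitions, n_scans(x)))
  g <- x$geometry
  cat(sprintf("  geometry: %dx%d x %d slices, %.2f mm pixels, %.2f mm slices\n",
              g$matrix_size, g$matrix_size, g$n_slices, g$pixel_size_mm,
              g$slice_thickness_mm))
  invisible(x)
}
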