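#' Recode image-quality ratings by visibility
#'
#' A quality rating of 1 (poor) is recoded to 0 when the reader also rated
#' the lesion as not visible; all other ratings pass through unchanged.
#' Vectorised.
#'
#' @param visible `"yes"`/`"no"` (the 1=yes/2=no response encoding is
#'   normalised by [normalize_visible()]).
#' @param quality_raw ordinal rating in {1, 2, 3}.
#' @return recoded quality in {0, 1, 2, 3}.
#' @export
#' @examples
#' recode_quality("no", 1)   # 0
#' recode_quality("yes", 1)  # 1
recode_quality <- function(visible, quality_raw) {
  visible <- normalize_visible(visible)
  if (!all(quality_raw %in% c(1, 2, 3)))
    stop("quality_raw must be in {1, 2, 3}")
  ifelse(quality_raw == 1 & visible == "no", 0, quality_raw)
}

#' Normalise visibility encodings
#'
#' Accepts `"yes"`/`"no"` (any case), logical, or the reading-experiment
#' encoding 1 = yes / 2 = no; returns `"yes"`/`"no"`.
#'
#' @param visible vector to normalise.
#' @return character vector of `"yes"`/`"no"`.
#' @export
normalize_visible <- function(visible) {
  if (is.logical(visible)) return(ifelse(visible, "yes", "no"))
  if (is.numeric(visible)) {
    if (!all(visible %in% c(1, 2)))
      stop("numeric visibility must use the 1 = yes / 2 = no encoding")
    return(ifelse(visible == 1, "yes", "no"))
  }
  v <- tolower(as.character(visible))
  if (!all(v %in% c("yes", "no")))
    stop("visibility must be yes/no (or 1/2, or logical)")
  v
}

#' Visibility rate for one lesion
#'
#' @param responses reader-response data.frame with columns `lesion_id` and
#'   `visible`.
#' @param lesion_id which lesion to summarise.
#' @return data.frame with `positive_count`, `total`, `percent` and
#'   `percent_1dp`.
#' @export
#' @examples
#' # 629 of 630 positive responses -> 99.8%
visibility_rate <- function(responses, lesion_id) {
  sub <- responses[responses$lesion_id == lesion_id, ]
  if (nrow(sub) == 0) stop("no responses for lesion ", lesion_id)
  v <- normalize_visible(sub$visible)
  pos <- sum(v == "yes")
  pct <- 100 * pos / nrow(sub)
  data.frame(lesion_id = lesion_id, positive_count = pos,
             total = nrow(sub), percent = pct,
             percent_1dp = round(pct, 1), stringsAsFactors = FALSE)
}

#' Aggregate recoded image-quality ratings over the design grid
#'
#' Two-stage mean, mirroring the visual-grading analysis: recoded quality is
#' first averaged within each reader across the repetitions of a lesion x
#' dose x reconstruction cell, then averaged across readers. The error bar
#' is the standard error of the mean across readers.
#'
#' @param responses reader-response data.frame (`reader_id`, `scan_id`,
#'   `dose_mGy`, `reconstruction`, `repetition`, `lesion_id`, `visible`,
#'   `quality`).
#' @param design the [study_design()].
#' @return data.frame per lesion x dose x reconstruction with `n_readers`,
#'   `mean_quality` (across readers of within-reader means), `sem_quality`
#'   and the per-reader means as a semicolon-joined column.
#' @export
aggregate_quality <- function(responses, design) {
  scans <- design_scans(design)
  readers <- sort(unique(responses$reader_id))
  lesions <- sort(unique(responses$lesion_id))
  expected <- nrow(scans) * length(readers) * length(lesions)
  key <- paste(responses$reader_id, responses$scan_id, responses$lesion_id)
  want <- as.vector(outer(
    as.vector(outer(readers, scans$scan_id, paste)), lesions, paste))
  gaps <- setdiff(want, key)
  if (length(gaps))
    stop("reader responses incomplete; ", length(gaps),
         " missing reader/scan/lesion combination(s), e.g. ",
         paste(utils::head(gaps, 3), collapse = "; "))
  if (nrow(responses) != expected)
    stop("duplicate reader responses present")
  responses$q_recoded <- recode_quality(responses$visible,
                                        responses$quality)
  grid <- expand.grid(lesion_id = lesions, dose_mGy = design$doses_mGy,
                      reconstruction = design$reconstructions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- responses[responses$lesion_id == grid$lesion_id[i] &
                        responses$dose_mGy == grid$dose_mGy[i] &
                        responses$reconstruction == grid$reconstruction[i], ]
    per_reader <- vapply(readers, function(r)
      mean(cell$q_recoded[cell$reader_id == r]), 0)
    data.frame(grid[i, ], n_readers = length(readers),
               mean_quality = mean(per_reader),
               sem_quality = sd(per_reader) / sqrt(length(readers)),
               reader_means = paste(signif(per_reader, 10), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Reader-arm summary
#'
#' Visibility rates per lesion plus the aggregated quality grid.
#'
#' @inheritParams aggregate_quality
#' @return list with `visibility` (per-lesion rates) and `quality`
#'   (the [aggregate_quality()] grid).
#' @export
reader_summary <- function(responses, design) {
  lesions <- sort(unique(responses$lesion_id))
  vis <- do.call(rbind, lapply(lesions, function(l)
    visibility_rate(responses, l)))
  list(visibility = vis, quality = aggregate_quality(responses, design))
}
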