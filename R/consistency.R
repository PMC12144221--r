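#' Per-lesion detection counts over the dose grid
#'
#' Tallies matched (true positive) labels per lesion x dose x reconstruction
#' cell. Every cell of the design must be covered by the detection records;
#' missing scans raise a completeness error naming them.
#'
#' @param detections detection records from [match_study()].
#' @param design the [study_design()] the records belong to.
#' @return data.frame with columns `lesion_id`, `dose_mGy`,
#'   `reconstruction`, `n_detected`, `n_repetitions`.
#' @export
detection_table <- function(detections, design) {
  scans <- design_scans(design)
  missing <- setdiff(scans$scan_id, unique(detections$scan_id))
  if (length(missing))
    stop("detection records incomplete; missing scan id(s): ",
         paste(missing, collapse = ", "))
  lesions <- sort(unique(detections$lesion_id))
  grid <- expand.grid(lesion_id = lesions, dose_mGy = design$doses_mGy,
                      reconstruction = design$reconstructions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$n_detected <- mapply(function(l, d, r) {
    sum(detections$matched[detections$lesion_id == l &
                             detections$dose_mGy == d &
                             detections$reconstruction == r])
  }, grid$lesion_id, grid$dose_mGy, grid$reconstruction)
  grid$n_repetitions <- design$repetitions
  if (any(grid$n_detected > grid$n_repetitions))
    stop("cell count exceeds repetitions; duplicated detection records?")
  grid <- grid[order(grid$lesion_id, grid$reconstruction, grid$dose_mGy), ]
  rownames(grid) <- NULL
  grid
}

#' Detection rate as a percentage
#'
#' @param count number of positive outcomes (0 <= count <= n_total).
#' @param n_total denominator (> 0).
#' @return data.frame with `count`, `total`, `percent` (full precision) and
#'   `percent_1dp` (rounded to one decimal, the form used in reports).
#' @export
#' @examples
#' detection_rate(117, 126)$percent_1dp  # 92.9
detection_rate <- function(count, n_total) {
  if (any(n_total <= 0)) stop("n_total must be > 0")
  if (any(count < 0 | count > n_total))
    stop("count must lie in [0, n_total]")
  pct <- 100 * count / n_total
  data.frame(count = count, total = n_total, percent = pct,
             percent_1dp = round(pct, 1))
}

#' Scan-level triage summary
#'
#' The phantom is lesion-positive by construction, so every triage-positive
#' scan is a scan-level true positive and every negative summary report is a
#' false negative.
#'
#' @param triage triage table from [match_study()].
#' @return data.frame with one row: `n_scans`, `n_positive`, `n_negative`,
#'   `tp_percent`, `fn_percent` (full precision) and their `_1dp` roundings.
#' @export
triage_summary <- function(triage) {
  n <- nrow(triage)
  if (n == 0) stop("empty triage table")
  npos <- sum(triage$decision == "positive")
  nneg <- n - npos
  data.frame(n_scans = n, n_positive = npos, n_negative = nneg,
             tp_percent = 100 * npos / n, fn_percent = 100 * nneg / n,
             tp_percent_1dp = round(100 * npos / n, 1),
             fn_percent_1dp = round(100 * nneg / n, 1))
}

.cv <- function(x, sd_type = "sample") {
  if (sd_type == "sample") sd(x) / mean(x)
  else sqrt(mean((x - mean(x))^2)) / mean(x)
}

#' Reproducibility of label size / intensity as coefficient of variation
#'
#' Only fully reproducible cells contribute: a dose x reconstruction cell
#' qualifies for a lesion only if **all** repetitions produced a matched
#' label. Two pooling schemes are computed: `"per_dose"` (default) takes the
#' CV across repetitions within each qualifying dose and averages those CVs
#' across qualifying doses; `"pooled"` computes a single CV over all values
#' from qualifying cells. The sample (n-1) standard deviation is used by
#' default.
#'
#' @param detections detection records from [match_study()].
#' @param design the [study_design()].
#' @param measure `"size"` or `"intensity"`.
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return data.frame per lesion x reconstruction with `n_qualifying_doses`,
#'   `cv_per_dose`, `cv_pooled` and `computable` (FALSE, with NA CVs, when
#'   no cell qualifies).
#' @export
reproducibility_cv <- function(detections, design,
                               measure = c("size", "intensity"),
                               sd_type = c("sample", "population")) {
  measure <- match.arg(measure)
  sd_type <- match.arg(sd_type)
  lesions <- sort(unique(detections$lesion_id))
  out <- expand.grid(lesion_id = lesions,
                     reconstruction = design$reconstructions,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$measure <- measure
  out$n_qualifying_doses <- 0L
  out$cv_per_dose <- NA_real_
  out$cv_pooled <- NA_real_
  out$computable <- FALSE
  for (i in seq_len(nrow(out))) {
    sub <- detections[detections$lesion_id == out$lesion_id[i] &
                        detections$reconstruction == out$reconstruction[i], ]
    per_dose_cv <- c(); pooled_vals <- c()
    for (d in design$doses_mGy) {
      cell <- sub[sub$dose_mGy == d, ]
      if (nrow(cell) == design$repetitions && all(cell$matched)) {
        vals <- cell[[measure]]
        per_dose_cv <- c(per_dose_cv, .cv(vals, sd_type))
        pooled_vals <- c(pooled_vals, vals)
      }
    }
    if (length(per_dose_cv)) {
      out$n_qualifying_doses[i] <- length(per_dose_cv)
      out$cv_per_dose[i] <- mean(per_dose_cv)
      out$cv_pooled[i] <- .cv(pooled_vals, sd_type)
      out$computable[i] <- TRUE
    }
  }
  out
}

#' Per-cell label size and intensity summaries
#'
#' Mean over the matched repetitions per lesion x dose x reconstruction
#' cell; the individual repeat values are retained as a semicolon-joined
#' column. Cells with no matched label yield NA means, never zeros.
#'
#' @param detections detection records from [match_study()].
#' @param design the [study_design()].
#' @return data.frame per lesion x dose x reconstruction with `n_matched`,
#'   `mean_size`, `mean_intensity`, `size_values`, `intensity_values`.
#' @export
label_summary <- function(detections, design) {
  lesions <- sort(unique(detections$lesion_id))
  grid <- expand.grid(lesion_id = lesions, dose_mGy = design$doses_mGy,
                      reconstruction = design$reconstructions,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cell <- detections[detections$lesion_id == grid$lesion_id[i] &
                         detections$dose_mGy == grid$dose_mGy[i] &
                         detections$reconstruction ==
                           grid$reconstruction[i] &
                         detections$matched, , drop = FALSE]
    data.frame(grid[i, ], n_matched = nrow(cell),
               mean_size = if (nrow(cell)) mean(cell$size) else NA_real_,
               mean_intensity = if (nrow(cell)) mean(cell$intensity)
               else NA_real_,
               size_values = paste(signif(cell$size, 10), collapse = ";"),
               intensity_values = paste(signif(cell$intensity, 10),
                                        collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Full consistency report
#'
#' Aggregates a matched study into the report consumed by the pipeline:
#' per-lesion totals and rates (overall and per reconstruction), the triage
#' summary, per-cell detection counts, label summaries and CVs for size and
#' intensity under both pooling schemes.
#'
#' @param detections,triage outputs of [match_study()].
#' @param design the [study_design()].
#' @return a list of class `consistency_report`.
#' @export
consistency_report <- function(detections, triage, design) {
  tab <- detection_table(detections, design)
  lesions <- sort(unique(detections$lesion_id))
  nsc <- n_scans(design)
  totals <- do.call(rbind, lapply(lesions, function(l) {
    tot <- sum(tab$n_detected[tab$lesion_id == l])
    r <- detection_rate(tot, nsc)
    cbind(data.frame(lesion_id = l, stringsAsFactors = FALSE), r)
  }))
  per_recon <- do.call(rbind, lapply(lesions, function(l) {
    do.call(rbind, lapply(design$reconstructions, function(rc) {
      tot <- sum(tab$n_detected[tab$lesion_id == l &
                                  tab$reconstruction == rc])
      r <- detection_rate(tot, nsc / length(design$reconstructions))
      cbind(data.frame(lesion_id = l, reconstruction = rc,
                       stringsAsFactors = FALSE), r)
    }))
  }))
  structure(list(
    lesion_totals = totals,
    lesion_totals_by_reconstruction = per_recon,
    total_labels = sum(totals$count),
    triage = triage_summary(triage),
    detection_table = tab,
    label_summary = label_summary(detections, design),
    cv_size = reproducibility_cv(detections, design, "size"),
    cv_intensity = reproducibility_cv(detections, design, "intensity")
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("<consistency_report>\n")
  cat(sprintf("  %d labels across %d scans; triage: %.1f%% positive / %.1f%% negative\n",
              x$total_labels, x$triage$n_scans, x$triage$tp_percent_1dp,
              x$triage$fn_percent_1dp))
  for (i in seq_len(nrow(x$lesion_totals))) {
    cat(sprintf("  %-5s %3d labels (%.1f%%)\n", x$lesion_totals$lesion_id[i],
                x$lesion_totals$count[i], x$lesion_totals$percent_1dp[i]))
  }
  cv <- x$cv_size[x$cv_size$computable, ]
  if (nrow(cv)) {
    cat("  size CV (mean of per-dose CVs over fully reproducible cells):\n")
    for (i in seq_len(nrow(cv)))
      cat(sprintf("    %-5s %-4s %.2f\n", cv$lesion_id[i],
                  cv$reconstruction[i], round(cv$cv_per_dose[i], 2)))
  }
  invisible(x)
}
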