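#' Mann-Whitney U test (two-sided)
#'
#' Rank-sum comparison of two independent samples. In `"exact"` mode the
#' p-value comes from the full permutation distribution of U (no ties,
#' feasible group sizes); `"approximate"` uses the normal approximation with
#' continuity correction and tie-corrected variance. The default `"auto"`
#' rule uses the exact distribution when `n_x + n_y <= 20` and the data
#' contain no ties, matching common practice. When exact mode is requested
#' but ties are present, the test falls back to the approximation and says
#' so in the `note` field.
#'
#' @param x,y non-empty numeric vectors.
#' @param mode `"auto"`, `"exact"` or `"approximate"`.
#' @return list with `U` (the U statistic for `x`), `p` (two-sided),
#'   `method`, `note` (NULL or a fallback message), `n_x`, `n_y`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # 0.1
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approximate")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- any(duplicated(c(x, y)))
  note <- NULL
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= 20) && !ties,
                  exact = TRUE,
                  approximate = FALSE)
  if (exact && ties) {
    exact <- FALSE
    note <- "ties present; exact mode fell back to the normal approximation"
  }
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact, correct = TRUE,
                                     alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal approximation",
       note = note, n_x = length(x), n_y = length(y))
}

#' Bonferroni adjustment
#'
#' Each p-value is multiplied by the family size `m` and capped at 1.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param m family size; must be at least `length(p_values)`.
#' @return adjusted p-values.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values)))
    stop("p-values must lie in [0, 1]")
  if (m < length(p_values)) stop("m must be >= number of p-values")
  p.adjust(p_values, method = "bonferroni", n = m)
}

#' Pairwise family of Mann-Whitney comparisons
#'
#' Compares a per-cell measure between groups, pairwise within a stratum,
#' with Bonferroni correction over the pairs of each stratum. The unit of
#' analysis is the per-cell mean across repetitions (one value per dose), so
#' a comparison between two lesions within one reconstruction uses up to one
#' value per dose per group; cells without a value (no matched label) are
#' dropped.
#'
#' @param measures data.frame with one row per group x stratum x dose cell
#'   and a numeric value column (e.g. [label_summary()] output or the
#'   [aggregate_quality()] grid).
#' @param value name of the value column (e.g. `"mean_size"`,
#'   `"mean_quality"`).
#' @param group column defining the compared groups (e.g. `"lesion_id"`).
#' @param stratum column defining the family strata (e.g.
#'   `"reconstruction"`); use NULL for a single family.
#' @param alpha significance level applied to adjusted p-values.
#' @param drop_empty if FALSE (default) a pair with an empty group is an
#'   error; if TRUE such pairs are silently omitted and the family size `m`
#'   counts only the comparisons actually performed (a condition under which
#'   a lesion never receives a label has no measurement to compare).
#' @return data.frame with one row per pair: stratum, the two group labels,
#'   group sizes, `U`, `p_raw`, `m`, `p_adjusted`, `significant`, `method`.
#'   With `drop_empty = TRUE` the result may have zero rows.
#' @export
compare_family <- function(measures, value, group, stratum = NULL,
                           alpha = 0.05, drop_empty = FALSE) {
  stopifnot(value %in% names(measures), group %in% names(measures))
  strata <- if (is.null(stratum)) list(all = measures)
  else split(measures, measures[[stratum]])
  out <- lapply(names(strata), function(sname) {
    sub <- strata[[sname]]
    groups <- sort(unique(sub[[group]]))
    if (length(groups) < 2) return(NULL)
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      gx <- sub[[value]][sub[[group]] == pr[1]]
      gy <- sub[[value]][sub[[group]] == pr[2]]
      gx <- gx[!is.na(gx)]; gy <- gy[!is.na(gy)]
      if (length(gx) < 1 || length(gy) < 1) {
        if (drop_empty) return(NULL)
        stop("group with no observations in comparison ",
             pr[1], " vs ", pr[2])
      }
      mw <- mann_whitney_u(gx, gy)
      data.frame(stratum = sname, group_x = pr[1], group_y = pr[2],
                 n_x = mw$n_x, n_y = mw$n_y, U = mw$U, p_raw = mw$p,
                 method = mw$method, stringsAsFactors = FALSE)
    })
    rows <- do.call(rbind, rows)
    if (is.null(rows)) return(NULL)
    rows$m <- nrow(rows)
    rows$p_adjusted <- bonferroni(rows$p_raw, nrow(rows))
    rows
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    if (!drop_empty) stop("need at least two groups to compare")
    out <- data.frame(stratum = character(), group_x = character(),
                      group_y = character(), n_x = integer(),
                      n_y = integer(), U = numeric(), p_raw = numeric(),
                      m = integer(), p_adjusted = numeric(),
                      significant = logical(), method = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out$significant <- out$p_adjusted < alpha
  rownames(out) <- NULL
  out[, c("stratum", "group_x", "group_y", "n_x", "n_y", "U", "p_raw",
          "m", "p_adjusted", "significant", "method")]
}
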