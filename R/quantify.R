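#' Segment positive label pixels by blue-channel threshold
#'
#' A voxel belongs to a label iff its blue channel value is less than or
#' equal to the threshold ("maximum threshold" semantics: 100 is the largest
#' admissible blue value for a positive label pixel).
#'
#' @param series a [heatmap_series()] or an integer (slice, row, col, 3)
#'   array with values in 0..255.
#' @param blue_threshold inclusive upper bound on the blue channel for
#'   positive pixels; default 100.
#' @return a logical array with the spatial shape of the series.
#' @export
segment_label_mask <- function(series, blue_threshold = 100) {
  px <- if (inherits(series, "heatmap_series")) series$pixels else series
  d <- dim(px)
  if (is.null(d) || length(d) != 4L || d[4] != 3L)
    stop("input is not an RGB stack: expected a (slice, row, col, 3) array")
  if (blue_threshold < 0 || blue_threshold > 255)
    stop("blue_threshold must lie in [0, 255]")
  mask <- px[, , , 3L, drop = FALSE] <= blue_threshold
  dim(mask) <- d[1:3]
  mask
}

# neighbourhood offset tables (excluding the origin)
.conn_offsets <- function(connectivity) {
  if (connectivity == 26) {
    g <- expand.grid(ds = -1:1, dr = -1:1, dc = -1:1)
    g <- g[!(g$ds == 0 & g$dr == 0 & g$dc == 0), ]
  } else if (connectivity == 8) {
    g <- expand.grid(ds = 0, dr = -1:1, dc = -1:1)
    g <- g[!(g$dr == 0 & g$dc == 0), ]
  } else if (connectivity == 4) {
    g <- data.frame(ds = 0, dr = c(-1, 1, 0, 0), dc = c(0, 0, -1, 1))
  } else stop("connectivity must be one of 4, 8 (in-plane) or 26 (volumetric)")
  as.matrix(g)
}

#' Extract connected label components from a mask
#'
#' Groups positive voxels into maximal connected components under the chosen
#' connectivity (volumetric 26-neighbourhood by default, so a label spanning
#' adjacent slices is one component; in-plane 8 or 4 available). Adjacency
#' is resolved by vectorised neighbour matching and the components of the
#' resulting voxel graph.
#'
#' @param mask logical (slice, row, col) array, e.g. from
#'   [segment_label_mask()].
#' @param connectivity 4, 8 (both in-plane) or 26 (volumetric, default).
#' @return a list of components ordered by (min slice, min row, min col);
#'   each is a list with `pixel_coords` (matrix of 0-based slice/row/col),
#'   `n_pixels` and `centroid_vox` (0-based, fractional). An empty mask
#'   yields an empty list.
#' @export
extract_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L)
    stop("mask must be a 3-D logical array (slice, row, col)")
  idx <- which(mask)
  if (length(idx) == 0L) return(list())
  coo <- arrayInd(idx, d)  # 1-based (slice, row, col)
  off <- .conn_offsets(connectivity)
  # linear key of each positive voxel; neighbours looked up with match()
  key <- (as.numeric(coo[, 1]) - 1) +
    d[1] * ((coo[, 2] - 1) + as.numeric(d[2]) * (coo[, 3] - 1))
  edges <- vector("list", nrow(off))
  for (j in seq_len(nrow(off))) {
    ns <- coo[, 1] + off[j, 1]; nr <- coo[, 2] + off[j, 2]
    nc <- coo[, 3] + off[j, 3]
    valid <- ns >= 1 & ns <= d[1] & nr >= 1 & nr <= d[2] &
      nc >= 1 & nc <= d[3]
    nkey <- (as.numeric(ns) - 1) + d[1] * ((nr - 1) + as.numeric(d[2]) * (nc - 1))
    hit <- match(nkey, key)
    ok <- valid & !is.na(hit)
    if (any(ok)) edges[[j]] <- cbind(which(ok), hit[ok])
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  comps <- lapply(split(seq_along(idx), memb), function(ii) {
    pc <- coo[ii, , drop = FALSE] - 1L  # 0-based
    colnames(pc) <- c("slice", "row", "col")
    list(pixel_coords = pc, n_pixels = nrow(pc),
         centroid_vox = colMeans(pc))
  })
  ord <- order(vapply(comps, function(cp) min(cp$pixel_coords[, "slice"]), 0),
               vapply(comps, function(cp) min(cp$pixel_coords[, "row"]), 0),
               vapply(comps, function(cp) min(cp$pixel_coords[, "col"]), 0))
  unname(comps[ord])
}

#' Physical size of a label component
#'
#' Default ("area") convention: number of positive pixels times the squared
#' pixel size, in mm^2. The literal-linear convention (pixel count times
#' pixel size) is selectable; both are carried through the pipeline output.
#'
#' @param component a component from [extract_components()], or a pixel
#'   count.
#' @param pixel_size_mm in-plane pixel size in mm (> 0).
#' @param convention `"area"` (default) or `"linear"`.
#' @return size in mm^2 (area) or mm-weighted pixel count (linear).
#' @export
component_size <- function(component, pixel_size_mm,
                           convention = c("area", "linear")) {
  convention <- match.arg(convention)
  if (pixel_size_mm <= 0) stop("pixel_size_mm must be > 0")
  n <- if (is.list(component)) component$n_pixels else as.numeric(component)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("component must contain at least one pixel")
  if (convention == "area") n * pixel_size_mm^2 else n * pixel_size_mm
}

#' Mean inverted-grayscale intensity of a label component
#'
#' Each component pixel's RGB value is converted to grayscale, inverted and
#' normalised to `[0, 1]`; the component intensity is the mean:
#' `mean((255 - gray) / 255)`. Grayscale defaults to the ITU-R BT.601 luma
#' (0.299 R + 0.587 G + 0.114 B), computed in floating point; an
#' equal-weights mean is available.
#'
#' @param component a component from [extract_components()].
#' @param series the [heatmap_series()] the component was extracted from.
#' @param gray `"bt601"` (default) or `"mean"`.
#' @return intensity in `[0, 1]`.
#' @export
component_intensity <- function(component, series,
                                gray = c("bt601", "mean")) {
  gray <- match.arg(gray)
  px <- if (inherits(series, "heatmap_series")) series$pixels else series
  d <- dim(px)
  pc <- component$pixel_coords
  if (any(pc[, 1] < 0 | pc[, 1] >= d[1] | pc[, 2] < 0 | pc[, 2] >= d[2] |
          pc[, 3] < 0 | pc[, 3] >= d[3]))
    stop("component pixels lie outside the series")
  i1 <- cbind(pc[, 1] + 1L, pc[, 2] + 1L, pc[, 3] + 1L)
  r <- px[cbind(i1, 1L)]; g <- px[cbind(i1, 2L)]; b <- px[cbind(i1, 3L)]
  gval <- if (gray == "bt601") 0.299 * r + 0.587 * g + 0.114 * b
  else (r + g + b) / 3
  mean((255 - gval) / 255)
}

#' Quantify all label components of one heatmap series
#'
#' Convenience wrapper: segmentation, component extraction, and per-component
#' size and intensity.
#'
#' @inheritParams segment_label_mask
#' @inheritParams extract_components
#' @param size_convention passed to [component_size()].
#' @param gray passed to [component_intensity()].
#' @return data.frame with one row per component: `component_id`,
#'   `n_pixels`, `size` (default convention), `size_linear`, `intensity`,
#'   centroid in 0-based voxel and in mm coordinates.
#' @export
quantify_series <- function(series, blue_threshold = 100, connectivity = 26,
                            size_convention = "area", gray = "bt601") {
  stopifnot(inherits(series, "heatmap_series"))
  mask <- segment_label_mask(series, blue_threshold)
  comps <- extract_components(mask, connectivity)
  if (length(comps) == 0L) {
    return(data.frame(component_id = integer(), n_pixels = integer(),
                      size = numeric(), size_linear = numeric(),
                      intensity = numeric(), centroid_slice = numeric(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      centroid_slice_mm = numeric(), centroid_row_mm = numeric(),
                      centroid_col_mm = numeric(), stringsAsFactors = FALSE))
  }
  ps <- series$pixel_size_mm; st <- series$slice_thickness_mm
  do.call(rbind, lapply(seq_along(comps), function(i) {
    cp <- comps[[i]]
    data.frame(component_id = i, n_pixels = cp$n_pixels,
               size = component_size(cp, ps, size_convention),
               size_linear = component_size(cp, ps, "linear"),
               intensity = component_intensity(cp, series, gray),
               centroid_slice = cp$centroid_vox[["slice"]],
               centroid_row = cp$centroid_vox[["row"]],
               centroid_col = cp$centroid_vox[["col"]],
               centroid_slice_mm = cp$centroid_vox[["slice"]] * st,
               centroid_row_mm = cp$centroid_vox[["row"]] * ps,
               centroid_col_mm = cp$centroid_vox[["col"]] * ps,
               stringsAsFactors = FALSE)
  }))
}
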