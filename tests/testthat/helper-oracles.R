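# Independent oracles: deliberately naive implementations (explicit loops,
# exhaustive enumeration) against which the package's vectorised /
# graph-based code paths are checked.

# per-voxel loop segmentation
oracle_mask <- function(px, thr) {
  d <- dim(px)
  out <- array(FALSE, d[1:3])
  for (s in seq_len(d[1])) for (r in seq_len(d[2])) for (cc in seq_len(d[3]))
    out[s, r, cc] <- px[s, r, cc, 3] <= thr
  out
}

# queue-based flood fill; returns an integer label array (0 = background)
oracle_flood_fill <- function(mask, connectivity = 26) {
  d <- dim(mask)
  offs <- if (connectivity == 26) {
    g <- expand.grid(-1:1, -1:1, -1:1)
    as.matrix(g[rowSums(g != 0) > 0, ])
  } else if (connectivity == 8) {
    g <- expand.grid(0, -1:1, -1:1)
    as.matrix(g[rowSums(g != 0) > 0, ])
  } else {
    matrix(c(0, -1, 0, 0, 1, 0, 0, 0, -1, 0, 0, 1), ncol = 3, byrow = TRUE)
  }
  lab <- array(0L, d)
  nxt <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- integer(length(mask))
    queue[1] <- start
    head <- 1L; tail <- 1L
    lab[start] <- nxt
    while (head <= tail) {
      cur <- queue[head]; head <- head + 1L
      co <- arrayInd(cur, d)
      for (j in seq_len(nrow(offs))) {
        ns <- co[1] + offs[j, 1]; nr <- co[2] + offs[j, 2]
        nc <- co[3] + offs[j, 3]
        if (ns >= 1 && ns <= d[1] && nr >= 1 && nr <= d[2] &&
            nc >= 1 && nc <= d[3] && mask[ns, nr, nc] &&
            lab[ns, nr, nc] == 0L) {
          lab[ns, nr, nc] <- nxt
          tail <- tail + 1L
          queue[tail] <- arrayInd2lin(ns, nr, nc, d)
        }
      }
    }
  }
  lab
}

arrayInd2lin <- function(s, r, cc, d) s + d[1] * ((r - 1) + d[2] * (cc - 1))

# component partition as a canonical set of sorted pixel-key strings
partition_signature <- function(groups) {
  sig <- unname(vapply(groups, function(px) {
    keys <- sort(paste(px[, 1], px[, 2], px[, 3], sep = ","))
    paste(keys, collapse = "|")
  }, ""))
  sort(sig)
}

# loop-based intensity recomputation
oracle_intensity <- function(pixel_coords, px, gray = "bt601") {
  total <- 0
  for (i in seq_len(nrow(pixel_coords))) {
    s <- pixel_coords[i, 1] + 1L; r <- pixel_coords[i, 2] + 1L
    cc <- pixel_coords[i, 3] + 1L
    rgb <- px[s, r, cc, ]
    g <- if (gray == "bt601")
      0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3]
    else mean(rgb)
    total <- total + (255 - g) / 255
  }
  total / nrow(pixel_coords)
}

# exhaustive assignment: all injective pairings of lesions to components
# with every pair within tolerance; maximise pair count, then minimise
# total distance. Returns matched lesion/component index pairs.
oracle_assignment <- function(dist, tolerance) {
  nL <- nrow(dist); nC <- ncol(dist)
  best <- list(npairs = -1, total = Inf, pairs = NULL)
  comps <- c(NA_integer_, seq_len(nC))
  # enumerate assignments lesion-by-lesion (NA = unmatched)
  rec <- function(i, used, pairs, total) {
    if (i > nL) {
      np <- nrow(pairs) %||% 0
      if (np > best$npairs || (np == best$npairs && total < best$total)) {
        best <<- list(npairs = np, total = total, pairs = pairs)
      }
      return(invisible())
    }
    for (j in comps) {
      if (is.na(j)) {
        rec(i + 1, used, pairs, total)
      } else if (!(j %in% used) && dist[i, j] <= tolerance) {
        rec(i + 1, c(used, j), rbind(pairs, c(i, j)), total + dist[i, j])
      }
    }
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  rec(1L, integer(), NULL, 0)
  best
}

# full enumeration Mann-Whitney two-sided p (no ties assumed)
oracle_mw_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  ustats <- apply(idx, 2, function(ii) {
    rx <- rank(pooled)[ii]
    sum(rx) - nx * (nx + 1) / 2
  })
  rx <- rank(pooled)[seq_len(nx)]
  u <- sum(rx) - nx * (nx + 1) / 2
  p1 <- if (u > nx * ny / 2) mean(ustats >= u) else mean(ustats <= u)
  list(U = u, p = min(1, 2 * p1))
}

# small well-separated test fixtures -------------------------------------

tiny_design <- function(doses = c(1, 5, 20), recons = c("IR", "FBP"),
                        reps = 3, matrix_size = 96, n_slices = 4) {
  study_design(doses, recons, reps, matrix_size = matrix_size,
               pixel_size_mm = 0.41, slice_thickness_mm = 0.75,
               n_slices = n_slices)
}

tiny_lesions <- function() {
  lesion_spec(c("MCA", "ACoA", "BA"), slice = c(1, 2, 3),
              row = c(25, 20, 70), col = c(20, 70, 50),
              max_diameter_mm = c(4, 4, 2))
}

# detection params with constant probability p for every lesion/recon
flat_params <- function(p, lesions = c("MCA", "ACoA", "BA"),
                        recons = c("IR", "FBP"), ...) {
  one <- lapply(stats::setNames(recons, recons), function(r)
    list(intercept = stats::qlogis(p), slope = 0))
  detection_params(lapply(stats::setNames(lesions, lesions),
                          function(l) one), ...)
}

random_rgb_stack <- function(dim3 = c(8, 64, 64)) {
  array(sample(0:255, prod(dim3) * 3, replace = TRUE), c(dim3, 3))
}
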