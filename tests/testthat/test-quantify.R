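test_that("blue-channel segmentation handles the boundary cases", {
  white <- array(255L, c(2, 8, 8, 3))
  expect_false(any(segment_label_mask(white, 100)))
  # one pure red pixel: blue = 0 <= 100
  px <- white
  px[1, 3, 5, ] <- c(255L, 0L, 0L)
  m <- segment_label_mask(px, 100)
  expect_equal(sum(m), 1)
  expect_true(m[1, 3, 5])
  # threshold is inclusive
  px[1, 3, 5, 3] <- 100L
  expect_true(segment_label_mask(px, 100)[1, 3, 5])
  px[1, 3, 5, 3] <- 101L
  expect_false(segment_label_mask(px, 100)[1, 3, 5])
  expect_error(segment_label_mask(array(0L, c(2, 8, 8)), 100), "RGB")
  expect_error(segment_label_mask(white, 300), "blue_threshold")
})

test_that("segmentation equals the per-pixel loop oracle", {
  set.seed(77)
  px <- random_rgb_stack(c(4, 16, 16))
  expect_identical(segment_label_mask(px, 100), oracle_mask(px, 100))
  expect_identical(segment_label_mask(px, 0), oracle_mask(px, 0))
  expect_identical(segment_label_mask(px, 255), oracle_mask(px, 255))
})

test_that("segmentation is idempotent and threshold-monotone", {
  set.seed(5)
  px <- random_rgb_stack(c(4, 24, 24))
  thr <- sort(sample(0:255, 6))
  masks <- lapply(thr, function(t) segment_label_mask(px, t))
  for (i in seq_len(length(thr) - 1)) {
    expect_true(all(masks[[i + 1]][masks[[i]]]))  # mask(T1) subset mask(T2)
  }
})

test_that("component extraction separates and orders blobs correctly", {
  mask <- array(FALSE, c(2, 12, 12))
  mask[1, 2:4, 2:4] <- TRUE          # blob A
  mask[1, 8:10, 8:10] <- TRUE        # blob B, > 1 background pixel away
  comps <- extract_components(mask, 26)
  expect_length(comps, 2)
  # deterministic ordering by (min slice, min row, min col)
  expect_equal(unname(comps[[1]]$pixel_coords[1, "row"]), 1)  # 0-based
  expect_equal(sum(vapply(comps, `[[`, 0L, "n_pixels")), sum(mask))
  expect_length(extract_components(array(FALSE, c(2, 5, 5))), 0)
  # diagonal voxels connect under 26 but not under in-plane 4
  m2 <- array(FALSE, c(1, 4, 4))
  m2[1, 1, 1] <- TRUE; m2[1, 2, 2] <- TRUE
  expect_length(extract_components(m2, 8), 1)
  expect_length(extract_components(m2, 4), 2)
  # slice-adjacent voxels: one component volumetrically, two in-plane
  m3 <- array(FALSE, c(2, 3, 3))
  m3[1, 2, 2] <- TRUE; m3[2, 2, 2] <- TRUE
  expect_length(extract_components(m3, 26), 1)
  expect_length(extract_components(m3, 8), 2)
})

test_that("component extraction equals the flood-fill oracle", {
  for (s in 1:5) {
    set.seed(100 + s)
    mask <- array(runif(4 * 20 * 20) < 0.25, c(4, 20, 20))
    for (conn in c(4, 8, 26)) {
      comps <- extract_components(mask, conn)
      lab <- oracle_flood_fill(mask, conn)
      oracle_groups <- lapply(split(which(mask), lab[mask]), function(ii) {
        arrayInd(ii, dim(mask)) - 1L
      })
      expect_identical(
        partition_signature(lapply(comps, `[[`, "pixel_coords")),
        partition_signature(oracle_groups))
    }
  }
})

test_that("component size follows the configured convention", {
  one <- list(pixel_coords = matrix(0, 1, 3), n_pixels = 1L)
  expect_equal(component_size(one, 1), 1)
  p25 <- list(pixel_coords = matrix(0, 25, 3), n_pixels = 25L)
  expect_equal(component_size(p25, 0.41), 25 * 0.41^2)  # 4.2025 mm^2
  expect_equal(component_size(p25, 0.41, "linear"), 25 * 0.41)  # 10.25
  expect_error(component_size(one, 0), "pixel_size_mm")
  expect_error(component_size(list(n_pixels = 0), 1), "at least one")
  # area convention scales quadratically with pixel size
  k <- 2.5
  expect_equal(component_size(p25, k * 0.41), k^2 * component_size(p25, 0.41))
})

test_that("component intensity inverts and normalises grayscale", {
  px <- array(255L, c(1, 4, 4, 3))
  px[1, 1, 1, ] <- c(0L, 0L, 0L)
  px[1, 1, 2, ] <- c(100L, 100L, 100L)
  black <- list(pixel_coords = cbind(0, 0, 0), n_pixels = 1L)
  grey <- list(pixel_coords = cbind(0, 0, 1), n_pixels = 1L)
  expect_equal(component_intensity(black, px), 1.0)
  expect_equal(component_intensity(grey, px), (255 - 100) / 255)
  expect_equal(component_intensity(grey, px, gray = "mean"),
               (255 - 100) / 255)
  # outside-series pixels rejected
  bad <- list(pixel_coords = cbind(0, 9, 0), n_pixels = 1L)
  expect_error(component_intensity(bad, px), "outside")
})

test_that("intensity equals the loop oracle and ignores pixel order", {
  set.seed(21)
  px <- random_rgb_stack(c(3, 12, 12))
  mask <- segment_label_mask(px, 100)
  comps <- extract_components(mask, 26)
  ser <- heatmap_series(px, 0.41, 0.75)
  for (cp in comps[seq_len(min(5, length(comps)))]) {
    expect_equal(component_intensity(cp, ser),
                 oracle_intensity(cp$pixel_coords, px), tolerance = 1e-12)
    shuffled <- cp
    perm <- sample(nrow(cp$pixel_coords))
    shuffled$pixel_coords <- cp$pixel_coords[perm, , drop = FALSE]
    expect_equal(component_intensity(shuffled, ser),
                 component_intensity(cp, ser), tolerance = 1e-15)
  }
})

test_that("quantify_series ties segmentation, grouping and metrics together", {
  d <- tiny_design()
  s <- render_heatmap(d, 20, "IR", tiny_lesions(), seed = 8)
  q <- quantify_series(s)
  expect_equal(nrow(q), 3)
  expect_true(all(q$intensity >= 0 & q$intensity <= 1))
  expect_equal(q$size, q$n_pixels * 0.41^2)
  expect_equal(q$size_linear, q$n_pixels * 0.41)
  # partition conservation: component pixels sum to mask total
  expect_equal(sum(q$n_pixels), sum(segment_label_mask(s)))
})
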