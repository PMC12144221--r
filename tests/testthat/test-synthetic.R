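test_that("label probability follows the logistic dose-response model", {
  p <- default_detection_params()
  # saturation: infinite intercept pins the probability at 1
  sat <- detection_params(list(L = list(IR = list(intercept = Inf,
                                                  slope = 1))))
  expect_equal(label_probability(0.5, "IR", "L", sat), 1.0)
  # zero slope and intercept: 0.5 at every dose
  flat <- detection_params(list(L = list(IR = list(intercept = 0,
                                                   slope = 0))))
  expect_equal(label_probability(c(0.47, 5, 20.09), "IR", "L", flat),
               rep(0.5, 3))
  # agrees with direct formula evaluation, including degradation term
  doses <- c(0.47, 1.01, 5.02, 14.06, 20.09)
  for (l in c("MCA", "ACoA", "BA")) for (r in c("IR", "FBP")) {
    pr <- p$detection[[l]][[r]]
    eta <- pr$intercept + pr$slope * log(doses)
    if (!is.null(pr$deg_knee_mGy))
      eta <- eta - pr$deg_rate * pmax(0, doses - pr$deg_knee_mGy)
    expect_equal(label_probability(doses, r, l, p), plogis(eta),
                 tolerance = 1e-12)
  }
  expect_error(label_probability(5, "IR", "nope", p), "unknown lesion")
  expect_error(label_probability(5, "nope", "MCA", p),
               "unknown reconstruction")
  expect_error(label_probability(-1, "IR", "MCA", p), "dose")
})

test_that("probability is monotone in dose without the degradation term", {
  p <- default_detection_params()
  doses <- sort(runif(50, 0.2, 25))
  for (l in c("MCA", "ACoA", "BA")) {
    pr <- label_probability(doses, "IR", l, p)
    expect_true(all(diff(pr) >= -1e-15))
  }
})

test_that("rendering is reproducible and respects the blue threshold", {
  d <- tiny_design()
  les <- tiny_lesions()
  s1 <- render_heatmap(d, 5, "IR", les, seed = 11)
  s2 <- render_heatmap(d, 5, "IR", les, seed = 11)
  expect_identical(s1$pixels, s2$pixels)
  # every rendered label pixel is below threshold; background above
  mask <- segment_label_mask(s1)
  rend <- attr(s1, "rendered_pixels")
  n_rend <- sum(vapply(rend, nrow, 0L))
  expect_equal(sum(mask), n_rend)
  # empty detection set: no positive pixel anywhere
  s0 <- render_heatmap(d, 5, "IR", les[0, ], seed = 11)
  expect_equal(sum(segment_label_mask(s0)), 0)
  expect_true(all(s0$pixels[, , , 3] > 100))
})

test_that("zero offset scale centres the blob on the lesion centroid", {
  d <- tiny_design()
  les <- tiny_lesions()[1, ]
  p <- default_detection_params()
  p$offset_scale_mm <- 0
  p$size_jitter_sd <- 0
  s <- render_heatmap(d, 20, "IR", les, params = p, seed = 3)
  q <- quantify_series(s)
  expect_equal(nrow(q), 1)
  expect_lt(abs(q$centroid_row - les$row), 0.5)
  expect_lt(abs(q$centroid_col - les$col), 0.5)
  expect_equal(q$centroid_slice, les$slice)
})

test_that("a blob entirely outside the stack is a generation error", {
  d <- tiny_design()
  les <- lesion_spec("X", slice = 3, row = 95, col = 95,
                     max_diameter_mm = 2)
  p <- default_detection_params()
  p$offset_scale_mm <- 60  # push the centre far out of bounds
  seeds_err <- 0
  for (s in 1:20) {
    r <- try(render_heatmap(d, 20, "IR", les, params = p, seed = s),
             silent = TRUE)
    if (inherits(r, "try-error")) seeds_err <- seeds_err + 1
  }
  expect_gt(seeds_err, 0)
})

test_that("segmentation recovers exactly the rendered pixel sets", {
  d <- tiny_design()
  les <- tiny_lesions()
  s <- render_heatmap(d, 20, "IR", les, seed = 5)
  rend <- attr(s, "rendered_pixels")
  comps <- extract_components(segment_label_mask(s))
  expect_length(comps, length(rend))
  expect_identical(
    partition_signature(lapply(comps, `[[`, "pixel_coords")),
    partition_signature(rend))
})

test_that("simulation is deterministic and substream-stable", {
  d <- tiny_design()
  les <- tiny_lesions()
  st1 <- simulate_study(d, les, seed = 42)
  st2 <- simulate_study(d, les, seed = 42)
  expect_identical(st1$truth, st2$truth)
  expect_identical(lapply(st1$series, `[[`, "pixels"),
                   lapply(st2$series, `[[`, "pixels"))
  # adding a dose must not perturb the draws of existing scans
  d_more <- tiny_design(doses = c(1, 5, 12, 20))
  st3 <- simulate_study(d_more, les, seed = 42, render = FALSE)
  shared <- intersect(st1$truth$scan_id, st3$truth$scan_id)
  expect_length(unique(st1$truth$scan_id), length(shared))
  a <- st1$truth[st1$truth$scan_id %in% shared, ]
  b <- st3$truth[st3$truth$scan_id %in% shared, ]
  b <- b[order(match(paste(b$scan_id, b$lesion_id),
                     paste(a$scan_id, a$lesion_id))), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("degenerate detection probabilities give all or no labels", {
  d <- tiny_design()
  les <- tiny_lesions()
  st1 <- simulate_study(d, les, params = flat_params(1), seed = 1)
  expect_true(all(st1$truth$detected))
  tally <- table(st1$truth$lesion_id)
  expect_true(all(tally == n_scans(d)))
  st0 <- simulate_study(d, les, params = flat_params(0), seed = 1)
  expect_false(any(st0$truth$detected))
  expect_true(all(vapply(st0$series, function(s)
    sum(segment_label_mask(s)) == 0, TRUE)))
})

test_that("per-scan component count equals truth-table detections", {
  d <- tiny_design()
  les <- tiny_lesions()
  st <- simulate_study(d, les, params = flat_params(0.6), seed = 9)
  for (sid in names(st$series)) {
    ncomp <- length(extract_components(
      segment_label_mask(st$series[[sid]])))
    ndet <- sum(st$truth$detected[st$truth$scan_id == sid])
    expect_equal(ncomp, ndet)
  }
})

test_that("empirical detection frequency matches the model probability", {
  # Bernoulli Monte-Carlo: one lesion, fixed p = 0.7, many repetitions
  d <- study_design(1, "IR", repetitions = 2000, matrix_size = 32,
                    n_slices = 2)
  les <- lesion_spec("L", 1, 16, 16, 4)
  st <- simulate_study(d, les, params = flat_params(0.7, "L", "IR"),
                       seed = 123, render = FALSE)
  frac <- mean(st$truth$detected)
  se <- sqrt(0.7 * 0.3 / 2000)
  expect_lt(abs(frac - 0.7), 3 * se)
})

test_that("simulated readers respect degenerate visibility models", {
  d <- tiny_design()
  les <- tiny_lesions()
  always <- reader_params(visibility = list(
    MCA = c(intercept = Inf, slope = 0),
    ACoA = c(intercept = Inf, slope = 0),
    BA = c(intercept = Inf, slope = 0)))
  resp <- simulate_readers(d, les, always, seed = 2)
  expect_equal(nrow(resp), 5 * n_scans(d) * 3)
  expect_true(all(resp$visible == "yes"))
  never <- reader_params(visibility = list(
    MCA = c(intercept = -Inf, slope = 0),
    ACoA = c(intercept = -Inf, slope = 0),
    BA = c(intercept = -Inf, slope = 0)))
  resp0 <- simulate_readers(d, les, never, seed = 2)
  expect_true(all(resp0$visible == "no"))
  expect_true(all(resp0$quality %in% 1:3))
})

test_that("positive reader responses increase with dose on average", {
  d <- study_design(c(0.5, 2, 8), "IR", repetitions = 2, matrix_size = 32,
                    n_slices = 2)
  les <- lesion_spec("L", 1, 16, 16, 4)
  rp <- reader_params(n_readers = 2,
                      visibility = list(L = c(intercept = 0.5, slope = 1.5)),
                      reader_shift = c(0, 0))
  totals <- matrix(0, nrow = 500, ncol = 3)
  for (s in 1:500) {
    resp <- simulate_readers(d, les, rp, seed = s)
    totals[s, ] <- tapply(resp$visible == "yes", resp$dose_mGy, sum)
  }
  m <- colMeans(totals)
  expect_true(all(diff(m) > 0))
})
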