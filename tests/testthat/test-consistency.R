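sim_matched <- function(p = 0.6, seed = 4, design = tiny_design()) {
  les <- tiny_lesions()
  st <- simulate_study(design, les, params = flat_params(p), seed = seed)
  scans <- design_scans(design)
  comp <- do.call(rbind, lapply(names(st$series), function(sid) {
    q <- quantify_series(st$series[[sid]])
    if (nrow(q)) cbind(scan_id = sid, q, stringsAsFactors = FALSE) else NULL
  }))
  m <- match_study(comp, scans, les, 10, design$geometry$pixel_size_mm,
                   design$geometry$slice_thickness_mm)
  list(study = st, matched = m, design = design)
}

test_that("detection counts tally the truth table exactly", {
  x <- sim_matched()
  tab <- detection_table(x$matched$detections, x$design)
  expect_true(all(tab$n_detected >= 0 & tab$n_detected <= 3))
  truth <- x$study$truth
  for (i in seq_len(nrow(tab))) {
    expect_equal(tab$n_detected[i],
                 sum(truth$detected[truth$lesion_id == tab$lesion_id[i] &
                                      truth$dose_mGy == tab$dose_mGy[i] &
                                      truth$reconstruction ==
                                        tab$reconstruction[i]]))
  }
  # marginal conservation: per-reconstruction sums equal lesion totals
  for (l in unique(tab$lesion_id)) {
    per_recon <- tapply(tab$n_detected[tab$lesion_id == l],
                        tab$reconstruction[tab$lesion_id == l], sum)
    expect_equal(sum(per_recon), sum(tab$n_detected[tab$lesion_id == l]))
  }
})

test_that("degenerate studies give full or empty detection tables", {
  full <- sim_matched(p = 1)
  tab <- detection_table(full$matched$detections, full$design)
  expect_true(all(tab$n_detected == 3))
  expect_equal(sum(tab$n_detected[tab$lesion_id == "MCA"]),
               n_scans(full$design))
  none <- sim_matched(p = 0)
  tab0 <- detection_table(none$matched$detections, none$design)
  expect_true(all(tab0$n_detected == 0))
  expect_true(all(none$matched$triage$decision == "negative"))
})

test_that("incomplete detection records raise a completeness error", {
  x <- sim_matched()
  det <- x$matched$detections
  dropped <- det[det$scan_id != det$scan_id[1], ]
  expect_error(detection_table(dropped, x$design), det$scan_id[1])
})

test_that("detection rates report exact printed-precision percentages", {
  expect_equal(detection_rate(117, 126)$percent_1dp, 92.9)
  expect_equal(detection_rate(3, 126)$percent_1dp, 2.4)
  expect_equal(detection_rate(0, 126)$percent_1dp, 0)
  expect_equal(detection_rate(117, 126)$percent, 100 * 117 / 126)
  expect_error(detection_rate(1, 0), "n_total")
  expect_error(detection_rate(5, 4), "count")
})

test_that("triage summary fractions are complementary", {
  tri <- data.frame(scan_id = sprintf("s%d", 1:126),
                    decision = rep(c("positive", "negative"), c(117, 9)))
  ts <- triage_summary(tri)
  expect_equal(ts$fn_percent_1dp, 7.1)
  expect_equal(ts$tp_percent + ts$fn_percent, 100)
  expect_lte(abs(ts$tp_percent_1dp + ts$fn_percent_1dp - 100), 0.1)
  x <- sim_matched()
  ts2 <- triage_summary(x$matched$triage)
  expect_equal(ts2$n_negative,
               sum(x$matched$triage$n_components == 0))
})

test_that("CV uses only fully reproducible cells and both poolings", {
  # hand-built detections: one lesion, two doses, one reconstruction
  det <- data.frame(
    scan_id = sprintf("s%d", 1:6),
    dose_mGy = rep(c(1, 2), each = 3), reconstruction = "IR",
    repetition = rep(1:3, 2), lesion_id = "A",
    matched = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    size = c(2, 4, 6, 9, 9, NA), intensity = c(rep(0.5, 5), NA))
  des <- study_design(c(1, 2), "IR", 3)
  cv <- reproducibility_cv(det, des, "size")
  # only dose 1 qualifies (dose 2 lacks a third positive label)
  expect_equal(cv$n_qualifying_doses, 1L)
  expect_equal(cv$cv_per_dose, sd(c(2, 4, 6)) / mean(c(2, 4, 6)))  # 0.5
  expect_equal(cv$cv_pooled, sd(c(2, 4, 6)) / mean(c(2, 4, 6)))
  # identical repeats: CV exactly 0
  det$size <- c(5, 5, 5, 9, 9, NA)
  cv0 <- reproducibility_cv(det, des, "size")
  expect_equal(cv0$cv_per_dose, 0)
  # no qualifying cells: flagged not-computable, not zero
  det$matched <- FALSE
  cvna <- reproducibility_cv(det, des, "size")
  expect_false(cvna$computable)
  expect_true(is.na(cvna$cv_per_dose))
})

test_that("CV matches a loop oracle and is scale invariant", {
  x <- sim_matched(p = 0.8, seed = 6)
  det <- x$matched$detections
  des <- x$design
  cv <- reproducibility_cv(det, des, "size")
  for (i in seq_len(nrow(cv))) {
    sub <- det[det$lesion_id == cv$lesion_id[i] &
                 det$reconstruction == cv$reconstruction[i], ]
    percv <- c(); pool <- c()
    for (d in des$doses_mGy) {
      v <- sub$size[sub$dose_mGy == d & sub$matched]
      if (length(v) == des$repetitions) {
        percv <- c(percv, sd(v) / mean(v)); pool <- c(pool, v)
      }
    }
    if (length(percv)) {
      expect_equal(cv$cv_per_dose[i], mean(percv), tolerance = 1e-12)
      expect_equal(cv$cv_pooled[i], sd(pool) / mean(pool),
                   tolerance = 1e-12)
    } else expect_false(cv$computable[i])
  }
  # scale invariance
  det2 <- det; det2$size <- det2$size * 7.3
  cv2 <- reproducibility_cv(det2, des, "size")
  expect_equal(cv2$cv_per_dose, cv$cv_per_dose, tolerance = 1e-12)
})

test_that("label summaries average matched repeats and keep gaps absent", {
  det <- data.frame(
    scan_id = sprintf("s%d", 1:6),
    dose_mGy = rep(c(1, 2), each = 3), reconstruction = "IR",
    repetition = rep(1:3, 2), lesion_id = "A",
    matched = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
    size = c(10, 10, 10, NA, NA, NA),
    intensity = c(0.2, 0.4, 0.6, NA, NA, NA))
  des <- study_design(c(1, 2), "IR", 3)
  ls <- label_summary(det, des)
  expect_equal(ls$mean_size[ls$dose_mGy == 1], 10)
  expect_equal(ls$mean_intensity[ls$dose_mGy == 1], 0.4)
  expect_true(is.na(ls$mean_size[ls$dose_mGy == 2]))
  expect_equal(ls$n_matched, c(3L, 0L))
})

test_that("the consistency report assembles coherent totals", {
  x <- sim_matched(p = 0.7, seed = 12)
  rep_ <- consistency_report(x$matched$detections, x$matched$triage,
                             x$design)
  expect_equal(rep_$total_labels, sum(x$study$truth$detected))
  # per-reconstruction totals sum to overall lesion totals
  for (l in rep_$lesion_totals$lesion_id) {
    pr <- rep_$lesion_totals_by_reconstruction
    expect_equal(sum(pr$count[pr$lesion_id == l]),
                 rep_$lesion_totals$count[rep_$lesion_totals$lesion_id == l])
  }
  expect_true(all(rep_$lesion_totals$percent >= 0 &
                    rep_$lesion_totals$percent <= 100))
})
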