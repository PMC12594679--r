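test_that("cohorts are reproducible and respect multipliers", {
  tpl <- cohortTemplate()
  a <- makeCohort(tpl, 9, rngSeed = 42, metricsOnly = TRUE)
  b <- makeCohort(tpl, 9, rngSeed = 42, metricsOnly = TRUE)
  expect_identical(cohortMetricsTable(a, "g"), cohortMetricsTable(b, "g"))
  zero <- makeCohort(tpl, 6, effect = c(peg = 0, detachment = 0, tubule = 0),
                     rngSeed = 7, metricsOnly = TRUE)
  for (el in zero) expect_true(all(featureCounts(el$groundTruth)$count == 0))
  expect_error(makeCohort(tpl, 3, effect = c(peg = -1)), "non-negative")
  expect_error(makeCohort(tpl, 3, effect = c(bogus = 1)), "unknown effect")
})

test_that("per-stack counts follow the scaled Poisson law", {
  tpl <- cohortTemplate()
  mc <- list(peg = c(attached = 3, partially_detached = 0),
             detachment = c(endothelium = 0, pericyte = 0, macroglia = 0),
             tubule = c(closed = 0, luminal = 0, abluminal = 0,
                        transendothelial = 0))
  co <- makeCohort(tpl, 4000, effect = c(peg = 0.3), rngSeed = 99,
                   meanCounts = mc, metricsOnly = TRUE)
  counts <- vapply(co, function(el) countsOf(el$groundTruth, "peg_socket", "all"),
                   numeric(1))
  # mean 3 * 0.3 = 0.9; MC error ~ sqrt(0.9/4000) ~ 0.015
  expect_lt(abs(mean(counts) - 0.9), 0.05)
  expect_lt(abs(var(counts) - 0.9), 0.1)   # Poisson: variance = mean
})

test_that("ground-truth frequencies and thickness vary as designed", {
  co <- makeCohort(cohortTemplate(), 12, rngSeed = 3, metricsOnly = TRUE,
                   bmBaseSdNm = 8)
  mt <- cohortMetricsTable(co, "ctl")
  expect_equal(nrow(mt), 12)
  expect_equal(unique(mt$depth_um), 30)
  expect_gt(sd(mt$bm_mean_nm), 0)       # between-capillary BM variability
  expect_gt(mean(mt$peg_per_10um), 1)   # control pegs present
  expect_true(all(mt$transendothelial_count == 0))
})

test_that("rasterised cohort stacks are detected to match their manifests", {
  co <- makeCohort(phantomSpec(nSlices = 24L), 2, rngSeed = 12,
                   meanCounts = list(
                     peg = c(attached = 2, partially_detached = 1),
                     detachment = c(endothelium = 1, pericyte = 0,
                                    macroglia = 0),
                     tubule = c(closed = 2, luminal = 1, abluminal = 0,
                                transendothelial = 0)),
                   rasterize = TRUE)
  for (el in co) {
    cm <- summarizeCapillary(el$volume, el$roleMap)
    expect_equal(featureCounts(cm), featureCounts(el$groundTruth))
  }
  measured <- cohortMetricsTable(co, "g", source = "measured")
  gt <- cohortMetricsTable(co, "g", source = "ground_truth")
  expect_equal(measured$peg_per_10um, gt$peg_per_10um)
  expect_equal(measured$tubule_per_10um, gt$tubule_per_10um)
  expect_true(all(abs(measured$bm_mean_nm - gt$bm_mean_nm) <= 6))
})
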