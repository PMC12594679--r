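test_that("uniform shell has degenerate analytic summary and zero counts", {
  sp <- smallSpec(5L, bmBaseNm = 102)
  ats <- analyticThicknessSummary(sp)
  expect_equal(unname(ats), c(102, 102))
  gt <- generatePhantom(sp)$groundTruth
  expect_equal(aggregateMeanNm(gt), 102)
  expect_equal(aggregateMaxNm(gt), 102)
  expect_true(all(featureCounts(gt)$count == 0))
})

test_that("analytic summary integrates the sinusoidal thickness field", {
  sp <- smallSpec(40L, bmBaseNm = 120, bmAmplitudeNm = 40)
  ats <- analyticThicknessSummary(sp)
  expect_equal(unname(ats["mean_nm"]), 120, tolerance = 1e-6)
  expect_equal(unname(ats["max_nm"]), 160, tolerance = 1e-4)
  # amplitude = base - 12 -> max = 2*base - 12
  sp2 <- smallSpec(40L, bmBaseNm = 120, bmAmplitudeNm = 108)
  expect_equal(unname(analyticThicknessSummary(sp2)["max_nm"]), 228,
               tolerance = 1e-4)
})

test_that("ground-truth frequencies are exact count * 10 / depth arithmetic", {
  sp <- phantomSpec(nSlices = 300L,
                    pegs = rbind(pegFeature(50, 0.5), pegFeature(150, 1.5),
                                 pegFeature(250, 2.5)))
  gt <- groundTruthFromSpec(sp)
  expect_equal(depthUm(gt), 30)
  expect_equal(countsOf(gt, "peg_socket", "all"), 3)
  cts <- featureCounts(gt)
  expect_equal(cts$freq_per_10um[cts$feature_type == "peg_socket" &
                                 cts$subtype == "all"], 1.0)
})

test_that("regeneration is bit-identical and rasterisation matches roleMask", {
  sp <- richSpec(12L)
  a <- generatePhantom(sp)
  b <- generatePhantom(sp)
  expect_identical(voxelData(a$volume), voxelData(b$volume))
  bm <- roleMask(a$volume, a$roleMap, "basement_membrane")
  expect_identical(sum(bm), sum(voxelData(a$volume) == 3L))
})

test_that("the BM rasterises as one connected ring per slice, gaps or not", {
  sp <- smallSpec(6L,
    detachments = detachmentFeature("endothelium", 3, 2.0, gap_nm = 30))
  ph <- generatePhantom(sp)
  bm <- roleMask(ph$volume, ph$roleMap, "basement_membrane")
  for (k in seq_len(nSlices(ph$volume))) {
    lab <- EBImage::bwlabel(matrix(as.integer(bm[, , k]), dim(bm)[1]))
    expect_equal(max(lab), 1)   # detachment gaps sit beside, not inside, the BM
  }
})

test_that("spec validation rejects impossible phantoms", {
  expect_error(smallSpec(5L, bmBaseNm = 10), "shell vanishes")
  expect_error(smallSpec(0L), "nSlices")
  expect_error(smallSpec(5L, pegs = pegFeature(3, 4.5)), "pericyte arc")
  expect_error(
    smallSpec(5L, macroglia = FALSE,
              detachments = detachmentFeature("macroglia", 3, 5.0)),
    "macroglia")
  expect_error(
    smallSpec(8L, pegs = rbind(pegFeature(4, 1.0), pegFeature(4, 1.02))),
    "overlap")
  # same arc but disjoint z is fine
  expect_silent(
    smallSpec(12L, pegs = rbind(pegFeature(3, 1.0), pegFeature(10, 1.0))))
})

test_that("boundary jitter is seeded and off by default", {
  sp <- smallSpec(3L)
  clean1 <- generatePhantom(sp)
  clean2 <- generatePhantom(sp)
  expect_identical(voxelData(clean1$volume), voxelData(clean2$volume))
  j1 <- generatePhantom(sp, jitterSdNm = 4)
  j2 <- generatePhantom(sp, jitterSdNm = 4)
  expect_identical(voxelData(j1$volume), voxelData(j2$volume))
  expect_false(identical(voxelData(j1$volume), voxelData(clean1$volume)))
})
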