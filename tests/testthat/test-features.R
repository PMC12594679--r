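test_that("detectors recover the planted manifest exactly", {
  ph <- generatePhantom(richSpec(30L))
  cm <- summarizeCapillary(ph$volume, ph$roleMap)
  expect_equal(featureCounts(cm), featureCounts(ph$groundTruth))
  ev <- featureEvents(cm)
  # states, classes and z-extents match what was planted
  pegs <- ev[ev$feature_type == "peg_socket", ]
  expect_equal(sort(pegs$attachment_state),
               c("attached", "attached", "partially_detached"))
  expect_true(all(pegs$z_end - pegs$z_start + 1L == 3L))
  tub <- ev[ev$feature_type == "tubule", ]
  expect_setequal(tub$opening_class,
                  c("closed", "luminal", "abluminal", "transendothelial"))
  det <- ev[ev$feature_type == "detachment", ]
  expect_setequal(det$target_role, c("endothelium", "pericyte", "macroglia"))
  expect_true(all(det$max_gap_nm >= 12))
  expect_false(any(ev$boundary))
})

test_that("lucent socket space around a detached peg is measured and not double counted", {
  sp <- phantomSpec(nSlices = 16L,
    pegs = pegFeature(8, 1.2, state = "partially_detached", gap_nm = 30))
  ph <- generatePhantom(sp)
  pegs <- detectPegSockets(ph$volume, ph$roleMap)
  expect_equal(nrow(pegs), 1L)
  expect_equal(pegs$attachment_state, "partially_detached")
  expect_equal(pegs$max_gap_nm, 30)     # 5 px shell at 6 nm/px
  expect_gt(length(attr(pegs, "lucent_voxels")), 0)
  # summarizeCapillary claims the socket space for the peg: no detachments
  cm <- summarizeCapillary(ph$volume, ph$roleMap)
  expect_equal(countsOf(cm, "detachment", "all"), 0)
})

test_that("threshold 'attached' pegs stay attached", {
  sp <- phantomSpec(nSlices = 16L, pegs = pegFeature(8, 1.2))
  ph <- generatePhantom(sp)
  pegs <- detectPegSockets(ph$volume, ph$roleMap)
  expect_equal(nrow(pegs), 1L)
  expect_equal(pegs$attachment_state, "attached")
  expect_equal(pegs$max_gap_nm, 0)
})

test_that("gap-width thresholds exclude sub-resolution detachments", {
  narrow <- generatePhantom(phantomSpec(nSlices = 12L,
    detachments = detachmentFeature("endothelium", 6, 4.0, gap_nm = 6)))
  ev <- detectDetachments(narrow$volume, narrow$roleMap, "endothelium")
  expect_equal(nrow(ev), 0L)   # 1-px gap measures 6 nm < 12 nm minimum
  wide <- generatePhantom(phantomSpec(nSlices = 12L,
    detachments = detachmentFeature("endothelium", 6, 4.0, gap_nm = 24)))
  ev2 <- detectDetachments(wide$volume, wide$roleMap, "endothelium")
  expect_equal(nrow(ev2), 1L)
  expect_gte(ev2$max_gap_nm, 12)
})

test_that("fully attached phantoms are a clean negative control", {
  ph <- generatePhantom(phantomSpec(nSlices = 10L))
  for (tr in c("endothelium", "pericyte", "macroglia"))
    expect_equal(nrow(detectDetachments(ph$volume, ph$roleMap, tr)), 0L)
  expect_equal(nrow(detectPegSockets(ph$volume, ph$roleMap)), 0L)
})

test_that("size and persistence thresholds drop small components", {
  sp <- phantomSpec(nSlices = 16L, tubules = tubuleFeature(8, 2.2))
  ph <- generatePhantom(sp)
  expect_equal(nrow(detectTubules(ph$volume, ph$roleMap)), 1L)
  expect_equal(nrow(detectTubules(ph$volume, ph$roleMap,
                                  params = list(min_voxels = 1e6))), 0L)
  pg <- phantomSpec(nSlices = 16L, pegs = pegFeature(8, 1.0))
  php <- generatePhantom(pg)
  expect_equal(nrow(detectPegSockets(php$volume, php$roleMap,
                                     params = list(min_z_slices = 10))), 0L)
  expect_error(detectTubules(ph$volume, ph$roleMap,
                             params = list(bogus = 1)), "unknown detector")
})

test_that("absent roles: missing from map errors, mapped-but-empty warns", {
  vox <- array(0L, c(20, 20, 4))
  vox[8:12, 8:12, ] <- 1L
  vox[6:7, 8:12, ] <- 2L
  vol <- LabelVolume(vox)
  rmNoPeri <- RoleMap(c(`0` = "background", `1` = "lumen",
                        `2` = "endothelium"))
  expect_error(detectPegSockets(vol, rmNoPeri), "required role missing")
  expect_warning(ev <- detectPegSockets(vol, phantomRoleMap()),
                 "no voxels")
  expect_equal(nrow(ev), 0L)
})

test_that("frequency normalisation is exact arithmetic", {
  expect_equal(frequencyPer10um(6, 300, 100), 2.0)
  expect_equal(frequencyPer10um(0, 300, 100), 0.0)
  expect_equal(frequencyPer10um(9, 130, 100), 9 * 10000 / 13000)
  expect_error(frequencyPer10um(1, 0, 100), "nSlices")
  expect_error(frequencyPer10um(1, 10, 0), "dzNm")
})

test_that("concatenating a stack with itself doubles counts, keeps frequency", {
  sp <- phantomSpec(nSlices = 14L,
    pegs = pegFeature(7, 1.0),
    tubules = tubuleFeature(7, 4.0, opening = "luminal"))
  ph <- generatePhantom(sp)
  vox <- voxelData(ph$volume)
  doubled <- LabelVolume(array(c(vox, vox), dim(vox) * c(1, 1, 2)),
                         voxelSizeNm(ph$volume))
  one <- summarizeCapillary(ph$volume, ph$roleMap)
  two <- summarizeCapillary(doubled, ph$roleMap)
  expect_equal(featureCounts(two)$count, 2L * featureCounts(one)$count)
  expect_equal(featureCounts(two)$freq_per_10um,
               featureCounts(one)$freq_per_10um)
})

test_that("swapping lumen and BM roles swaps luminal and abluminal classes", {
  sp <- phantomSpec(nSlices = 16L,
    tubules = rbind(tubuleFeature(5, 4.0, opening = "luminal"),
                    tubuleFeature(10, 5.0, opening = "abluminal"),
                    tubuleFeature(14, 3.0, opening = "closed")))
  ph <- generatePhantom(sp)
  swapped <- roles(ph$roleMap)
  swapped[swapped == "lumen"] <- "zz"
  swapped[swapped == "basement_membrane"] <- "lumen"
  swapped[swapped == "zz"] <- "basement_membrane"
  rm2 <- RoleMap(swapped)
  ev1 <- detectTubules(ph$volume, ph$roleMap)
  ev2 <- detectTubules(ph$volume, rm2)
  expect_equal(sum(ev1$opening_class == "luminal"),
               sum(ev2$opening_class == "abluminal"))
  expect_equal(sum(ev1$opening_class == "abluminal"),
               sum(ev2$opening_class == "luminal"))
  expect_equal(sum(ev1$opening_class == "closed"),
               sum(ev2$opening_class == "closed"))
  expect_equal(sum(ev1$opening_class == "transendothelial"),
               sum(ev2$opening_class == "transendothelial"))
})

test_that("re-analysis is deterministic", {
  ph <- generatePhantom(richSpec(20L))
  a <- summarizeCapillary(ph$volume, ph$roleMap)
  b <- summarizeCapillary(ph$volume, ph$roleMap)
  expect_identical(featureCounts(a), featureCounts(b))
  expect_identical(featureEvents(a), featureEvents(b))
})
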