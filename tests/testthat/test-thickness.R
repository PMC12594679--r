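test_that("local thickness has the fixed odd-diameter convention", {
  bar <- matrix(FALSE, 5, 12)
  bar[3, 2:11] <- TRUE
  lt <- localThicknessMap(bar)
  expect_true(all(lt[bar] == 1))          # one-pixel bar -> diameter 1
  sq <- matrix(FALSE, 9, 9)
  sq[3:7, 3:7] <- TRUE
  expect_equal(localThicknessMap(sq)[5, 5], 5)   # 5x5 square centre
  s <- sliceLocalThickness(bar, 6)
  expect_true(length(s) > 0 && all(s == 6))      # returned in nm
})

test_that("solid discs measure their diameter to within one pixel", {
  for (r in c(6, 10, 15)) {
    n <- 2 * r + 9
    ctr <- (n + 1) / 2
    yy <- matrix(rep(seq_len(n), n), n)
    m <- (yy - ctr)^2 + (t(yy) - ctr)^2 <= r^2
    mx <- max(localThicknessMap(m))
    expect_lte(abs(mx - 2 * r), 1)
  }
})

test_that("an annulus of known width recovers its thickness", {
  m <- annulusMask(220, 100, 83)      # width 17 px = 102 nm at 6 nm/px
  s <- sliceLocalThickness(m, 6)
  expect_true(all(abs(s - 102) <= 6))
})

test_that("fast path agrees with the exhaustive oracle", {
  set.seed(101)
  for (i in 1:6) {
    m <- randomBlobMask()
    fast <- localThicknessMap(m)
    oracle <- bruteForceLocalThickness(m)
    expect_equal(max(fast), max(oracle))
    # ridge samples are a subset of the oracle's thickness values
    expect_true(all(sliceLocalThickness(m, 1) %in% oracle[m]))
  }
  expect_error(bruteForceLocalThickness(matrix(TRUE, 60, 60), maxPixels = 100),
               "pixel cap")
})

test_that("sample multiset is invariant to rotation, flip and translation", {
  set.seed(7)
  m <- randomBlobMask(40)
  ref <- sort(sliceLocalThickness(m, 6))
  rot90 <- t(m)[ncol(m):1, ]
  expect_equal(sort(sliceLocalThickness(rot90, 6)), ref)
  expect_equal(sort(sliceLocalThickness(m[nrow(m):1, ], 6)), ref)
  shifted <- matrix(FALSE, nrow(m) + 6, ncol(m) + 6)
  shifted[4:(nrow(m) + 3), 4:(ncol(m) + 3)] <- m
  expect_equal(sort(sliceLocalThickness(shifted, 6)), ref)
})

test_that("dilating a mask never decreases the maximum thickness", {
  set.seed(19)
  for (i in 1:4) {
    m <- randomBlobMask(40)
    d <- EBImage::dilate(matrix(as.integer(m), nrow(m)),
                         EBImage::makeBrush(3, "box")) > 0
    d[1, ] <- d[nrow(d), ] <- d[, 1] <- d[, ncol(d)] <- FALSE
    expect_gte(max(localThicknessMap(d)), max(localThicknessMap(m)))
  }
})

test_that("stack aggregation pools samples and skips BM-free slices", {
  ph <- generatePhantom(smallSpec(5L, bmBaseNm = 60))
  tp <- stackThickness(ph$volume, ph$roleMap)
  expect_true(aggregateMeanNm(tp) > 0)
  expect_lte(aggregateMeanNm(tp), aggregateMaxNm(tp))
  expect_true(abs(aggregateMeanNm(tp) - 60) <= 6)
  expect_true(abs(aggregateMaxNm(tp) - 60) <= 6)
  expect_equal(length(thicknessSamples(tp)), tp@nSamplesTotal)

  # erase the BM from slice 1: skipped, aggregates equal the 4-slice stack
  vox <- voxelData(ph$volume)
  vox[, , 1][vox[, , 1] == 3L] <- 2L
  holey <- LabelVolume(vox, voxelSizeNm(ph$volume))
  expect_warning(tp2 <- stackThickness(holey, ph$roleMap), "skipped")
  expect_equal(skippedSlices(tp2), 1L)
  sub <- LabelVolume(voxelData(ph$volume)[, , 2:5, drop = FALSE],
                     voxelSizeNm(ph$volume))
  tp3 <- stackThickness(sub, ph$roleMap)
  expect_equal(aggregateMeanNm(tp2), aggregateMeanNm(tp3))
  expect_equal(aggregateMaxNm(tp2), aggregateMaxNm(tp3))

  # no BM anywhere is an error
  none <- LabelVolume(array(0L, c(8, 8, 2)))
  expect_error(stackThickness(none, phantomRoleMap()), "no basement membrane")
})
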