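# Shared fixtures, all generated in code.

# compact capillary geometry for fast unit tests (10 nm BM = 10 px at 6 nm/px)
smallSpec <- function(nSlices = 8L, bmBaseNm = 60, ...) {
  phantomSpec(nSlices = nSlices, lumenRadiusNm = 300,
              endotheliumThicknessNm = 150, bmBaseNm = bmBaseNm,
              pericyteThicknessNm = 100, macrogliaThicknessNm = 100, ...)
}

# random blob mask (union of discs), border kept background
randomBlobMask <- function(n = 48L, nBlobs = 4L, rMax = 9L) {
  m <- matrix(FALSE, n, n)
  yy <- matrix(rep(seq_len(n), n), n)
  xx <- t(yy)
  for (b in seq_len(nBlobs)) {
    cy <- sample(seq(rMax, n - rMax), 1)
    cx <- sample(seq(rMax, n - rMax), 1)
    r <- sample(3:rMax, 1)
    m <- m | ((yy - cy)^2 + (xx - cx)^2 <= r^2)
  }
  m[1, ] <- m[n, ] <- m[, 1] <- m[, n] <- FALSE
  m
}

# annulus mask in pixels
annulusMask <- function(n, rOuter, rInner) {
  ctr <- (n + 1) / 2
  yy <- matrix(rep(seq_len(n), n), n)
  xx <- t(yy)
  r <- sqrt((yy - ctr)^2 + (xx - ctr)^2)
  r >= rInner & r < rOuter
}

# a phantom planting one feature of every kind, well separated in (z, arc);
# z positions scale with the stack length
richSpec <- function(nSlices = 30L) {
  zAt <- function(f) as.integer(max(2, min(nSlices - 1, round(f * nSlices))))
  phantomSpec(
    nSlices = nSlices,
    pegs = rbind(pegFeature(zAt(8 / 30), 0.6),
                 pegFeature(zAt(15 / 30), 1.6, state = "partially_detached"),
                 pegFeature(zAt(24 / 30), 2.6)),
    detachments = rbind(detachmentFeature("endothelium", zAt(8 / 30), 4.0),
                        detachmentFeature("pericyte", zAt(20 / 30), 0.4,
                                          gap_nm = 30),
                        detachmentFeature("macroglia", zAt(15 / 30), 4.8)),
    tubules = rbind(tubuleFeature(zAt(6 / 30), 5.5, opening = "closed"),
                    tubuleFeature(zAt(12 / 30), 3.0, opening = "luminal"),
                    tubuleFeature(zAt(18 / 30), 4.4, opening = "abluminal"),
                    tubuleFeature(zAt(25 / 30), 5.8,
                                  opening = "transendothelial")))
}

countsOf <- function(x, type, sub) {
  cts <- featureCounts(x)
  cts$count[cts$feature_type == type & cts$subtype == sub]
}
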