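# Simulated capillary cohorts: the study design is n capillaries per group,
# each capillary one phantom stack, per-stack feature counts Poisson around
# group means, compared between a control and an effect (diabetic-like)
# group.

#' Study-condition cohort template and feature means
#'
#' \code{cohortTemplate()} returns the phantom geometry used for simulated
#' cohorts: 300-section stacks (30 um of capillary depth, the upper end of
#' the 130-300 sections an SBF-SEM image set spans) with the default
#' cross-section geometry. \code{cohortMeanCounts()} returns the control
#' per-stack feature means: 9 peg-and-socket formations (3.0 per 10 um, one
#' in ten partially detached), rare detachments (0.6 endothelial, 0.6
#' pericyte, 0.3 macroglial per stack) and 9 tubules (7 closed, 1 luminal,
#' 1 abluminal, 0 transendothelial). \code{diabeticEffect()} returns the
#' effect multipliers defining the diabetic-like group: peg frequency x0.4,
#' detachment frequency x6, tubule frequency x2.5, lucent gap width x1.
#'
#' @return see description.
#' @name cohortDesign
NULL

#' @rdname cohortDesign
#' @export
cohortTemplate <- function() phantomSpec(nSlices = 300L)

#' @rdname cohortDesign
#' @export
cohortMeanCounts <- function() list(
  peg = c(attached = 8.1, partially_detached = 0.9),
  detachment = c(endothelium = 0.6, pericyte = 0.6, macroglia = 0.3),
  tubule = c(closed = 7, luminal = 1, abluminal = 1, transendothelial = 0))

#' @rdname cohortDesign
#' @export
diabeticEffect <- function() c(peg = 0.4, detachment = 6, tubule = 2.5, gap = 1)

meanCountsFromSpec <- function(spec) {
  pg <- spec@pegs; dt <- spec@detachments; tb <- spec@tubules
  list(
    peg = c(attached = sum(pg$state == "attached"),
            partially_detached = sum(pg$state == "partially_detached")),
    detachment = c(endothelium = sum(dt$target_role == "endothelium"),
                   pericyte = sum(dt$target_role == "pericyte"),
                   macroglia = sum(dt$target_role == "macroglia")),
    tubule = c(closed = sum(tb$opening == "closed"),
               luminal = sum(tb$opening == "luminal"),
               abluminal = sum(tb$opening == "abluminal"),
               transendothelial = sum(tb$opening == "transendothelial")))
}

# greedy non-overlapping placement of sampled features on the (z, theta)
# cylinder; returns NULL when a feature cannot be placed (caller drops it)
placeFeature <- function(placed, zExtent, hw, n, thetaRange, maxTries = 200L) {
  zHalf <- (zExtent - 1L) %/% 2L
  for (i in seq_len(maxTries)) {
    zc <- sample.int(n - zExtent + 1L, 1L) + zHalf
    th <- wrap2pi(runif(1, thetaRange[1], thetaRange[2]))
    z1 <- zc - zHalf; z2 <- z1 + zExtent - 1L
    clash <- FALSE
    for (p in placed)
      if (z1 <= p$z2 && p$z1 <= z2 && circDist(th, p$th) < hw + p$hw) {
        clash <- TRUE; break
      }
    if (!clash) return(list(z_center = zc, theta = th, z1 = z1, z2 = z2,
                            th = th, hw = hw))
  }
  NULL
}

groundTruthFromCounts <- function(pegC, detC, tubC, meanNm, maxNm, depthUm) {
  cts <- data.frame(
    feature_type = c("peg_socket", "peg_socket", "peg_socket",
                     "detachment", "detachment", "detachment", "detachment",
                     "tubule", "tubule", "tubule", "tubule", "tubule"),
    subtype = c("all", "attached", "partially_detached",
                "all", "endothelium", "pericyte", "macroglia",
                "all", "closed", "luminal", "abluminal", "transendothelial"),
    count = c(sum(pegC), pegC[["attached"]], pegC[["partially_detached"]],
              sum(detC), detC[["endothelium"]], detC[["pericyte"]],
              detC[["macroglia"]],
              sum(tubC), tubC[["closed"]], tubC[["luminal"]],
              tubC[["abluminal"]], tubC[["transendothelial"]]),
    stringsAsFactors = FALSE)
  cts$freq_per_10um <- cts$count * 10 / depthUm
  new("GroundTruth", analyticMeanNm = meanNm, analyticMaxNm = maxNm,
      depthUm = depthUm, counts = cts)
}

#' Simulate a cohort of capillary phantoms
#'
#' Draws \code{nStacks} phantoms from a template: per-stack feature counts
#' are Poisson with mean = control mean x effect multiplier, the BM base
#' thickness varies between capillaries (Gaussian, \code{bmBaseSdNm}), and
#' per-stack seeds derive deterministically from \code{rngSeed}. Placement
#' samples non-overlapping (z, arc) positions; in the rare case a feature
#' cannot be placed it is dropped and the ground truth reflects what was
#' actually planted.
#'
#' With \code{metricsOnly = TRUE} no features are placed and no specs built:
#' each element carries only the generative \linkS4class{GroundTruth}
#' (counts + analytic thickness). This is the mode for large simulation
#' studies (power, type-I error), where detector exactness has been
#' established separately. With \code{rasterize = TRUE} each element also
#' carries the rendered \code{volume} and \code{roleMap}.
#'
#' @param template a \linkS4class{PhantomSpec} (geometry; its planted
#'   features, if any, define the mean counts unless \code{meanCounts} is
#'   given).
#' @param nStacks number of capillaries (>= 1).
#' @param effect named multipliers \code{peg}, \code{detachment},
#'   \code{tubule}, \code{gap} (missing entries default to 1); must be
#'   non-negative.
#' @param rngSeed integer master seed.
#' @param meanCounts control means, see \code{\link{cohortMeanCounts}}.
#' @param bmBaseSdNm between-capillary SD of the BM base thickness (nm).
#' @param pegDetachedFraction if non-NULL, overrides the attached/detached
#'   split: each peg is partially detached with this probability.
#' @param metricsOnly,rasterize see description.
#' @param imagePx forwarded to \code{\link{generatePhantom}}.
#' @return list of per-stack lists (\code{spec}, \code{groundTruth},
#'   optionally \code{volume}, \code{roleMap}).
#' @export
makeCohort <- function(template, nStacks, effect = c(), rngSeed = 1L,
                       meanCounts = NULL, bmBaseSdNm = 8,
                       pegDetachedFraction = NULL, metricsOnly = FALSE,
                       rasterize = FALSE, imagePx = NULL) {
  stopifnot(is(template, "PhantomSpec"), nStacks >= 1)
  eff <- c(peg = 1, detachment = 1, tubule = 1, gap = 1)
  if (length(effect)) {
    unknown <- setdiff(names(effect), names(eff))
    if (length(unknown)) stop("unknown effect multiplier(s): ",
                              paste(unknown, collapse = ", "))
    if (any(effect < 0)) stop("effect multipliers must be non-negative")
    eff[names(effect)] <- effect
  }
  if (is.null(meanCounts)) {
    meanCounts <- meanCountsFromSpec(template)
    if (sum(unlist(meanCounts)) == 0) meanCounts <- cohortMeanCounts()
  }
  set.seed(rngSeed)
  stackSeeds <- sample.int(.Machine$integer.max - 1L, nStacks)

  dx <- template@voxelSizeNm[3]
  n <- template@nSlices
  arc <- template@pericyteArcRad
  rRef <- min(template@lumenRadiusNm) + 0.35 * template@endotheliumThicknessNm

  lapply(seq_len(nStacks), function(i) {
    set.seed(stackSeeds[i])
    base_i <- rnorm(1, template@bmBaseNm, bmBaseSdNm)
    base_i <- max(base_i, template@bmAmplitudeNm + 2 * dx + 2)
    pegC <- vapply(meanCounts$peg, function(m) rpois(1, m * eff["peg"]),
                   integer(1))
    if (!is.null(pegDetachedFraction)) {
      tot <- sum(pegC)
      det <- rbinom(1, tot, pegDetachedFraction)
      pegC <- c(attached = tot - det, partially_detached = det)
    }
    detC <- vapply(meanCounts$detachment,
                   function(m) rpois(1, m * eff["detachment"]), integer(1))
    tubC <- vapply(meanCounts$tubule,
                   function(m) rpois(1, m * eff["tubule"]), integer(1))

    depth <- n * template@voxelSizeNm[1] / 1000
    if (metricsOnly) {
      ats <- analyticThicknessSummary(
        phantomSpec(nSlices = n, voxelSizeNm = template@voxelSizeNm,
                    lumenRadiusNm = template@lumenRadiusNm,
                    endotheliumThicknessNm = template@endotheliumThicknessNm,
                    bmBaseNm = base_i, bmAmplitudeNm = template@bmAmplitudeNm,
                    bmThetaLobes = template@bmThetaLobes,
                    bmZPeriodNm = template@bmZPeriodNm))
      return(list(spec = NULL,
                  groundTruth = groundTruthFromCounts(
                    pegC, detC, tubC, unname(ats["mean_nm"]),
                    unname(ats["max_nm"]), depth),
                  seed = stackSeeds[i]))
    }

    # ---- placement ----
    placed <- list()
    pegRows <- emptyPegs(); detRows <- emptyDetachments()
    tubRows <- emptyTubules()
    gapNm <- 30 * eff[["gap"]]
    for (st in c("partially_detached", "attached")) {
      for (j in seq_len(pegC[[if (st == "attached") "attached"
                              else "partially_detached"]])) {
        g <- if (st == "partially_detached") gapNm else 0
        hw <- (30 + g + 4 * dx) / rRef
        pl <- placeFeature(placed, 3L, hw, n,
                           c(arc[1] + hw, arc[2] - hw))
        if (is.null(pl)) next
        placed[[length(placed) + 1L]] <- pl
        pegRows <- rbind(pegRows, pegFeature(pl$z_center, pl$theta,
                                             state = st, gap_nm = gapNm))
      }
    }
    detGap <- 24 * eff[["gap"]]
    arcR <- 0.35
    for (tr in names(detC)) for (j in seq_len(detC[[tr]])) {
      hw <- arcR / 2 + 4 * dx / rRef
      thetaRange <- switch(tr,
        pericyte = c(arc[1] + hw, arc[2] - hw),
        macroglia = c(arc[2] + hw, arc[1] + 2 * pi - hw),
        c(0, 2 * pi))
      pl <- placeFeature(placed, 3L, hw, n, thetaRange)
      if (is.null(pl)) next
      placed[[length(placed) + 1L]] <- pl
      detRows <- rbind(detRows, detachmentFeature(tr, pl$z_center, pl$theta,
                                                  arc_rad = arcR,
                                                  gap_nm = detGap))
    }
    for (op in names(tubC)) for (j in seq_len(tubC[[op]])) {
      hw <- (30 + 4 * dx) / rRef
      pl <- placeFeature(placed, 3L, hw, n, c(0, 2 * pi))
      if (is.null(pl)) next
      placed[[length(placed) + 1L]] <- pl
      tubRows <- rbind(tubRows, tubuleFeature(pl$z_center, pl$theta,
                                              opening = op))
    }

    sp <- phantomSpec(
      nSlices = n, voxelSizeNm = template@voxelSizeNm,
      lumenRadiusNm = template@lumenRadiusNm,
      endotheliumThicknessNm = template@endotheliumThicknessNm,
      bmBaseNm = base_i, bmAmplitudeNm = template@bmAmplitudeNm,
      bmThetaLobes = template@bmThetaLobes,
      bmZPeriodNm = template@bmZPeriodNm,
      pericyteArcRad = arc,
      pericyteThicknessNm = template@pericyteThicknessNm,
      macroglia = template@macroglia,
      macrogliaThicknessNm = template@macrogliaThicknessNm,
      pegs = pegRows, detachments = detRows, tubules = tubRows,
      rngSeed = stackSeeds[i])
    out <- list(spec = sp, groundTruth = groundTruthFromSpec(sp),
                seed = stackSeeds[i])
    if (rasterize) {
      ph <- generatePhantom(sp, imagePx = imagePx)
      out$volume <- ph$volume
      out$roleMap <- ph$roleMap
    }
    out
  })
}

countOf <- function(cts, type, sub) {
  cts$count[cts$feature_type == type & cts$subtype == sub]
}
freqOf <- function(cts, type, sub) {
  cts$freq_per_10um[cts$feature_type == type & cts$subtype == sub]
}

#' Per-capillary metrics table of a cohort
#'
#' One row per stack with the per-10-um feature frequencies and BM thickness
#' summaries, either from the generative ground truth
#' (\code{source = "ground_truth"}) or by running the detectors and the
#' thickness measurement on rasterised volumes (\code{source = "measured"};
#' requires \code{makeCohort(..., rasterize = TRUE)}).
#'
#' @param cohort result of \code{\link{makeCohort}}.
#' @param groupLabel value for the \code{group} column.
#' @param source see description.
#' @param params detector parameter overrides (measured mode).
#' @param thickness measure BM thickness in measured mode (slower).
#' @return data.frame, one row per capillary.
#' @export
cohortMetricsTable <- function(cohort, groupLabel,
                               source = c("ground_truth", "measured"),
                               params = list(), thickness = TRUE) {
  source <- match.arg(source)
  rows <- lapply(seq_along(cohort), function(i) {
    el <- cohort[[i]]
    if (source == "ground_truth") {
      gt <- el$groundTruth
      cts <- featureCounts(gt)
      bmMean <- aggregateMeanNm(gt); bmMax <- aggregateMaxNm(gt)
      depth <- depthUm(gt)
    } else {
      if (is.null(el$volume))
        stop("cohort was not rasterized; rerun makeCohort(rasterize = TRUE)")
      cm <- summarizeCapillary(el$volume, el$roleMap, params)
      cts <- featureCounts(cm)
      depth <- depthUm(cm)
      if (thickness) {
        tp <- stackThickness(el$volume, el$roleMap)
        bmMean <- aggregateMeanNm(tp); bmMax <- aggregateMaxNm(tp)
      } else bmMean <- bmMax <- NA_real_
    }
    data.frame(
      capillary = i, group = groupLabel, depth_um = depth,
      peg_per_10um = freqOf(cts, "peg_socket", "all"),
      peg_detached_per_10um = freqOf(cts, "peg_socket", "partially_detached"),
      detachment_endothelium_per_10um = freqOf(cts, "detachment", "endothelium"),
      detachment_pericyte_per_10um = freqOf(cts, "detachment", "pericyte"),
      detachment_macroglia_per_10um = freqOf(cts, "detachment", "macroglia"),
      detachment_per_10um = freqOf(cts, "detachment", "all"),
      tubule_per_10um = freqOf(cts, "tubule", "all"),
      transendothelial_count = countOf(cts, "tubule", "transendothelial"),
      bm_mean_nm = bmMean, bm_max_nm = bmMax)
  })
  do.call(rbind, rows)
}
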