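#' @import methods
#' @importFrom stats rnorm rpois runif rbinom pt pnorm sd var shapiro.test setNames
#' @importFrom utils combn packageVersion
#' @importFrom tools file_ext
NULL

#' Recognised neurovascular-unit roles
#'
#' The fixed vocabulary of biological roles a segmentation label may carry.
#' Label 0 is always \code{background} (electron-lucent / unsegmented space).
#'
#' @format Character vector of role names.
#' @export
NVU_ROLES <- c("background", "lumen", "endothelium", "pericyte",
               "basement_membrane", "macroglia", "tubule")

#' LabelVolume: an anisotropic 3D segmentation label grid
#'
#' Stores a stack of integer label sections together with the physical voxel
#' geometry. Voxels are held as an integer array with dimensions
#' \code{(y, x, z)} so that slice \code{k} is \code{voxelData(x)[, , k]};
#' page \code{k} of a multi-page TIFF corresponds to slice \code{z = k}.
#' Voxel sizes are carried in nanometres as \code{c(dz, dy, dx)} and the
#' axial step is kept independent of the in-plane sizes: the grid is never
#' resampled to isotropy.
#'
#' @slot voxels integer array, dim \code{(ny, nx, nz)}, labels >= 0.
#' @slot voxelSizeNm named numeric, \code{c(dz, dy, dx)} in nm; default
#'   \code{c(100, 6, 6)} (100 nm serial sections at 6 nm/pixel).
#' @export
setClass("LabelVolume",
  representation(voxels = "array", voxelSizeNm = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@voxels)
    if (length(d) != 3L) msg <- c(msg, "voxels must be a 3D array (y, x, z)")
    if (any(d < 1L)) msg <- c(msg, "all dimensions must be >= 1")
    if (!is.numeric(object@voxels) ||
        any(object@voxels < 0, na.rm = TRUE) ||
        anyNA(object@voxels) ||
        any(object@voxels != round(object@voxels)))
      msg <- c(msg, "labels must be non-negative integers")
    vs <- object@voxelSizeNm
    if (length(vs) != 3L || any(!is.finite(vs)) || any(vs <= 0))
      msg <- c(msg, "voxelSizeNm must be three strictly positive values (dz, dy, dx)")
    if (length(msg)) msg else TRUE
  })

#' Construct a LabelVolume
#'
#' @param voxels 3D integer array of labels, dim \code{(ny, nx, nz)}.
#' @param voxelSizeNm numeric length 3, \code{c(dz, dy, dx)} in nanometres.
#' @return A \linkS4class{LabelVolume}.
#' @examples
#' v <- LabelVolume(array(0L, c(8, 8, 3)))
#' nSlices(v)
#' @export
LabelVolume <- function(voxels, voxelSizeNm = c(dz = 100, dy = 6, dx = 6)) {
  storage.mode(voxels) <- "integer"
  voxelSizeNm <- as.numeric(voxelSizeNm)
  names(voxelSizeNm) <- c("dz", "dy", "dx")
  new("LabelVolume", voxels = voxels, voxelSizeNm = voxelSizeNm)
}

#' RoleMap: mapping from segmentation labels to NVU roles
#'
#' @slot roles named character vector; names are label ids (as characters),
#'   values are roles from \code{\link{NVU_ROLES}}. Label 0 must map to
#'   \code{background}.
#' @export
setClass("RoleMap",
  representation(roles = "character"),
  validity = function(object) {
    msg <- character()
    ids <- names(object@roles)
    if (is.null(ids) || anyNA(suppressWarnings(as.integer(ids))))
      msg <- c(msg, "role ids must be integer-valued names")
    if (anyDuplicated(ids)) msg <- c(msg, "duplicate label id in role map")
    if (!all(object@roles %in% NVU_ROLES))
      msg <- c(msg, paste0("unknown role(s): ",
        paste(setdiff(object@roles, NVU_ROLES), collapse = ", ")))
    if (!"0" %in% ids || object@roles[["0"]] != "background")
      msg <- c(msg, "label 0 must map to background")
    if (length(msg)) msg else TRUE
  })

#' Construct a RoleMap
#'
#' @param roles named character vector or list, label id -> role.
#' @return A \linkS4class{RoleMap}.
#' @examples
#' RoleMap(c(`0` = "background", `1` = "basement_membrane"))
#' @export
RoleMap <- function(roles) {
  roles <- unlist(roles)
  new("RoleMap", roles = roles[order(as.integer(names(roles)))])
}

#' PhantomSpec: parameters of a synthetic capillary phantom
#'
#' A phantom is a capillary cross-section stack with the capillary axis along
#' z: concentric lumen disc, endothelium annulus, basement-membrane (BM)
#' shell of angular/axial sinusoidally modulated thickness, a pericyte arc
#' and (optionally) a macroglial wrap outside the BM, plus planted
#' peg-and-socket formations, detachment gaps and endothelial tubules.
#' All geometry is specified in physical nanometres and rasterised by
#' centre-sampling on the anisotropic voxel grid.
#'
#' The shell thickness field is
#' \deqn{w(\theta, z) = base + amplitude \cdot \sin(k_\theta \theta + 2\pi z / z_{period})}
#'
#' @slot nSlices integer number of serial sections (1..10000; the study's
#'   stacks span 130-300).
#' @slot voxelSizeNm numeric \code{c(dz, dy, dx)} nm, default \code{(100, 6, 6)}.
#' @slot lumenRadiusNm numeric, scalar or per-slice profile.
#' @slot endotheliumThicknessNm numeric scalar.
#' @slot bmBaseNm,bmAmplitudeNm base and modulation amplitude of the BM
#'   thickness field (nm).
#' @slot bmThetaLobes integer angular wavenumber \eqn{k_\theta}.
#' @slot bmZPeriodNm axial period of the modulation (nm).
#' @slot pericyteArcRad numeric length 2, angular interval (start, end) in
#'   radians covered by the pericyte (end may exceed 2*pi).
#' @slot pericyteThicknessNm,macrogliaThicknessNm numeric scalars.
#' @slot macroglia logical, render a macroglial wrap on the remaining surface.
#' @slot pegs data.frame of planted peg-and-socket formations
#'   (\code{z_center, z_extent_slices, theta, radius_nm, state, gap_nm}).
#' @slot detachments data.frame of planted cell-BM gaps
#'   (\code{target_role, z_center, z_extent_slices, theta, arc_rad, gap_nm}).
#' @slot tubules data.frame of planted endothelial tubules
#'   (\code{z_center, z_extent_slices, theta, radius_nm, opening}).
#' @slot rngSeed integer seed (used only by optional boundary jitter and by
#'   cohort sampling; the phantom itself is deterministic).
#' @export
setClass("PhantomSpec",
  representation(
    nSlices = "integer", voxelSizeNm = "numeric",
    lumenRadiusNm = "numeric", endotheliumThicknessNm = "numeric",
    bmBaseNm = "numeric", bmAmplitudeNm = "numeric",
    bmThetaLobes = "integer", bmZPeriodNm = "numeric",
    pericyteArcRad = "numeric", pericyteThicknessNm = "numeric",
    macroglia = "logical", macrogliaThicknessNm = "numeric",
    pegs = "data.frame", detachments = "data.frame", tubules = "data.frame",
    rngSeed = "integer"),
  validity = function(object) validPhantomSpec(object))

#' GroundTruth: analytic summary and planted-feature inventory of a phantom
#'
#' @slot analyticMeanNm,analyticMaxNm quadrature mean and maximum of the BM
#'   thickness field (independent of rasterisation).
#' @slot depthUm capillary depth, \code{nSlices * dz / 1000}.
#' @slot counts data.frame with columns \code{feature_type, subtype, count,
#'   freq_per_10um}; frequencies are exactly \code{count * 10 / depthUm}.
#' @export
setClass("GroundTruth",
  representation(analyticMeanNm = "numeric", analyticMaxNm = "numeric",
                 depthUm = "numeric", counts = "data.frame"),
  validity = function(object) {
    msg <- character()
    if (!(object@analyticMaxNm >= object@analyticMeanNm &&
          object@analyticMeanNm > 0))
      msg <- c(msg, "analytic max must be >= analytic mean > 0")
    if (object@depthUm <= 0) msg <- c(msg, "depth must be positive")
    cts <- object@counts
    if (any(cts$count < 0) || any(cts$count != round(cts$count)))
      msg <- c(msg, "counts must be non-negative integers")
    if (any(abs(cts$freq_per_10um - cts$count * 10 / object@depthUm) > 1e-9))
      msg <- c(msg, "freq_per_10um must equal count * 10 / depthUm")
    if (length(msg)) msg else TRUE
  })

#' ThicknessProfile: per-slice and aggregate BM thickness of a stack
#'
#' @slot perSlice data.frame, one row per slice: \code{z, n_samples, mean_nm,
#'   max_nm, skipped}.
#' @slot samples list of numeric vectors, thickness samples (nm) per slice.
#' @slot aggregateMeanNm sample-count-weighted mean over all slices.
#' @slot aggregateMaxNm global maximum sample.
#' @slot nSamplesTotal integer.
#' @slot skippedSlices integer vector of z indices with an empty BM mask.
#' @export
setClass("ThicknessProfile",
  representation(perSlice = "data.frame", samples = "list",
                 aggregateMeanNm = "numeric", aggregateMaxNm = "numeric",
                 nSamplesTotal = "integer", skippedSlices = "integer"),
  validity = function(object) {
    msg <- character()
    all_s <- unlist(object@samples)
    if (length(all_s)) {
      if (any(all_s <= 0)) msg <- c(msg, "all thickness samples must be > 0")
      if (abs(object@aggregateMaxNm - max(all_s)) > 1e-9)
        msg <- c(msg, "aggregateMaxNm must equal the maximum sample")
      if (abs(object@aggregateMeanNm - mean(all_s)) > 1e-9)
        msg <- c(msg, "aggregateMeanNm must equal the pooled sample mean")
    }
    if (object@nSamplesTotal != length(all_s))
      msg <- c(msg, "nSamplesTotal inconsistent with samples")
    if (length(msg)) msg else TRUE
  })

#' CapillaryMetrics: feature counts and per-10-um frequencies for one stack
#'
#' @slot depthUm capillary depth in micrometres (\code{nSlices * dz / 1000}).
#' @slot nSlices integer.
#' @slot counts data.frame \code{feature_type, subtype, count, freq_per_10um}.
#' @slot events data.frame of individual feature events (see
#'   \code{\link{detectPegSockets}}).
#' @export
setClass("CapillaryMetrics",
  representation(depthUm = "numeric", nSlices = "integer",
                 counts = "data.frame", events = "data.frame"),
  validity = function(object) {
    cts <- object@counts
    msg <- character()
    if (any(cts$count < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(abs(cts$freq_per_10um - cts$count * 10 / object@depthUm) > 1e-9))
      msg <- c(msg, "freq_per_10um must equal count * 10 / depthUm")
    if (length(msg)) msg else TRUE
  })

#' ComparisonResult: a two-group comparison in the study's reporting style
#'
#' Mean, SEM (sd/sqrt(n) with the n-1 sample standard deviation) and n per
#' group, the test statistic and two-tailed p value, and significance flags
#' at the 0.05 / 0.01 / 0.001 thresholds with the figure-legend asterisk
#' notation.
#'
#' @slot metric character, name of the compared quantity (may be NA).
#' @slot testName \code{"student_t_unpaired"} or \code{"mann_whitney_u"}.
#' @slot method character note on how p was obtained (e.g. exact enumeration).
#' @slot statistic numeric (t or U).
#' @slot pTwoTailed numeric in [0, 1].
#' @slot groupLabels,groupNs,groupMeans,groupSems per-group descriptives
#'   (SEM is NA for n = 1).
#' @slot significantAt named logical for thresholds 0.05, 0.01, 0.001.
#' @slot stars character: "ns", "*", "**" or "***".
#' @export
setClass("ComparisonResult",
  representation(metric = "character", testName = "character",
                 method = "character", statistic = "numeric",
                 pTwoTailed = "numeric", groupLabels = "character",
                 groupNs = "integer", groupMeans = "numeric",
                 groupSems = "numeric", significantAt = "logical",
                 stars = "character"),
  validity = function(object) {
    msg <- character()
    p <- object@pTwoTailed
    if (!(p >= 0 && p <= 1)) msg <- c(msg, "p must lie in [0, 1]")
    want <- c(`0.05` = p < 0.05, `0.01` = p < 0.01, `0.001` = p < 0.001)
    if (!identical(unname(object@significantAt), unname(want)))
      msg <- c(msg, "significance flags inconsistent with p")
    if (length(msg)) msg else TRUE
  })

#' RunConfig: validated configuration for the end-to-end pipeline
#'
#' @slot seed integer master seed, recorded in every output artifact.
#' @slot outDir character output directory or NA (no files written).
#' @slot nPerGroup,nSlices integers for the simulated cohorts.
#' @slot effect named numeric multipliers defining the second (diabetic-like)
#'   group relative to the control template.
#' @slot detectorParams list of detector thresholds.
#' @slot testChoice "auto", "student_t" or "mann_whitney".
#' @slot rasterize logical; if TRUE stacks are rendered and analysed with the
#'   detectors, otherwise metrics come from the generative ground truth.
#' @slot thickness logical; measure BM thickness on rasterised stacks.
#' @slot groupLabels character length 2.
#' @slot template \linkS4class{PhantomSpec} cohort template.
#' @export
setClass("RunConfig",
  representation(seed = "integer", outDir = "character",
                 nPerGroup = "integer", nSlices = "integer",
                 effect = "numeric", detectorParams = "list",
                 testChoice = "character", rasterize = "logical",
                 thickness = "logical", groupLabels = "character",
                 template = "PhantomSpec"))

#' AnalysisReport: the end-to-end pipeline result
#'
#' @slot metrics per-capillary metrics table (one row per stack).
#' @slot events per-event table pooled over stacks.
#' @slot comparisons list of \linkS4class{ComparisonResult}.
#' @slot comparisonTable data.frame summary of the comparisons.
#' @slot seed integer seed the run used.
#' @slot configEcho list echoing the configuration.
#' @slot warnings character vector (skipped slices, boundary events, ...).
#' @slot version package version string.
#' @export
setClass("AnalysisReport",
  representation(metrics = "data.frame", events = "data.frame",
                 comparisons = "list", comparisonTable = "data.frame",
                 seed = "integer", configEcho = "list",
                 warnings = "character", version = "character"))
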