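#' @title Accessor generics
#' @description Accessors for the core containers. Slot access via \code{@}
#'   is internal; user code goes through these.
#' @param x an object.
#' @param ... further arguments for methods.
#' @return See the method documentation.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))

#' @rdname accessors
#' @export
setGeneric("voxelSizeNm", function(x) standardGeneric("voxelSizeNm"))

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname accessors
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' @rdname accessors
#' @export
setGeneric("roleLabels", function(x, role) standardGeneric("roleLabels"))

#' @rdname accessors
#' @export
setGeneric("depthUm", function(x) standardGeneric("depthUm"))

#' @rdname accessors
#' @export
setGeneric("featureCounts", function(x) standardGeneric("featureCounts"))

#' @rdname accessors
#' @export
setGeneric("aggregateMeanNm", function(x) standardGeneric("aggregateMeanNm"))

#' @rdname accessors
#' @export
setGeneric("aggregateMaxNm", function(x) standardGeneric("aggregateMaxNm"))

#' @rdname accessors
#' @export
setGeneric("perSlice", function(x) standardGeneric("perSlice"))

#' @rdname accessors
#' @export
setGeneric("thicknessSamples", function(x) standardGeneric("thicknessSamples"))

#' @rdname accessors
#' @export
setGeneric("skippedSlices", function(x) standardGeneric("skippedSlices"))

#' @rdname accessors
#' @export
setGeneric("featureEvents", function(x) standardGeneric("featureEvents"))

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname accessors
#' @export
setGeneric("testUsed", function(x) standardGeneric("testUsed"))

#' @rdname accessors
#' @export
setGeneric("metricsTable", function(x) standardGeneric("metricsTable"))

#' @rdname accessors
#' @export
setGeneric("comparisons", function(x) standardGeneric("comparisons"))

# ---- LabelVolume ----

#' @rdname accessors
#' @export
setMethod("voxelData", "LabelVolume", function(x) x@voxels)

#' @rdname accessors
#' @export
setMethod("voxelSizeNm", "LabelVolume", function(x) x@voxelSizeNm)

#' @rdname accessors
#' @export
setMethod("nSlices", "LabelVolume", function(x) dim(x@voxels)[3L])

#' @rdname accessors
#' @export
setMethod("dim", "LabelVolume", function(x) dim(x@voxels))

#' @rdname accessors
#' @export
setMethod("depthUm", "LabelVolume",
  function(x) dim(x@voxels)[3L] * x@voxelSizeNm[["dz"]] / 1000)

# ---- RoleMap ----

#' @rdname accessors
#' @export
setMethod("roles", "RoleMap", function(x) x@roles)

#' @describeIn accessors integer label ids mapping to \code{role} (possibly
#'   empty).
#' @param role a role name from \code{\link{NVU_ROLES}}.
#' @export
setMethod("roleLabels", "RoleMap", function(x, role) {
  if (!role %in% NVU_ROLES)
    stop("unknown role name: ", role, call. = FALSE)
  as.integer(names(x@roles)[x@roles == role])
})

# ---- GroundTruth / CapillaryMetrics ----

#' @rdname accessors
#' @export
setMethod("depthUm", "GroundTruth", function(x) x@depthUm)

#' @rdname accessors
#' @export
setMethod("featureCounts", "GroundTruth", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("aggregateMeanNm", "GroundTruth", function(x) x@analyticMeanNm)

#' @rdname accessors
#' @export
setMethod("aggregateMaxNm", "GroundTruth", function(x) x@analyticMaxNm)

#' @rdname accessors
#' @export
setMethod("depthUm", "CapillaryMetrics", function(x) x@depthUm)

#' @rdname accessors
#' @export
setMethod("nSlices", "CapillaryMetrics", function(x) x@nSlices)

#' @rdname accessors
#' @export
setMethod("featureCounts", "CapillaryMetrics", function(x) x@counts)

#' @rdname accessors
#' @export
setMethod("featureEvents", "CapillaryMetrics", function(x) x@events)

# ---- ThicknessProfile ----

#' @rdname accessors
#' @export
setMethod("aggregateMeanNm", "ThicknessProfile", function(x) x@aggregateMeanNm)

#' @rdname accessors
#' @export
setMethod("aggregateMaxNm", "ThicknessProfile", function(x) x@aggregateMaxNm)

#' @rdname accessors
#' @export
setMethod("perSlice", "ThicknessProfile", function(x) x@perSlice)

#' @rdname accessors
#' @export
setMethod("thicknessSamples", "ThicknessProfile",
  function(x) unlist(x@samples, use.names = FALSE))

#' @rdname accessors
#' @export
setMethod("skippedSlices", "ThicknessProfile", function(x) x@skippedSlices)

# ---- ComparisonResult / AnalysisReport ----

#' @rdname accessors
#' @export
setMethod("pValue", "ComparisonResult", function(x) x@pTwoTailed)

#' @rdname accessors
#' @export
setMethod("testUsed", "ComparisonResult", function(x) x@testName)

#' @rdname accessors
#' @export
setMethod("metricsTable", "AnalysisReport", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("comparisons", "AnalysisReport", function(x) x@comparisons)

# ---- show methods ----

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@voxels)
  vs <- object@voxelSizeNm
  cat(sprintf("LabelVolume: %d x %d px in-plane, %d slices\n", d[1], d[2], d[3]))
  cat(sprintf("  voxel size (dz, dy, dx): %g x %g x %g nm | depth %.2f um\n",
              vs[1], vs[2], vs[3], depthUm(object)))
  cat(sprintf("  labels present: %s\n",
              paste(sort(unique(as.vector(object@voxels))), collapse = " ")))
})

setMethod("show", "RoleMap", function(object) {
  cat("RoleMap:\n")
  for (id in names(object@roles))
    cat(sprintf("  %s -> %s\n", id, object@roles[[id]]))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf("PhantomSpec: %d slices, BM %g +/- %g nm (k_theta=%d)\n",
              object@nSlices, object@bmBaseNm, object@bmAmplitudeNm,
              object@bmThetaLobes))
  cat(sprintf("  planted: %d pegs, %d detachments, %d tubules\n",
              nrow(object@pegs), nrow(object@detachments), nrow(object@tubules)))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: depth %.2f um, analytic BM %.1f (mean) / %.1f (max) nm\n",
              object@depthUm, object@analyticMeanNm, object@analyticMaxNm))
  print(object@counts, row.names = FALSE)
})

setMethod("show", "ThicknessProfile", function(object) {
  cat(sprintf("ThicknessProfile: %d samples over %d slices (%d skipped)\n",
              object@nSamplesTotal,
              nrow(object@perSlice), length(object@skippedSlices)))
  cat(sprintf("  aggregate mean %.1f nm, max %.1f nm\n",
              object@aggregateMeanNm, object@aggregateMaxNm))
})

setMethod("show", "CapillaryMetrics", function(object) {
  cat(sprintf("CapillaryMetrics: depth %.2f um (%d slices), %d events\n",
              object@depthUm, object@nSlices, nrow(object@events)))
  print(object@counts, row.names = FALSE)
})

setMethod("show", "ComparisonResult", function(object) {
  cat(sprintf("%s (%s): %s vs %s\n",
              object@testName, object@method,
              object@groupLabels[1], object@groupLabels[2]))
  for (i in 1:2)
    cat(sprintf("  %s: mean %.4g +/- %.4g SEM (n=%d)\n", object@groupLabels[i],
                object@groupMeans[i], object@groupSems[i], object@groupNs[i]))
  cat(sprintf("  statistic %.4g, two-tailed p = %.4g %s\n",
              object@statistic, object@pTwoTailed, object@stars))
})

setMethod("show", "AnalysisReport", function(object) {
  cat(sprintf("AnalysisReport (nvumorph %s, seed %d): %d capillaries, %d comparisons\n",
              object@version, object@seed, nrow(object@metrics),
              length(object@comparisons)))
  print(object@comparisonTable, row.names = FALSE)
  if (length(object@warnings))
    cat("warnings:", length(object@warnings), "(see @warnings)\n")
})
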