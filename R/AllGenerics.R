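#' Accessors for consdyn data classes
#'
#' Small generic accessors so downstream code never touches slots directly.
#'
#' @param x a consdyn S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nTimepoints", function(x) standardGeneric("nTimepoints"))
#' @rdname accessors
#' @export
setGeneric("nRegions", function(x) standardGeneric("nRegions"))
#' @rdname accessors
#' @export
setGeneric("regionIds", function(x) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setGeneric("trSeconds", function(x) standardGeneric("trSeconds"))
#' @rdname accessors
#' @export
setGeneric("tsData", function(x) standardGeneric("tsData"))
#' @rdname accessors
#' @export
setGeneric("fcWeights", function(x) standardGeneric("fcWeights"))
#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname accessors
#' @export
setGeneric("taperWeights", function(x) standardGeneric("taperWeights"))
#' @rdname accessors
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))
#' @rdname accessors
#' @export
setGeneric("windowMatrices", function(x) standardGeneric("windowMatrices"))
#' @rdname accessors
#' @export
setGeneric("windowStarts", function(x) standardGeneric("windowStarts"))
#' @rdname accessors
#' @export
setGeneric("mapData", function(x) standardGeneric("mapData"))
#' @rdname accessors
#' @export
setGeneric("mapMask", function(x) standardGeneric("mapMask"))
#' @rdname accessors
#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))
#' @rdname accessors
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @rdname accessors
#' @export
setGeneric("modularityQ", function(x) standardGeneric("modularityQ"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("fractionIntegrated", function(x) standardGeneric("fractionIntegrated"))
#' @rdname accessors
#' @export
setGeneric("stateCentroid", function(x, state) standardGeneric("stateCentroid"))

#' @rdname accessors
setMethod("nTimepoints", "RoiTimeseries", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nTimepoints", "VolumeSeries", function(x) dim(x@data)[4])
#' @rdname accessors
setMethod("nRegions", "RoiTimeseries", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nRegions", "FCMatrix", function(x) nrow(x@weights))
#' @rdname accessors
setMethod("regionIds", "RoiTimeseries", function(x) colnames(x@data))
#' @rdname accessors
setMethod("regionIds", "FCMatrix", function(x) rownames(x@weights))
#' @rdname accessors
setMethod("regionIds", "DynamicFCSeries", function(x) x@regionIds)
#' @rdname accessors
setMethod("trSeconds", "RoiTimeseries", function(x) x@trSeconds)
#' @rdname accessors
setMethod("trSeconds", "VolumeSeries", function(x) x@trSeconds)
#' @rdname accessors
setMethod("tsData", "RoiTimeseries", function(x) x@data)
#' @rdname accessors
setMethod("tsData", "VolumeSeries", function(x) x@data)
#' @rdname accessors
setMethod("fcWeights", "FCMatrix", function(x) x@weights)
#' @rdname accessors
setMethod("fcWeights", "BrainGraph", function(x) x@weights)
#' @rdname accessors
setMethod("provenance", "FCMatrix", function(x) x@provenance)
#' @rdname accessors
setMethod("taperWeights", "TaperWindow", function(x) x@weights)
#' @rdname accessors
setMethod("nWindows", "DynamicFCSeries", function(x) length(x@matrices))
#' @rdname accessors
setMethod("windowMatrices", "DynamicFCSeries", function(x) x@matrices)
#' @rdname accessors
setMethod("windowStarts", "DynamicFCSeries", function(x) x@windowStarts)
#' @rdname accessors
setMethod("mapData", "VoxelMap", function(x) x@data)
#' @rdname accessors
setMethod("mapMask", "VoxelMap", function(x) x@mask)
#' @rdname accessors
setMethod("mapKind", "VoxelMap", function(x) x@kind)
#' @rdname accessors
setMethod("moduleAssignment", "ModulePartition", function(x) x@assignment)
#' @rdname accessors
setMethod("modularityQ", "ModulePartition", function(x) x@qValue)
#' @rdname accessors
setMethod("stateLabels", "StateAssignment", function(x) x@labels)
#' @rdname accessors
setMethod("fractionIntegrated", "StateAssignment", function(x) x@fractionIntegrated)
#' @rdname accessors
#' @param state "integrated" or "segregated".
setMethod("stateCentroid", "StateAssignment", function(x, state) {
  state <- match.arg(state, c("integrated", "segregated"))
  if (state == "integrated") x@centroidIntegrated else x@centroidSegregated
})

setMethod("show", "RoiTimeseries", function(object) {
  cat(sprintf("RoiTimeseries: %d timepoints x %d regions (TR = %gs)\n",
              nrow(object@data), ncol(object@data), object@trSeconds))
  cat(sprintf("  subject: %s  condition: %s\n", object@subjectId, object@condition))
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeSeries: %dx%dx%d grid, %d timepoints, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], sum(object@mask)))
})

setMethod("show", "FCMatrix", function(object) {
  cat(sprintf("FCMatrix (%s): %d x %d, weight range [%.3f, %.3f]\n",
              object@provenance, nrow(object@weights), ncol(object@weights),
              min(object@weights), max(object@weights)))
})

setMethod("show", "TaperWindow", function(object) {
  cat(sprintf("TaperWindow: %d taps (rect %g TR * gaussian sigma %g TR), step %g TR\n",
              length(object@weights), object@rectLengthTr,
              object@gaussianSigmaTr, object@stepTr))
})

setMethod("show", "DynamicFCSeries", function(object) {
  cat(sprintf("DynamicFCSeries: %d windows of %d regions (%d-tap taper)\n",
              length(object@matrices), length(object@regionIds),
              length(object@taper@weights)))
})

setMethod("show", "VoxelMap", function(object) {
  cat(sprintf("VoxelMap (%s): %s grid, %d in-mask voxels\n", object@kind,
              paste(dim(object@data), collapse = "x"), sum(object@mask)))
})

setMethod("show", "BrainGraph", function(object) {
  cat(sprintf("BrainGraph: %d nodes, %d edges (density %.3f%s)\n",
              nrow(object@weights), sum(object@weights[upper.tri(object@weights)] > 0),
              object@density, if (object@binarized) ", binarised" else ""))
})

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition: %d modules over %d nodes, Q = %.4f (gamma %g)\n",
              object@nModules, length(object@assignment), object@qValue,
              object@gamma))
})

setMethod("show", "CartographicProfile", function(object) {
  cat(sprintf("CartographicProfile: %d windows, %d x %d PC/z bins\n",
              nrow(object@histograms), length(object@binsP) - 1L,
              length(object@binsZ) - 1L))
})

setMethod("show", "StateAssignment", function(object) {
  cat(sprintf("StateAssignment: %d windows, %.1f%% integrated (inertia %.4f)\n",
              length(object@labels), 100 * object@fractionIntegrated,
              object@kmeansInertia))
})
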