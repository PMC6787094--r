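#' ROI timeseries container
#'
#' Holds a T x N matrix of denoised regional BOLD signals together with the
#' sampling interval (TR). Region identifiers are kept as column names.
#'
#' @slot data numeric matrix, one row per timepoint, one column per region.
#' @slot trSeconds positive scalar, repetition time in seconds.
#' @slot subjectId character scalar label.
#' @slot condition character scalar label (e.g. "awake", "deep").
#'
#' @examples
#' ts <- RoiTimeseries(matrix(rnorm(40), 10, 4), trSeconds = 2)
#' nTimepoints(ts)
#' @export
setClass("RoiTimeseries",
  representation(data = "matrix", trSeconds = "numeric",
                 subjectId = "character", condition = "character"))

setValidity("RoiTimeseries", function(object) {
  d <- object@data
  if (!is.numeric(d)) return("data must be numeric")
  if (nrow(d) < 2L) return("fewer than 2 timepoints")
  if (ncol(d) < 2L) return("fewer than 2 regions")
  if (anyNA(d) || any(!is.finite(d))) return("data contains missing or non-finite values")
  if (is.null(colnames(d))) return("region ids (column names) are required")
  if (anyDuplicated(colnames(d))) return("region ids must be unique")
  if (length(object@trSeconds) != 1L || object@trSeconds <= 0)
    return("trSeconds must be a positive scalar")
  TRUE
})

#' @param data,trSeconds,subjectId,condition see slots.
#' @rdname RoiTimeseries-class
#' @export
RoiTimeseries <- function(data, trSeconds, subjectId = "subject",
                          condition = "unspecified") {
  data <- as.matrix(data)
  if (is.null(colnames(data)))
    colnames(data) <- sprintf("R%03d", seq_len(ncol(data)))
  new("RoiTimeseries", data = data, trSeconds = as.numeric(trSeconds),
      subjectId = subjectId, condition = condition)
}

#' 4D volumetric timeseries with a brain mask
#'
#' @slot data numeric X x Y x Z x T array.
#' @slot mask logical X x Y x Z array; analyses are restricted to TRUE voxels.
#' @slot voxelSizeMm numeric length-3, voxel edge lengths in mm.
#' @slot trSeconds positive scalar.
#' @export
setClass("VolumeSeries",
  representation(data = "array", mask = "array", voxelSizeMm = "numeric",
                 trSeconds = "numeric"))

setValidity("VolumeSeries", function(object) {
  if (length(dim(object@data)) != 4L) return("data must be a 4D array")
  if (dim(object@data)[4] < 2L) return("fewer than 2 timepoints")
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    return("mask must be a 3D logical array")
  if (!identical(dim(object@mask), dim(object@data)[1:3]))
    return("mask dimensions must match the spatial grid of data")
  if (!any(object@mask)) return("mask has no TRUE voxel")
  if (length(object@voxelSizeMm) != 3L || any(object@voxelSizeMm <= 0))
    return("voxelSizeMm must be 3 positive reals")
  if (object@trSeconds <= 0) return("trSeconds must be positive")
  TRUE
})

#' @param data,mask,voxelSizeMm,trSeconds see slots.
#' @rdname VolumeSeries-class
#' @export
VolumeSeries <- function(data, mask = NULL, voxelSizeMm = c(2, 2, 2),
                         trSeconds = 2) {
  if (is.null(mask)) mask <- array(TRUE, dim(data)[1:3])
  new("VolumeSeries", data = data, mask = mask,
      voxelSizeMm = as.numeric(voxelSizeMm), trSeconds = as.numeric(trSeconds))
}

.fcProvenances <- c("static", "window", "centroid_integrated",
                    "centroid_segregated", "mean_difference",
                    "common_difference")

#' Functional connectivity matrix
#'
#' Symmetric signed matrix of edge weights between regions. For correlation
#' matrices (provenance "static", "window" or a state centroid) entries lie in
#' [-1, 1] with unit diagonal; difference matrices may exceed that range and
#' have zero diagonal. The diagonal is ignored by all downstream metrics.
#'
#' @slot weights symmetric numeric N x N matrix; region ids as dimnames.
#' @slot provenance one of static, window, centroid_integrated,
#'   centroid_segregated, mean_difference, common_difference.
#' @export
setClass("FCMatrix",
  representation(weights = "matrix", provenance = "character"))

setValidity("FCMatrix", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (any(!is.finite(w))) return("weights must be finite")
  if (length(w) > 0 && max(abs(w - t(w))) > 1e-8)
    return("weights must be symmetric")
  if (!object@provenance %in% .fcProvenances)
    return(sprintf("unknown provenance '%s'", object@provenance))
  TRUE
})

#' @param weights,provenance see slots.
#' @param regionIds optional character vector of region labels.
#' @rdname FCMatrix-class
#' @export
FCMatrix <- function(weights, provenance = "static", regionIds = NULL) {
  weights <- as.matrix(weights)
  weights <- (weights + t(weights)) / 2  # enforce exact symmetry
  if (!is.null(regionIds)) dimnames(weights) <- list(regionIds, regionIds)
  if (is.null(rownames(weights))) {
    ids <- sprintf("R%03d", seq_len(nrow(weights)))
    dimnames(weights) <- list(ids, ids)
  }
  new("FCMatrix", weights = weights, provenance = provenance)
}

#' Tapered sliding-window shape
#'
#' Weights of a symmetric taper obtained by convolving a rectangle with a
#' Gaussian kernel; used as observation weights in windowed correlation.
#'
#' @slot weights nonnegative numeric vector summing to one.
#' @slot rectLengthTr integer rectangle length in TRs (default 22).
#' @slot gaussianSigmaTr Gaussian kernel SD in TRs (default 3).
#' @slot stepTr window step in TRs (default 1).
#' @seealso [buildTaper()]
#' @export
setClass("TaperWindow",
  representation(weights = "numeric", rectLengthTr = "numeric",
                 gaussianSigmaTr = "numeric", stepTr = "numeric"))

setValidity("TaperWindow", function(object) {
  w <- object@weights
  if (any(w < 0)) return("taper weights must be nonnegative")
  if (abs(sum(w) - 1) > 1e-10) return("taper weights must sum to 1")
  if (max(abs(w - rev(w))) > 1e-10) return("taper must be symmetric about its centre")
  TRUE
})

#' Ordered sequence of windowed FC matrices
#'
#' @slot matrices list of W symmetric numeric matrices (one per window).
#' @slot windowStarts integer vector of 0-based first-tap indices.
#' @slot taper the [TaperWindow-class] used.
#' @slot regionIds character region labels shared by all windows.
#' @export
setClass("DynamicFCSeries",
  representation(matrices = "list", windowStarts = "integer",
                 taper = "TaperWindow", regionIds = "character"))

setValidity("DynamicFCSeries", function(object) {
  W <- length(object@matrices)
  if (W < 1L) return("no windows")
  if (length(object@windowStarts) != W)
    return("windowStarts length must match number of windows")
  if (W > 1L && any(diff(object@windowStarts) <= 0))
    return("windowStarts must be strictly increasing")
  TRUE
})

.voxelMapKinds <- c("icc_raw", "icc_norm", "sampen", "mask", "seed_corr", "stat")

#' Voxelwise scalar map on a masked grid
#'
#' @slot data numeric 3D array; values are meaningful only inside the mask.
#' @slot mask logical 3D array.
#' @slot kind map type: icc_raw, icc_norm, sampen, mask, seed_corr or stat.
#' @slot voxelSizeMm numeric length-3 voxel size in mm.
#' @export
setClass("VoxelMap",
  representation(data = "array", mask = "array", kind = "character",
                 voxelSizeMm = "numeric"))

setValidity("VoxelMap", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (!identical(dim(object@data), dim(object@mask)))
    return("mask dimensions must match data")
  if (!object@kind %in% .voxelMapKinds)
    return(sprintf("unknown map kind '%s'", object@kind))
  TRUE
})

#' @param data,mask,kind,voxelSizeMm see slots.
#' @rdname VoxelMap-class
#' @export
VoxelMap <- function(data, mask = NULL, kind = "stat", voxelSizeMm = c(2, 2, 2)) {
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  new("VoxelMap", data = data, mask = mask, kind = kind,
      voxelSizeMm = as.numeric(voxelSizeMm))
}

#' Thresholded brain graph
#'
#' Nonnegative weighted (or binarised) adjacency matrix produced by
#' proportional thresholding of an FC matrix. No self-loops.
#'
#' @slot weights nonnegative symmetric matrix.
#' @slot density realised edge density in (0, 1].
#' @slot binarized logical; TRUE if retained edges were set to 1.
#' @export
setClass("BrainGraph",
  representation(weights = "matrix", density = "numeric", binarized = "logical"))

setValidity("BrainGraph", function(object) {
  w <- object@weights
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (any(w < 0)) return("thresholded weights must be nonnegative")
  if (any(diag(w) != 0)) return("self-loops are not allowed")
  if (max(abs(w - t(w))) > 1e-10) return("weights must be symmetric")
  TRUE
})

#' Module partition of a signed network
#'
#' @slot assignment integer vector; module of node i, labelled 1..nModules
#'   contiguously.
#' @slot nModules integer number of modules.
#' @slot qValue signed modularity Q of the assignment.
#' @slot gamma resolution parameter used.
#' @seealso [louvainSigned()], [signedModularity()]
#' @export
setClass("ModulePartition",
  representation(assignment = "integer", nModules = "integer",
                 qValue = "numeric", gamma = "numeric"))

setValidity("ModulePartition", function(object) {
  a <- object@assignment
  if (!identical(sort(unique(a)), seq_len(object@nModules)))
    return("modules must be labelled 1..nModules contiguously")
  if (object@gamma <= 0) return("gamma must be positive")
  TRUE
})

#' Cartographic profile of a dynamic FC series
#'
#' Per-window joint histograms of node participation coefficients and
#' within-module z-scores, row-normalised to proportions; the feature vectors
#' used to cluster windows into integrated and segregated states.
#'
#' @slot histograms W x (Bp * Bz) matrix, each row summing to 1. Bin index
#'   runs fastest over participation bins.
#' @slot binsP numeric vector of Bp + 1 participation bin edges over [0, 1].
#' @slot binsZ numeric vector of Bz + 1 z-score bin edges over [-5, 5].
#' @slot meanPcPerWindow numeric vector of per-window mean participation.
#' @export
setClass("CartographicProfile",
  representation(histograms = "matrix", binsP = "numeric", binsZ = "numeric",
                 meanPcPerWindow = "numeric"))

setValidity("CartographicProfile", function(object) {
  h <- object@histograms
  if (any(h < 0)) return("histogram proportions must be nonnegative")
  if (max(abs(rowSums(h) - 1)) > 1e-8) return("histogram rows must sum to 1")
  if (length(object@meanPcPerWindow) != nrow(h))
    return("meanPcPerWindow length must match number of windows")
  TRUE
})

#' Integrated/segregated state assignment of time windows
#'
#' @slot labels character vector over windows, "integrated" or "segregated".
#' @slot centroidIntegrated,centroidSegregated state centroid
#'   [FCMatrix-class] objects (elementwise medians of member windows); may be
#'   empty (0 x 0) when only labels were computed.
#' @slot fractionIntegrated proportion of windows in the integrated state.
#' @slot kmeansInertia total within-cluster correlation distance of the best
#'   k-means restart.
#' @slot nRestarts,seed clustering reproducibility metadata.
#' @export
setClass("StateAssignment",
  representation(labels = "character", centroidIntegrated = "FCMatrix",
                 centroidSegregated = "FCMatrix", fractionIntegrated = "numeric",
                 kmeansInertia = "numeric", nRestarts = "integer",
                 seed = "integer"))

setValidity("StateAssignment", function(object) {
  if (!all(object@labels %in% c("integrated", "segregated")))
    return("labels must be 'integrated' or 'segregated'")
  fi <- mean(object@labels == "integrated")
  if (abs(fi - object@fractionIntegrated) > 1e-10)
    return("fractionIntegrated inconsistent with labels")
  TRUE
})
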