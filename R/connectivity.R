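#' Static functional connectivity
#'
#' Pairwise Pearson correlation between regional timecourses over the full
#' scan length.
#'
#' @param ts a [RoiTimeseries-class].
#' @return an [FCMatrix-class] with provenance "static".
#' @export
staticFC <- function(ts) {
  stopifnot(is(ts, "RoiTimeseries"))
  sds <- apply(ts@data, 2, sd)
  if (any(sds == 0))
    stop("constant region timecourse(s): ",
         paste(colnames(ts@data)[sds == 0], collapse = ", "))
  FCMatrix(cor(ts@data), provenance = "static")
}

#' Build the tapered sliding-window shape
#'
#' Convolves a rectangle of `rectLength` TRs with a Gaussian kernel of SD
#' `sigma` TRs and keeps the central `rectLength + 1` taps of the full
#' convolution, renormalised to sum one. For an even rectangle the Gaussian
#' is sampled on a half-integer grid so the product is exactly symmetric.
#' With the defaults (22-TR rectangle, sigma 3) the taper has 23 taps, which
#' yields T - 22 windows when slid with a 1-TR step. `sigma = 0` is the
#' degenerate limit and returns the bare rectangle.
#'
#' @param rectLength rectangle length in TRs (default 22).
#' @param sigma Gaussian SD in TRs (default 3).
#' @param step window step in TRs (default 1).
#' @return a [TaperWindow-class].
#' @examples
#' length(taperWeights(buildTaper()))  # 23
#' @export
buildTaper <- function(rectLength = 22L, sigma = 3, step = 1L) {
  if (rectLength < 2L) stop("rectLength must be >= 2")
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) {
    w <- rep(1 / rectLength, rectLength)
    return(new("TaperWindow", weights = w, rectLengthTr = rectLength,
               gaussianSigmaTr = 0, stepTr = as.numeric(step)))
  }
  halfGrid <- rectLength %% 2L == 0L
  K <- ceiling(3 * sigma)
  offs <- if (halfGrid) seq(-K + 0.5, K - 0.5, by = 1) else seq(-K, K)
  kern <- dnorm(offs, sd = sigma)
  kern <- kern / sum(kern)
  full <- convolve(rep(1, rectLength), rev(kern), type = "open")
  Lw <- rectLength + 1L
  start <- (length(full) - Lw) %/% 2L + 1L
  w <- full[start:(start + Lw - 1L)]
  w <- (w + rev(w)) / 2  # remove floating-point asymmetry
  w <- w / sum(w)
  new("TaperWindow", weights = w, rectLengthTr = rectLength,
      gaussianSigmaTr = sigma, stepTr = as.numeric(step))
}

# Weighted Pearson correlation of the rows of `seg` using taper weights as
# observation weights (weighted means/covariances, not signal multiplication).
.weightedCor <- function(seg, w) {
  cw <- cov.wt(seg, wt = w, cor = TRUE, method = "ML")
  cw$cor
}

#' Dynamic (sliding-window) functional connectivity
#'
#' For every window start, computes the weighted Pearson correlation matrix
#' of the regional timecourses using the taper weights as observation
#' weights. With a taper of L taps and step 1, a T-timepoint series yields
#' T - L + 1 windows (229 windows for T = 251, 273 for T = 295 under the
#' default taper).
#'
#' @param ts a [RoiTimeseries-class].
#' @param taper a [TaperWindow-class]; default [buildTaper()].
#' @return a [DynamicFCSeries-class].
#' @export
dynamicFC <- function(ts, taper = buildTaper()) {
  stopifnot(is(ts, "RoiTimeseries"), is(taper, "TaperWindow"))
  w <- taper@weights
  L <- length(w)
  Tn <- nrow(ts@data)
  if (Tn < L + 1L)
    stop("need at least ", L + 1L, " timepoints for a ", L, "-tap taper")
  step <- max(1L, as.integer(round(taper@stepTr)))
  starts <- seq(1L, Tn - L + 1L, by = step)
  mats <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    s <- starts[k]
    seg <- ts@data[s:(s + L - 1L), , drop = FALSE]
    cm <- .weightedCor(seg, w)
    if (any(!is.finite(cm))) {
      bad <- colnames(seg)[!is.finite(diag(cm)) | colSums(!is.finite(cm)) > 0]
      stop(sprintf("zero weighted variance in window starting at %d (regions: %s)",
                   s - 1L, paste(unique(bad), collapse = ", ")))
    }
    dimnames(cm) <- list(colnames(ts@data), colnames(ts@data))
    mats[[k]] <- cm
  }
  new("DynamicFCSeries", matrices = mats, windowStarts = as.integer(starts - 1L),
      taper = taper, regionIds = colnames(ts@data))
}

#' Seed-based correlation
#'
#' Pearson correlation between a seed timecourse and every other region (ROI
#' input) or every in-mask voxel (volumetric input, seed given as a voxel
#' mask whose in-mask series are averaged).
#'
#' @param x a [RoiTimeseries-class] or [VolumeSeries-class].
#' @param seed for ROI input, a region label; for volumetric input, a logical
#'   3D array marking the seed voxels.
#' @return a named numeric vector of correlations (ROI input) or a
#'   [VoxelMap-class] of kind "seed_corr".
#' @export
seedCorrelationMap <- function(x, seed) {
  if (is(x, "RoiTimeseries")) {
    if (!seed %in% colnames(x@data)) stop("seed region not found: ", seed)
    sv <- x@data[, seed]
    if (sd(sv) == 0) stop("seed series is constant")
    return(drop(cor(sv, x@data)[1, ]))
  }
  stopifnot(is(x, "VolumeSeries"))
  if (!identical(dim(seed), dim(x@mask))) stop("seed mask grid mismatch")
  sVox <- which(seed & x@mask)
  if (length(sVox) == 0L) stop("empty seed")
  Tn <- dim(x@data)[4]
  flat <- matrix(x@data, ncol = Tn)
  sv <- colMeans(flat[sVox, , drop = FALSE])
  if (sd(sv) == 0) stop("seed series is constant")
  vox <- which(x@mask)
  r <- drop(cor(sv, t(flat[vox, , drop = FALSE]))[1, ])
  out <- array(0, dim(x@mask)); out[vox] <- r
  VoxelMap(out, x@mask, kind = "seed_corr", voxelSizeMm = x@voxelSizeMm)
}
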