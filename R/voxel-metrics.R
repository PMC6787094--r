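#' Sample entropy of a timeseries
#'
#' SampEn = -log(A/B), where B counts unordered pairs of distinct length-m
#' templates whose Chebyshev distance is at most r, and A counts the same for
#' length-(m + 1) templates. Both lengths use the same T - m templates, so a
#' perfectly predictable constant series gives A = B and SampEn exactly 0.
#' The tolerance is `r = rFactor` times the population standard deviation of
#' the series, making the measure invariant to affine rescaling.
#'
#' @param series numeric vector, length at least m + 2.
#' @param m template length (default 3).
#' @param rFactor tolerance as a multiple of the series SD (default 0.6).
#' @return a list of class `SampEnResult` with elements `value` (NA when no
#'   template pair matches at either length), `nMatchesMPlus1` (A),
#'   `nMatchesM` (B), `m`, `r` and `defined`.
#' @examples
#' sampleEntropy(rep(1, 100))$value          # exactly 0
#' sampleEntropy(rnorm(200))$value           # positive for white noise
#' @export
sampleEntropy <- function(series, m = 3L, rFactor = 0.6) {
  series <- as.numeric(series)
  if (m < 1L) stop("m must be >= 1")
  if (rFactor <= 0) stop("rFactor must be positive")
  if (length(series) < m + 2L)
    stop("series too short: need at least m + 2 = ", m + 2L, " points")
  sdPop <- sqrt(mean((series - mean(series))^2))
  r <- rFactor * sdPop
  counts <- .sampenCounts(series, as.integer(m), r)
  A <- counts[["A"]]; B <- counts[["B"]]
  defined <- A > 0 && B > 0
  value <- if (defined) -log(A / B) else NA_real_
  structure(list(value = value, nMatchesMPlus1 = A, nMatchesM = B,
                 m = as.integer(m), r = r, defined = defined),
            class = "SampEnResult")
}

#' @export
print.SampEnResult <- function(x, ...) {
  if (x$defined) {
    cat(sprintf("SampEn = %.4f (m = %d, r = %.4g; A = %g, B = %g)\n",
                x$value, x$m, x$r, x$nMatchesMPlus1, x$nMatchesM))
  } else {
    cat(sprintf("SampEn undefined (no matches; m = %d, r = %.4g)\n", x$m, x$r))
  }
  invisible(x)
}

#' Voxelwise sample entropy map
#'
#' Applies [sampleEntropy()] to every in-mask voxel. Voxels whose SampEn is
#' undefined (no template matches) are excluded from the output mask.
#'
#' @param vol a [VolumeSeries-class].
#' @param m,rFactor see [sampleEntropy()].
#' @return a [VoxelMap-class] of kind "sampen".
#' @export
sampenMap <- function(vol, m = 3L, rFactor = 0.6) {
  stopifnot(is(vol, "VolumeSeries"))
  vox <- which(vol@mask)
  if (length(vox) == 0L) stop("empty mask")
  Tn <- dim(vol@data)[4]
  flat <- matrix(vol@data, ncol = Tn)
  vals <- vapply(vox, function(v) {
    res <- sampleEntropy(flat[v, ], m = m, rFactor = rFactor)
    if (res$defined) res$value else NA_real_
  }, numeric(1))
  out <- array(0, dim(vol@data)[1:3])
  mask <- array(FALSE, dim(vol@data)[1:3])
  ok <- !is.na(vals)
  if (any(!ok))
    warning(sum(!ok), " voxels had undefined SampEn and were masked out")
  out[vox[ok]] <- vals[ok]
  mask[vox[ok]] <- TRUE
  VoxelMap(out, mask, kind = "sampen", voxelSizeMm = vol@voxelSizeMm)
}

#' Intrinsic connectivity contrast map
#'
#' For every in-mask voxel i, the raw ICC is the sum over all other in-mask
#' voxels j of the squared Pearson correlation between their timeseries: a
#' degree-like measure of global connectivity. Zero-variance voxels are
#' excluded with a warning. Normalise with [normalizeZscoreMap()].
#'
#' @param vol a [VolumeSeries-class].
#' @return a [VoxelMap-class] of kind "icc_raw".
#' @export
iccMap <- function(vol) {
  stopifnot(is(vol, "VolumeSeries"))
  vox <- which(vol@mask)
  if (length(vox) < 2L) stop("need at least 2 in-mask voxels")
  Tn <- dim(vol@data)[4]
  flat <- matrix(vol@data, ncol = Tn)
  Y <- t(flat[vox, , drop = FALSE])  # time x voxels
  sds <- apply(Y, 2, sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance in-mask voxels excluded from ICC")
    vox <- vox[sds > 0]
    Y <- Y[, sds > 0, drop = FALSE]
    if (ncol(Y) < 2L) stop("fewer than 2 voxels with nonzero variance")
  }
  R <- cor(Y)
  icc <- rowSums(R^2) - 1  # remove the self-correlation term
  out <- array(0, dim(vol@data)[1:3])
  mask <- array(FALSE, dim(vol@data)[1:3])
  out[vox] <- icc
  mask[vox] <- TRUE
  VoxelMap(out, mask, kind = "icc_raw", voxelSizeMm = vol@voxelSizeMm)
}

#' Z-score normalise a voxel map
#'
#' Subtracts the in-mask mean and divides by the in-mask population SD, so
#' the output distribution has zero mean and unit variance. A constant input
#' map yields all zeros.
#'
#' @param map a [VoxelMap-class].
#' @return a [VoxelMap-class]; kind "icc_raw" becomes "icc_norm".
#' @export
normalizeZscoreMap <- function(map) {
  stopifnot(is(map, "VoxelMap"))
  vals <- map@data[map@mask]
  if (length(vals) < 2L) stop("need at least 2 in-mask voxels")
  mu <- mean(vals)
  sdp <- sqrt(mean((vals - mu)^2))
  z <- if (sdp == 0) rep(0, length(vals)) else (vals - mu) / sdp
  out <- map
  out@data[map@mask] <- z
  out@data[!map@mask] <- 0
  if (map@kind == "icc_raw") out@kind <- "icc_norm"
  out
}

# 1D zero-padded convolution along a given axis of a 3D array
.convAxis <- function(arr, kernel, axis) {
  d <- dim(arr)
  r <- (length(kernel) - 1L) / 2L
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  da <- dim(a)
  m <- matrix(a, nrow = da[1])
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (k in seq_along(kernel)) {
    off <- k - 1L - r
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    out[ok, ] <- out[ok, ] + kernel[k] * m[src[ok], , drop = FALSE]
  }
  aperm(array(out, da), order(perm))
}

#' Gaussian smoothing of a voxel map
#'
#' Separable 3D Gaussian convolution with per-axis
#' `sigma = fwhm / (2 sqrt(2 log 2))` converted to voxel units. Smoothing is
#' mask-aware: the smoothed map is divided by the smoothed mask, avoiding
#' dimming at mask edges; a uniform map is returned unchanged.
#'
#' @param map a [VoxelMap-class].
#' @param fwhmMm kernel full width at half maximum in mm (e.g. 10).
#' @return a smoothed [VoxelMap-class].
#' @export
smoothMapGaussian <- function(map, fwhmMm) {
  stopifnot(is(map, "VoxelMap"))
  if (fwhmMm < 0) stop("fwhm must be nonnegative")
  sigmaVox <- fwhmMm / (2 * sqrt(2 * log(2))) / map@voxelSizeMm
  if (all(sigmaVox < 1e-6)) return(map)
  kernels <- lapply(sigmaVox, function(s) {
    if (s < 1e-6) return(1)
    r <- max(1L, ceiling(4 * s))
    k <- dnorm(seq(-r, r), sd = s)
    k / sum(k)
  })
  num <- map@data
  num[!map@mask] <- 0
  den <- array(as.numeric(map@mask), dim(map@mask))
  for (ax in 1:3) {
    if (length(kernels[[ax]]) > 1L) {
      num <- .convAxis(num, kernels[[ax]], ax)
      den <- .convAxis(den, kernels[[ax]], ax)
    }
  }
  out <- map
  sm <- array(0, dim(num))
  sm[map@mask] <- num[map@mask] / den[map@mask]
  out@data <- sm
  out
}

#' Binarise maps and take their voxelwise overlap
#'
#' Each map is binarised by its own threshold (voxel passes if value >=
#' threshold, within the map's mask); the result is the voxelwise logical AND
#' across all maps — e.g. intersecting significance maps of entropy and ICC
#' reductions within and then across datasets.
#'
#' @param maps list of [VoxelMap-class] objects on the same grid.
#' @param thresholds numeric vector, one threshold per map.
#' @return a [VoxelMap-class] of kind "mask" (data 0/1).
#' @export
binarizeAndOverlap <- function(maps, thresholds) {
  stopifnot(length(maps) >= 1L, length(thresholds) == length(maps))
  d0 <- dim(maps[[1]]@data)
  overlap <- array(TRUE, d0)
  mask <- array(TRUE, d0)
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    if (!identical(dim(m@data), d0)) stop("maps must share a voxel grid")
    overlap <- overlap & (m@data >= thresholds[i]) & m@mask
    mask <- mask & m@mask
  }
  VoxelMap(array(as.numeric(overlap), d0), mask, kind = "mask",
           voxelSizeMm = maps[[1]]@voxelSizeMm)
}
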