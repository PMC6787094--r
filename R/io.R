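#' Read an ROI timeseries table
#'
#' Reads a tab-separated table with a header row of region labels and one row
#' per timepoint. Optionally drops initial volumes (dummy scans acquired
#' before magnetisation equilibrium); the pipeline default is 5.
#'
#' @param path path to a TSV file.
#' @param trSeconds repetition time in seconds.
#' @param dropInitial number of initial timepoints to discard (default 0).
#' @param subjectId,condition labels stored with the object.
#' @return a [RoiTimeseries-class].
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeRoiTimeseries(RoiTimeseries(matrix(1:6, 3, 2), 2), f)
#' readRoiTimeseries(f, trSeconds = 2)
#' @export
readRoiTimeseries <- function(path, trSeconds, dropInitial = 0L,
                              subjectId = "subject", condition = "unspecified") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) < 2L) stop("fewer than 2 timepoints in ", path)
  m <- matrix(NA_real_, nrow(df), ncol(df), dimnames = list(NULL, colnames(df)))
  for (j in seq_len(ncol(df))) {
    v <- suppressWarnings(as.numeric(df[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("non-numeric entry at row %d, column '%s' in %s",
                   bad, colnames(df)[j], path))
    }
    m[, j] <- v
  }
  if (dropInitial > 0L) {
    if (nrow(m) - dropInitial < 2L)
      stop("fewer than 2 timepoints remain after dropping initial scans")
    m <- m[-seq_len(dropInitial), , drop = FALSE]
  }
  RoiTimeseries(m, trSeconds, subjectId = subjectId, condition = condition)
}

#' Write an ROI timeseries table
#'
#' @param ts a [RoiTimeseries-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeRoiTimeseries <- function(ts, path) {
  stopifnot(is(ts, "RoiTimeseries"))
  write.table(ts@data, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Read a confound regressor table
#'
#' TSV with a header of confound names and one row per timepoint (e.g. six
#' realignment parameters, their derivatives, noise components).
#'
#' @param path TSV path.
#' @return numeric matrix with confound names as column names.
#' @export
readConfounds <- function(path) {
  df <- read.delim(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("confound table contains non-finite values")
  m
}

#' Read a 4D NIfTI volume series
#'
#' @param path NIfTI (.nii/.nii.gz) path to a 4D image.
#' @param maskPath optional NIfTI path to a 3D mask (nonzero = in mask).
#' @param trSeconds repetition time; if NULL, taken from the NIfTI header.
#' @return a [VolumeSeries-class].
#' @export
readVolumeSeries <- function(path, maskPath = NULL, trSeconds = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  if (length(dim(arr)) != 4L) stop("expected a 4D image: ", path)
  pix <- RNifti::pixdim(img)
  if (is.null(trSeconds)) {
    trSeconds <- if (length(pix) >= 4) pix[4] else 2
    if (!is.finite(trSeconds) || trSeconds <= 0) trSeconds <- 2
  }
  mask <- if (is.null(maskPath)) NULL else {
    marr <- RNifti::readNifti(maskPath)
    array(as.numeric(marr) != 0, dim(marr)[1:3])
  }
  VolumeSeries(arr, mask = mask, voxelSizeMm = pix[1:3], trSeconds = trSeconds)
}

#' Read an integer-labelled atlas volume
#'
#' @param path NIfTI path to a 3D label image (0 = background).
#' @return integer 3D array.
#' @export
readAtlasVolume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.integer(round(as.numeric(img))), dim(img)[1:3])
  arr
}

#' Write a voxel map as NIfTI plus a TSV summary
#'
#' @param map a [VoxelMap-class].
#' @param path output NIfTI path; a sibling `.tsv` (voxel index, value) is
#'   written alongside unless `tsv = FALSE`.
#' @param tsv write the TSV summary too?
#' @return `path`, invisibly.
#' @export
writeVoxelMap <- function(map, path, tsv = TRUE) {
  stopifnot(is(map, "VoxelMap"))
  out <- map@data
  out[!map@mask] <- 0
  img <- RNifti::asNifti(out, reference = NULL)
  RNifti::pixdim(img) <- map@voxelSizeMm
  RNifti::writeNifti(img, path)
  if (tsv) {
    idx <- which(map@mask, arr.ind = TRUE) - 1L  # 0-based voxel addressing
    df <- data.frame(x = idx[, 1], y = idx[, 2], z = idx[, 3],
                     value = map@data[map@mask])
    write.table(df, paste0(sub("\\.nii(\\.gz)?$", "", path), ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Average voxel timeseries within atlas parcels
#'
#' Averages the series of all in-mask voxels sharing a nonzero atlas label,
#' producing one regional timecourse per label, in ascending label order.
#'
#' @param vol a [VolumeSeries-class].
#' @param atlas integer 3D array on the same grid; 0 marks background.
#' @return a [RoiTimeseries-class] with one column per retained label.
#' @export
parcellateVolume <- function(vol, atlas) {
  stopifnot(is(vol, "VolumeSeries"))
  if (!identical(dim(atlas), dim(vol@data)[1:3]))
    stop("atlas grid does not match the volume grid")
  labs <- sort(unique(atlas[atlas > 0]))
  if (length(labs) == 0L) stop("atlas contains no nonzero labels")
  Tn <- dim(vol@data)[4]
  vmask <- vol@mask
  inPar <- atlas > 0 & vmask
  vlab <- atlas[inPar]
  flat <- matrix(vol@data, ncol = Tn)  # voxels x time
  vmat <- flat[which(inPar), , drop = FALSE]
  counts <- tabulate(match(vlab, labs), nbins = length(labs))
  empty <- labs[counts == 0L]
  if (length(empty)) {
    warning("atlas labels with no in-mask voxels dropped: ",
            paste(empty, collapse = ", "))
    labs <- labs[counts > 0L]
    if (length(labs) == 0L) stop("no atlas label has in-mask voxels")
  }
  sums <- rowsum(vmat, group = factor(vlab, levels = labs))
  means <- sums / as.numeric(table(factor(vlab, levels = labs)))
  out <- t(means)
  colnames(out) <- as.character(labs)
  RoiTimeseries(out, vol@trSeconds)
}

# c * tanh(x / c) squashing of the demeaned series; c = 4 * MAD.
.despikeSeries <- function(x) {
  mu <- mean(x)
  d <- x - mu
  c0 <- 4 * mad(d)
  if (c0 <= 0) return(x)  # (near-)constant series left alone
  mu + c0 * tanh(d / c0)
}

# Joint OLS removal of intercept, linear trend and confounds; collinear
# confound columns (after adding the trend) are dropped with a warning.
.regressOut <- function(Y, confounds) {
  Tn <- nrow(Y)
  X <- cbind(intercept = 1, trend = seq_len(Tn) - (Tn + 1) / 2)
  if (!is.null(confounds) && ncol(confounds) > 0) {
    if (nrow(confounds) != Tn)
      stop("confound table has ", nrow(confounds), " rows but timeseries has ", Tn)
    X <- cbind(X, confounds)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      keep <- qrX$pivot[seq_len(qrX$rank)]
      dropped <- setdiff(seq_len(ncol(X)), keep)
      warning("dropping collinear confound columns: ",
              paste(colnames(X)[dropped], collapse = ", "))
      X <- X[, sort(keep), drop = FALSE]
    }
  }
  Y - X %*% qr.solve(qr(X), Y)
}

.bandpassMatrix <- function(Y, bandHz, trSeconds) {
  nyq <- 1 / (2 * trSeconds)
  low <- bandHz[1]; high <- bandHz[2]
  if (low < 0 || low >= high || high >= nyq)
    stop(sprintf("band (%g, %g) Hz must satisfy 0 <= low < high < Nyquist (%g Hz)",
                 low, high, nyq))
  filt <- if (low > 0) {
    signal::butter(4, c(low, high) / nyq, type = "pass")
  } else {
    signal::butter(4, high / nyq, type = "low")
  }
  apply(Y, 2, function(col) signal::filtfilt(filt, col))
}

#' Denoise timeseries: despiking, confound regression, band-pass
#'
#' Applies, in order: (1) optional hyperbolic-tangent despiking
#' (`x -> c tanh(x/c)` with `c` = 4 MAD of the demeaned series), (2) joint
#' ordinary-least-squares removal of an intercept, a linear trend and any
#' confound regressors, (3) zero-phase 4th-order Butterworth band-pass
#' applied forward and backward (length-preserving). Output series have
#' numerically zero mean and zero linear trend.
#'
#' @param ts a [RoiTimeseries-class] or [VolumeSeries-class].
#' @param confounds optional numeric T x K matrix of confound regressors.
#' @param bandHz length-2 numeric `(low, high)` in Hz, or NULL to skip
#'   filtering. Default `c(0.008, 0.09)`.
#' @param despike apply tanh despiking first? Default FALSE.
#' @return an object of the same class as `ts`.
#' @examples
#' ramp <- RoiTimeseries(cbind(a = 1:50, b = seq(2, 100, 2)), trSeconds = 2)
#' max(abs(tsData(denoiseTimeseries(ramp, bandHz = NULL))))  # ~0: pure trend
#' @export
denoiseTimeseries <- function(ts, confounds = NULL, bandHz = c(0.008, 0.09),
                              despike = FALSE) {
  if (is(ts, "VolumeSeries")) {
    Tn <- dim(ts@data)[4]
    flat <- matrix(ts@data, ncol = Tn)
    vox <- which(ts@mask)
    Y <- t(flat[vox, , drop = FALSE])
    Yd <- .denoiseMatrix(Y, confounds, bandHz, despike, ts@trSeconds)
    flat[vox, ] <- t(Yd)
    out <- ts
    out@data <- array(flat, dim(ts@data))
    return(out)
  }
  stopifnot(is(ts, "RoiTimeseries"))
  out <- ts
  out@data <- .denoiseMatrix(ts@data, confounds, bandHz, despike, ts@trSeconds)
  colnames(out@data) <- colnames(ts@data)
  validObject(out)
  out
}

.denoiseMatrix <- function(Y, confounds, bandHz, despike, trSeconds) {
  if (despike) Y <- apply(Y, 2, .despikeSeries)
  Y <- .regressOut(Y, confounds)
  if (!is.null(bandHz)) {
    Y <- .bandpassMatrix(Y, bandHz, trSeconds)
    # filtering can reintroduce a minute mean/trend component at the edges;
    # project it out again so the stated postcondition holds exactly
    Y <- .regressOut(Y, NULL)
  }
  Y
}

#' Extract principal-component noise regressors (aCompCor style)
#'
#' Returns the first k principal-component score timecourses of a
#' column-demeaned noise-voxel matrix (e.g. white matter or CSF signals),
#' ordered by decreasing explained variance and unit-normalised.
#'
#' @param noise numeric T x V matrix of noise-tissue voxel series.
#' @param k number of components.
#' @return T x k matrix with columns `PC1..PCk` and attribute
#'   `"explainedVariance"` (the corresponding variances).
#' @export
extractNoiseComponents <- function(noise, k) {
  noise <- as.matrix(noise)
  if (k > min(dim(noise)))
    stop("k = ", k, " exceeds min(T, V) = ", min(dim(noise)))
  pr <- prcomp(noise, center = TRUE, scale. = FALSE)
  sc <- pr$x[, seq_len(k), drop = FALSE]
  sc <- sweep(sc, 2, sqrt(colSums(sc^2)), "/")
  colnames(sc) <- sprintf("PC%d", seq_len(k))
  attr(sc, "explainedVariance") <- pr$sdev[seq_len(k)]^2
  sc
}
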