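#' Node-wise normalised connectivity entropy
#'
#' For every node, the N - 1 off-diagonal connectivity values in its column
#' are assigned to `nBins` equal-width bins over the fixed range [-1, 1]
#' (values outside clip into the outer bins), and the Shannon entropy of the
#' resulting proportions is normalised by log(nBins) — the entropy of a
#' uniform distribution — so H lies in [0, 1]. H = 0 when all values fall in
#' one bin; H = 1 when all bins are filled in exactly equal proportion.
#'
#' @param fc an [FCMatrix-class] or symmetric matrix.
#' @param nBins number of bins (default 10).
#' @return list of class `ConnectivityEntropyResult`: `nodeEntropy` (length
#'   N, in [0, 1]), `binProbabilities` (N x nBins), `nBins`, `globalMean`.
#' @examples
#' fc <- FCMatrix(cor(matrix(rnorm(600), 30, 20)))
#' range(connectivityEntropyNodes(fc)$nodeEntropy)
#' @export
connectivityEntropyNodes <- function(fc, nBins = 10L) {
  W <- if (is(fc, "FCMatrix")) fc@weights else as.matrix(fc)
  if (nBins < 2L) stop("nBins must be >= 2")
  N <- nrow(W)
  edges <- seq(-1, 1, length.out = nBins + 1L)
  P <- matrix(0, N, nBins)
  H <- numeric(N)
  for (i in seq_len(N)) {
    vals <- W[-i, i]
    b <- findInterval(pmin(pmax(vals, -1), 1), edges,
                      rightmost.closed = TRUE, all.inside = TRUE)
    p <- tabulate(b, nbins = nBins) / length(vals)
    P[i, ] <- p
    pp <- p[p > 0]
    H[i] <- -sum(pp * log(pp)) / log(nBins)
  }
  names(H) <- rownames(W)
  structure(list(nodeEntropy = H, binProbabilities = P,
                 nBins = as.integer(nBins), globalMean = mean(H)),
            class = "ConnectivityEntropyResult")
}

#' @export
print.ConnectivityEntropyResult <- function(x, ...) {
  cat(sprintf("Connectivity entropy over %d nodes (n = %d bins): mean %.4f, range [%.4f, %.4f]\n",
              length(x$nodeEntropy), x$nBins, x$globalMean,
              min(x$nodeEntropy), max(x$nodeEntropy)))
  invisible(x)
}

#' Mean connectivity entropy per resting-state network
#'
#' @param res a `ConnectivityEntropyResult` from
#'   [connectivityEntropyNodes()].
#' @param labels character vector of network labels (e.g. the 7-network
#'   scheme DMN, SOM, VIS, SAL, DAN, FPN, LIM), one per node.
#' @return named numeric vector of unweighted within-network means.
#' @export
summarizeByNetwork <- function(res, labels) {
  stopifnot(inherits(res, "ConnectivityEntropyResult"))
  if (length(labels) != length(res$nodeEntropy))
    stop("labels must cover all ", length(res$nodeEntropy), " nodes")
  means <- tapply(res$nodeEntropy, labels, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out
}
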