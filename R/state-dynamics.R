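#' Cartographic profiles of a dynamic FC series
#'
#' For every window: detect modules on the signed window matrix with
#' [louvainSigned()], compute node participation coefficients and
#' within-module z-scores with [nodeCartography()], and bin the (P, z) pairs
#' into a joint histogram (defaults 10 x 10 bins, P over [0, 1], z over
#' [-5, 5] with values clipped into the outer bins), row-normalised to
#' proportions. These per-window feature vectors are the input to
#' [kmeansStates()].
#'
#' @param dfc a [DynamicFCSeries-class].
#' @param gamma Louvain resolution (default 1).
#' @param nRepeats Louvain restarts per window (default 100).
#' @param seed optional RNG seed governing all windows.
#' @param binsP,binsZ numbers of participation and z-score bins.
#' @return a [CartographicProfile-class].
#' @export
cartographicProfiles <- function(dfc, gamma = 1, nRepeats = 100L, seed = NULL,
                                 binsP = 10L, binsZ = 10L) {
  stopifnot(is(dfc, "DynamicFCSeries"))
  W <- length(dfc@matrices)
  if (W < 2L) stop("need at least 2 windows")
  if (!is.null(seed)) set.seed(seed)
  pEdges <- seq(0, 1, length.out = binsP + 1L)
  zEdges <- seq(-5, 5, length.out = binsZ + 1L)
  H <- matrix(0, W, binsP * binsZ)
  meanPc <- numeric(W)
  for (k in seq_len(W)) {
    m <- dfc@matrices[[k]]
    part <- louvainSigned(m, gamma = gamma, nRepeats = nRepeats)
    cart <- nodeCartography(m, part)
    H[k, ] <- .jointHistRow(cart$participation, cart$withinModuleZ,
                            pEdges, zEdges)
    meanPc[k] <- mean(cart$participation)
  }
  new("CartographicProfile", histograms = H, binsP = pEdges, binsZ = zEdges,
      meanPcPerWindow = meanPc)
}

# Flattened joint histogram of (P, z) pairs as proportions; participation
# bin index runs fastest. Out-of-range values clip into the outer bins.
.jointHistRow <- function(p, z, pEdges, zEdges) {
  nP <- length(pEdges) - 1L
  nZ <- length(zEdges) - 1L
  pi <- findInterval(pmin(pmax(p, pEdges[1]), pEdges[nP + 1L]), pEdges,
                     rightmost.closed = TRUE, all.inside = TRUE)
  zi <- findInterval(pmin(pmax(z, zEdges[1]), zEdges[nZ + 1L]), zEdges,
                     rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate((zi - 1L) * nP + pi, nbins = nP * nZ)
  counts / length(p)
}

# k-means with distance 1 - Pearson(r) between rows; mean centroid update;
# empty clusters reseeded at the point farthest from its assigned centroid.
.kmeansCorr <- function(X, k, nRestarts, maxIter = 100L) {
  W <- nrow(X)
  rsd <- apply(X, 1, sd)
  if (any(rsd == 0))
    stop("degenerate input: constant histogram row(s) ",
         paste(which(rsd == 0), collapse = ", "))
  normRows <- function(M) {
    Mc <- M - rowMeans(M)
    nrm <- sqrt(rowSums(Mc^2))
    Mc / nrm
  }
  Xn <- normRows(X)
  best <- NULL
  for (r in seq_len(nRestarts)) {
    centers <- X[sample.int(W, k), , drop = FALSE]
    assign <- rep(0L, W)
    for (it in seq_len(maxIter)) {
      Cn <- normRows(centers)
      sim <- Xn %*% t(Cn)              # Pearson r between rows and centroids
      newAssign <- max.col(sim, ties.method = "first")
      for (cl in seq_len(k)) {         # reseed empty clusters
        if (!any(newAssign == cl)) {
          far <- which.min(sim[cbind(seq_len(W), newAssign)])
          newAssign[far] <- cl
        }
      }
      if (identical(newAssign, assign)) break
      assign <- newAssign
      centers <- do.call(rbind, lapply(seq_len(k), function(cl)
        colMeans(X[assign == cl, , drop = FALSE])))
    }
    inertia <- sum(1 - sim[cbind(seq_len(W), assign)])
    if (is.null(best) || inertia < best$inertia - 1e-12)
      best <- list(assign = assign, inertia = inertia)
  }
  best
}

#' Cluster windows into integrated and segregated states
#'
#' k-means (k = 2) on the cartographic histogram rows with correlation
#' distance (1 - Pearson r), repeated `nRestarts` times with random
#' re-initialisation; the best restart by total within-cluster distance is
#' kept. The cluster whose member windows have the higher mean participation
#' coefficient is labelled "integrated", the other "segregated".
#'
#' @param profile a [CartographicProfile-class].
#' @param k number of clusters (default 2; only 2 receives state labels).
#' @param nRestarts random restarts (default 500).
#' @param seed optional RNG seed.
#' @return a [StateAssignment-class] with labels, occupancy fraction and
#'   inertia (centroid matrices are filled in by [deriveStates()]).
#' @export
kmeansStates <- function(profile, k = 2L, nRestarts = 500L, seed = NULL) {
  stopifnot(is(profile, "CartographicProfile"))
  X <- profile@histograms
  if (nrow(X) < k) stop("fewer windows than clusters")
  if (!is.null(seed)) set.seed(seed)
  res <- .kmeansCorr(X, k, nRestarts)
  sizes <- tabulate(res$assign, nbins = k)
  if (any(sizes == 0L))
    stop("degenerate clustering: a cluster is empty after the best restart")
  meanPc <- tapply(profile@meanPcPerWindow, res$assign, mean)
  intCluster <- which.max(meanPc)
  labels <- ifelse(res$assign == intCluster, "integrated", "segregated")
  emptyFC <- FCMatrix(matrix(numeric(0), 0, 0), provenance = "centroid_integrated")
  new("StateAssignment", labels = labels,
      centroidIntegrated = emptyFC,
      centroidSegregated = FCMatrix(matrix(numeric(0), 0, 0),
                                    provenance = "centroid_segregated"),
      fractionIntegrated = mean(labels == "integrated"),
      kmeansInertia = res$inertia, nRestarts = as.integer(nRestarts),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' State centroid matrices
#'
#' Elementwise median of the window FC matrices assigned to each state.
#'
#' @param dfc a [DynamicFCSeries-class].
#' @param labels character vector over windows ("integrated"/"segregated"),
#'   e.g. from [stateLabels()].
#' @return list with `integrated` and `segregated` [FCMatrix-class] objects.
#' @export
stateCentroids <- function(dfc, labels) {
  stopifnot(is(dfc, "DynamicFCSeries"))
  if (length(labels) != length(dfc@matrices))
    stop("labels length must equal number of windows")
  med <- function(state, prov) {
    members <- dfc@matrices[labels == state]
    if (length(members) == 0L) stop("empty state: ", state)
    arr <- simplify2array(members)
    FCMatrix(apply(arr, c(1, 2), median), provenance = prov,
             regionIds = dfc@regionIds)
  }
  list(integrated = med("integrated", "centroid_integrated"),
       segregated = med("segregated", "centroid_segregated"))
}

#' Time spent in each state
#'
#' @param labels character vector of window state labels.
#' @return named numeric: `fractionIntegrated`, `fractionSegregated`
#'   (summing to 1).
#' @export
timeInState <- function(labels) {
  if (length(labels) < 1L) stop("no windows")
  fi <- mean(labels == "integrated")
  c(fractionIntegrated = fi, fractionSegregated = 1 - fi)
}

#' Full state derivation for one subject and condition
#'
#' Convenience wrapper chaining [cartographicProfiles()], [kmeansStates()]
#' and [stateCentroids()] into a complete [StateAssignment-class].
#'
#' @param dfc a [DynamicFCSeries-class].
#' @param gamma,nRepeats passed to [cartographicProfiles()].
#' @param nRestarts passed to [kmeansStates()].
#' @param seed RNG seed covering profiling and clustering.
#' @return a [StateAssignment-class] with centroids filled in.
#' @export
deriveStates <- function(dfc, gamma = 1, nRepeats = 100L, nRestarts = 500L,
                         seed = NULL) {
  profile <- cartographicProfiles(dfc, gamma = gamma, nRepeats = nRepeats,
                                  seed = seed)
  st <- kmeansStates(profile, k = 2L, nRestarts = nRestarts)
  cents <- stateCentroids(dfc, st@labels)
  st@centroidIntegrated <- cents$integrated
  st@centroidSegregated <- cents$segregated
  st
}
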