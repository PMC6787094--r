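#' Proportional thresholding of an FC matrix
#'
#' Retains the ceiling(density * N(N-1)/2) strongest edges ranked by signed
#' weight (anticorrelations are treated as weak, so negative edges drop out
#' first), zeroing the rest; ties are broken by (row, column) order. Retained
#' edges are set to 1 when `binarize = TRUE`. A thresholded brain graph must
#' be nonnegative, so any retained nonpositive weight (possible only at high
#' densities on matrices with many anticorrelations) is dropped with a
#' warning.
#'
#' @param fc an [FCMatrix-class].
#' @param density target edge density in (0, 1].
#' @param binarize set retained edges to 1?
#' @return a [BrainGraph-class].
#' @export
proportionalThreshold <- function(fc, density, binarize = FALSE) {
  stopifnot(is(fc, "FCMatrix"))
  if (density <= 0 || density > 1) stop("density must be in (0, 1]")
  w <- fc@weights
  diag(w) <- 0
  N <- nrow(w)
  ut <- which(upper.tri(w))
  nPairs <- length(ut)
  k <- ceiling(density * nPairs)
  if (k < 1L) stop("density retains no edges")
  vals <- w[ut]
  ord <- order(-vals, row(w)[ut], col(w)[ut])  # ties: (i, j) lexicographic
  keep <- ut[ord[seq_len(k)]]
  out <- matrix(0, N, N, dimnames = dimnames(w))
  out[keep] <- if (binarize) 1 else vals[ord[seq_len(k)]]
  if (any(out[keep] <= 0)) {
    nDrop <- sum(out[keep] <= 0)
    warning(nDrop, " retained edges had nonpositive weight and were dropped")
    out[keep][out[keep] <= 0] <- 0
  }
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  new("BrainGraph", weights = out, density = k / nPairs, binarized = binarize)
}

#' Signed modularity of a partition (direct evaluation)
#'
#' Evaluates the asymmetric two-term signed modularity
#' \deqn{Q = \frac{1}{v^+}\sum_{ij}(w^+_{ij} - \gamma e^+_{ij})\delta_{M_iM_j}
#'   - \frac{1}{v^+ + v^-}\sum_{ij}(w^-_{ij} - \gamma e^-_{ij})\delta_{M_iM_j}}
#' with strength-product chance terms \eqn{e^\pm_{ij} = s^\pm_i s^\pm_j / v^\pm}
#' summed over all node pairs (including i = j), so a uniform all-positive
#' complete graph scores Q = 0 for the single-module partition.
#'
#' @param W symmetric signed weight matrix (diagonal ignored).
#' @param assignment integer module labels, one per node.
#' @param gamma resolution parameter (default 1).
#' @return scalar Q.
#' @export
signedModularity <- function(W, assignment, gamma = 1) {
  W <- as.matrix(W)
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  D <- outer(assignment, assignment, "==")
  Qp <- if (vp > 0) (sum(Wp[D]) - gamma * sum(outer(sp, sp)[D]) / vp) / vp else 0
  Qn <- if (vn > 0) (sum(Wn[D]) - gamma * sum(outer(sn, sn)[D]) / vn) else 0
  Qp - if (vp + vn > 0) Qn / (vp + vn) else 0
}

#' Signed Louvain community detection
#'
#' Runs the Louvain greedy algorithm for signed weighted networks (positive
#' weights reward within-module placement at full strength; negative weights
#' penalise it with the smaller asymmetric scaling) `nRepeats` times with
#' randomised node sweep orders, and returns the partition with the highest
#' signed modularity Q, recomputed from the assignment via
#' [signedModularity()]. Ties keep the first occurrence.
#'
#' @param fc an [FCMatrix-class] or a symmetric numeric matrix.
#' @param gamma resolution parameter (default 1).
#' @param nRepeats number of randomised restarts (default 100).
#' @param seed optional RNG seed for reproducibility.
#' @return a [ModulePartition-class].
#' @export
louvainSigned <- function(fc, gamma = 1, nRepeats = 100L, seed = NULL) {
  W <- if (is(fc, "FCMatrix")) fc@weights else as.matrix(fc)
  diag(W) <- 0
  if (all(W == 0)) stop("all-zero matrix: no community structure to detect")
  if (!is.null(seed)) set.seed(seed)
  res <- .louvainBest(W, gamma, as.integer(nRepeats))
  a <- as.integer(factor(res$assignment, levels = unique(res$assignment)))
  new("ModulePartition", assignment = a, nModules = max(a),
      qValue = signedModularity(W, a, gamma), gamma = as.numeric(gamma))
}

#' Cartographic node measures: participation coefficient and within-module z
#'
#' Computes, from positive weights only, each node's participation
#' coefficient \eqn{P_i = 1 - \sum_s (\kappa_{is}/k_i)^2} (0 for a node whose
#' positive connections all stay within its own module; at most 1 - 1/M) and
#' within-module degree z-score \eqn{z_i = (\kappa_{is} - \bar\kappa_{s}) /
#' \sigma_{\kappa_s}} standardised over the node's own module members.
#' Nodes with zero positive strength get P = 0; modules with zero strength
#' SD (including singletons) get z = 0.
#'
#' @param fc an [FCMatrix-class] or symmetric matrix.
#' @param partition a [ModulePartition-class] covering all nodes.
#' @return list with `participation`, `withinModuleZ`, `moduleStrengths`
#'   (N x M kappa matrix), `totalPositiveStrength`, `moduleMeanStrength`,
#'   `moduleSdStrength`.
#' @export
nodeCartography <- function(fc, partition) {
  W <- if (is(fc, "FCMatrix")) fc@weights else as.matrix(fc)
  diag(W) <- 0
  a <- partition@assignment
  M <- partition@nModules
  if (length(a) != nrow(W)) stop("partition does not cover all nodes")
  Wp <- pmax(W, 0)
  memb <- outer(a, seq_len(M), "==") * 1  # N x M indicator
  kappa <- Wp %*% memb                    # positive strength into each module
  k <- rowSums(Wp)
  P <- 1 - rowSums((kappa / ifelse(k > 0, k, 1))^2)
  P[k == 0] <- 0
  own <- kappa[cbind(seq_along(a), a)]
  mu <- tapply(own, a, mean)
  sg <- tapply(own, a, sd)                # sample SD over module members
  sg[is.na(sg)] <- 0
  z <- ifelse(sg[a] > 0, (own - mu[a]) / sg[a], 0)
  list(participation = as.numeric(P), withinModuleZ = as.numeric(z),
       moduleStrengths = kappa, totalPositiveStrength = k,
       moduleMeanStrength = as.numeric(mu), moduleSdStrength = as.numeric(sg))
}

#' Characteristic path length of a thresholded graph
#'
#' Edge lengths are reciprocal weights (1 for binarised graphs); shortest
#' path distances d_ij come from Dijkstra's algorithm, and
#' \eqn{L = \frac{1}{n}\sum_i \sum_{j \ne i} d_{ij}/(n-1)}. Unreachable pairs
#' are excluded from the average and counted.
#'
#' @param g a [BrainGraph-class].
#' @return list with `charPathLength`, `distanceMatrix`, `nNodes`,
#'   `nUnreachablePairs`.
#' @export
weightedPathLength <- function(g) {
  stopifnot(is(g, "BrainGraph"))
  w <- g@weights
  if (all(w == 0)) stop("graph has no edges")
  len <- w
  len[w > 0] <- if (g@binarized) 1 else 1 / w[w > 0]
  ig <- igraph::graph_from_adjacency_matrix(len, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  d <- igraph::distances(ig, algorithm = "dijkstra")
  off <- d[row(d) != col(d)]
  unreachable <- sum(!is.finite(off))
  list(charPathLength = mean(off[is.finite(off)]), distanceMatrix = d,
       nNodes = nrow(w), nUnreachablePairs = unreachable)
}

#' Weighted clustering coefficient (geometric-mean triangles)
#'
#' Weights are scaled by the graph maximum; the triangle intensity of node i
#' is \eqn{t_i = \frac12 \sum_{j,h} (\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}}
#' and \eqn{C_i = 2 t_i / (k_i (k_i - 1))} with binary degree k_i; nodes with
#' fewer than two neighbours get C_i = 0.
#'
#' @param g a [BrainGraph-class].
#' @return list with `clustering`, `triangleIntensity`, `degree`.
#' @export
weightedClustering <- function(g) {
  stopifnot(is(g, "BrainGraph"))
  w <- g@weights
  mx <- max(w)
  if (mx == 0) stop("graph has no edges")
  W3 <- (w / mx)^(1 / 3)
  t3 <- diag(W3 %*% W3 %*% W3) / 2
  k <- rowSums(w > 0)
  C <- ifelse(k >= 2, 2 * t3 / (k * (k - 1)), 0)
  list(clustering = as.numeric(C), triangleIntensity = as.numeric(t3),
       degree = as.integer(k))
}

#' Degree-preserving rewired null graph
#'
#' Applies `swapsPerEdge * nEdges` attempted double-edge swaps; weights
#' travel with the rewired edges, so the binary degree sequence and the edge
#' weight multiset are preserved exactly while topology is randomised.
#'
#' @param g a [BrainGraph-class].
#' @param swapsPerEdge attempted swaps per edge (default 100).
#' @param seed optional RNG seed.
#' @return a rewired [BrainGraph-class].
#' @export
rewireNull <- function(g, swapsPerEdge = 100L, seed = NULL) {
  stopifnot(is(g, "BrainGraph"))
  if (!is.null(seed)) set.seed(seed)
  w <- g@weights
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  m <- nrow(idx)
  if (m < 2L) stop("graph too small to rewire (needs >= 2 edges)")
  res <- .rewireEdges(idx[, 1], idx[, 2], w[idx], nrow(w),
                      as.integer(swapsPerEdge) * m)
  out <- matrix(0, nrow(w), ncol(w), dimnames = dimnames(w))
  out[cbind(res$i, res$j)] <- res$w
  out[cbind(res$j, res$i)] <- res$w
  new("BrainGraph", weights = out, density = g@density, binarized = g@binarized)
}

#' Small-worldness across proportional densities
#'
#' For each density: threshold the FC matrix, compute the mean clustering
#' coefficient C and characteristic path length L, normalise each by the
#' mean over `nNulls` degree-preserving rewired null graphs, and form
#' \eqn{S = (C/C_{rand}) / (L/L_{rand})}. The returned S is the mean across
#' densities (random-like graphs give S near 1; lattice-like graphs well
#' above 1).
#'
#' @param fc an [FCMatrix-class].
#' @param densities density grid (default `c(0.10, 0.15, 0.20, 0.25)`).
#' @param nNulls rewired nulls per density (default 100).
#' @param binarize use binarised graphs?
#' @param seed optional RNG seed.
#' @param swapsPerEdge swaps per edge for each null (default 100).
#' @return list of class `SmallWorldResult`: `sValue`, `cGraph`, `cRandom`,
#'   `lGraph`, `lRandom` (means across densities), `perDensity` data frame,
#'   `nNulls`.
#' @export
smallWorldness <- function(fc, densities = c(0.10, 0.15, 0.20, 0.25),
                           nNulls = 100L, binarize = FALSE, seed = NULL,
                           swapsPerEdge = 100L) {
  stopifnot(is(fc, "FCMatrix"))
  if (any(densities <= 0 | densities > 1)) stop("densities must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(densities, function(dens) {
    g <- proportionalThreshold(fc, dens, binarize = binarize)
    Cg <- mean(weightedClustering(g)$clustering)
    pl <- weightedPathLength(g)
    if (pl$nUnreachablePairs > 0)
      warning(sprintf("density %.2f: %d unreachable pairs excluded from L",
                      dens, pl$nUnreachablePairs))
    Lg <- pl$charPathLength
    Cr <- numeric(nNulls); Lr <- numeric(nNulls)
    for (b in seq_len(nNulls)) {
      gr <- rewireNull(g, swapsPerEdge = swapsPerEdge)
      Cr[b] <- mean(weightedClustering(gr)$clustering)
      Lr[b] <- weightedPathLength(gr)$charPathLength
    }
    data.frame(density = dens, cGraph = Cg, cRandom = mean(Cr), lGraph = Lg,
               lRandom = mean(Lr),
               sValue = (Cg / mean(Cr)) / (Lg / mean(Lr)))
  })
  per <- do.call(rbind, rows)
  structure(list(sValue = mean(per$sValue), cGraph = mean(per$cGraph),
                 cRandom = mean(per$cRandom), lGraph = mean(per$lGraph),
                 lRandom = mean(per$lRandom), nNulls = as.integer(nNulls),
                 perDensity = per),
            class = "SmallWorldResult")
}

#' @export
print.SmallWorldResult <- function(x, ...) {
  cat(sprintf("Small-worldness S = %.3f (mean over %d densities, %d nulls)\n",
              x$sValue, nrow(x$perDensity), x$nNulls))
  invisible(x)
}
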