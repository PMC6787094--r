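.pooledT <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  if (sp2 == 0) return(if (mean(x) == mean(y)) 0 else Inf * sign(mean(x) - mean(y)))
  (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

.pairedT <- function(d) {
  n <- length(d)
  sdd <- sd(d)
  if (sdd == 0) return(if (mean(d) == 0) 0 else Inf * sign(mean(d)))
  mean(d) / (sdd / sqrt(n))
}

# all 2^n sign patterns as a matrix of +-1 (n <= ~16)
.allSigns <- function(n) {
  m <- 2L^n
  S <- matrix(1, m, n)
  for (j in seq_len(n))
    S[, j] <- rep(c(1, -1), each = 2L^(n - j), length.out = m)
  S
}

# paired t statistics for sign matrices, vectorised: sum of squares is
# invariant under sign flips
.pairedTMany <- function(S, d) {
  n <- length(d)
  M <- as.numeric(S %*% d) / n
  ss <- sum(d^2)
  v <- (ss - n * M^2) / (n - 1)
  v[v < 0] <- 0
  ifelse(v == 0, ifelse(M == 0, 0, Inf * sign(M)), M / sqrt(v / n))
}

#' Permutation t-test (paired or two-sample)
#'
#' Two-sided permutation test. Paired samples use sign-flipping of the
#' within-pair differences and the one-sample t statistic on differences;
#' unpaired samples use group-label shuffling and the classic pooled-variance
#' two-sample t. When the number of distinct permutations (2^n paired,
#' choose(n1+n2, n1) unpaired) does not exceed `nPerm`, the null is
#' enumerated exhaustively and the p-value is exact (the identity permutation
#' is part of the enumeration); otherwise `nPerm` random permutations are
#' drawn and p = (1 + b) / (nPerm + 1), which cannot be zero.
#'
#' @param x,y numeric samples (equal length if paired).
#' @param paired logical.
#' @param nPerm permutation budget (default 10000).
#' @param seed optional RNG seed.
#' @return list of class `StatResult`: `tObserved`, `pValue`, `effectG`
#'   (Hedges' g), `nPermutations` (used), `exhaustive`, `paired`, `seed`.
#' @examples
#' set.seed(1)
#' permutationTTest(rnorm(12, 1), rnorm(12), paired = TRUE, nPerm = 999)
#' @export
permutationTTest <- function(x, y, paired = FALSE, nPerm = 10000L, seed = NULL) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (paired && length(x) != length(y)) stop("paired samples must have equal length")
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 observations")
  if (!is.null(seed)) set.seed(seed)
  if (paired) {
    d <- x - y
    if (all(d == 0)) {
      return(structure(list(tObserved = 0, pValue = 1, effectG = 0,
                            nPermutations = 0L, exhaustive = TRUE,
                            paired = TRUE,
                            seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
                       class = "StatResult"))
    }
    tObs <- .pairedT(d)
    n <- length(d)
    exhaustive <- n <= 25 && 2^n <= nPerm
    if (exhaustive) {
      tStar <- .pairedTMany(.allSigns(n), d)
      p <- mean(abs(tStar) >= abs(tObs) - 1e-12)
      nUsed <- 2L^n
    } else {
      S <- matrix(sample(c(-1, 1), nPerm * n, replace = TRUE), nPerm, n)
      tStar <- .pairedTMany(S, d)
      p <- (1 + sum(abs(tStar) >= abs(tObs) - 1e-12)) / (nPerm + 1)
      nUsed <- as.integer(nPerm)
    }
    g <- hedgesG(x, y, paired = TRUE)
  } else {
    tObs <- .pooledT(x, y)
    z <- c(x, y)
    n1 <- length(x); n <- length(z)
    nDistinct <- choose(n, n1)
    exhaustive <- is.finite(nDistinct) && nDistinct <= nPerm
    if (exhaustive) {
      combos <- combn(n, n1)
      tStar <- apply(combos, 2, function(idx) .pooledT(z[idx], z[-idx]))
      p <- mean(abs(tStar) >= abs(tObs) - 1e-12)
      nUsed <- as.integer(nDistinct)
    } else {
      tStar <- vapply(seq_len(nPerm), function(b) {
        idx <- sample.int(n, n1)
        .pooledT(z[idx], z[-idx])
      }, numeric(1))
      p <- (1 + sum(abs(tStar) >= abs(tObs) - 1e-12)) / (nPerm + 1)
      nUsed <- as.integer(nPerm)
    }
    g <- hedgesG(x, y, paired = FALSE)
  }
  structure(list(tObserved = tObs, pValue = p, effectG = g,
                 nPermutations = nUsed, exhaustive = exhaustive,
                 paired = paired,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "StatResult")
}

#' @export
print.StatResult <- function(x, ...) {
  cat(sprintf("%s permutation t-test: t = %.3f, p = %.4g, Hedges' g = %.3f (%s%d permutations)\n",
              if (x$paired) "Paired" else "Two-sample", x$tObserved, x$pValue,
              x$effectG, if (x$exhaustive) "exhaustive " else "", x$nPermutations))
  invisible(x)
}

#' Hedges' g effect size
#'
#' Standardised mean difference with the small-sample bias correction
#' J = 1 - 3/(4 df - 1). The two-sample version standardises by the pooled
#' SD (df = n1 + n2 - 2); the paired version by the SD of the within-pair
#' differences (df = n - 1).
#'
#' @param x,y numeric samples.
#' @param paired logical.
#' @return scalar g (antisymmetric: g(x, y) = -g(y, x)).
#' @export
hedgesG <- function(x, y, paired = FALSE) {
  if (paired) {
    d <- x - y
    sdd <- sd(d)
    if (sdd == 0) {
      if (mean(d) == 0) return(0)
      stop("zero SD of differences with nonzero mean: g undefined")
    }
    df <- length(d) - 1
    return((1 - 3 / (4 * df - 1)) * mean(d) / sdd)
  }
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df)
  if (sp == 0) {
    if (mean(x) == mean(y)) return(0)
    stop("zero pooled SD with different means: g undefined")
  }
  (1 - 3 / (4 * df - 1)) * (mean(x) - mean(y)) / sp
}

#' Benjamini-Hochberg FDR control
#'
#' Standard step-up procedure; q-values are monotone and a hypothesis is
#' rejected when its q-value is at most `alpha`.
#'
#' @param pValues numeric vector of p-values in (0, 1].
#' @param alpha FDR level (default 0.05).
#' @return list with `qValues` and logical `reject`.
#' @export
bhFdr <- function(pValues, alpha = 0.05) {
  if (length(pValues) == 0L) stop("empty p-value vector")
  if (any(pValues <= 0 | pValues > 1)) stop("p-values must lie in (0, 1]")
  q <- p.adjust(pValues, method = "BH")
  list(qValues = q, reject = q <= alpha)
}

# stack of FCMatrix objects (or matrices) -> subjects x edges matrix
.edgeStack <- function(stack) {
  mats <- lapply(stack, function(m) if (is(m, "FCMatrix")) m@weights else as.matrix(m))
  N <- nrow(mats[[1]])
  ut <- upper.tri(mats[[1]])
  do.call(rbind, lapply(mats, function(m) {
    if (!identical(dim(m), c(N, N))) stop("FC matrices differ in dimension")
    m[ut]
  }))
}

# vectorised edgewise permutation p-values (paired: sign flips; unpaired:
# label shuffles shared across edges); permutations processed in chunks to
# bound memory at ~chunk x nEdges doubles
.edgewisePerm <- function(A, B, paired, nPerm, chunk = 512L) {
  E <- ncol(A)
  if (paired) {
    D <- A - B                                  # subjects x edges
    n <- nrow(D)
    tObs <- apply(D, 2, .pairedT)
    thr <- abs(tObs) - 1e-12
    ss <- colSums(D^2)
    exhaustive <- n <= 25 && 2^n <= nPerm
    total <- if (exhaustive) 2L^n else as.integer(nPerm)
    cnt <- numeric(E)
    done <- 0L
    while (done < total) {
      nb <- min(chunk, total - done)
      S <- if (exhaustive) {
        ints <- done + seq_len(nb) - 1L
        vapply(seq_len(n), function(j)
          ifelse(bitwAnd(ints, bitwShiftL(1L, j - 1L)) > 0L, -1, 1),
          numeric(nb))
      } else {
        matrix(sample(c(-1, 1), nb * n, replace = TRUE), nb, n)
      }
      if (nb == 1L) S <- matrix(S, 1L, n)
      M <- S %*% D / n
      v <- sweep(-n * M^2, 2, ss, "+") / (n - 1)
      v[v < 0] <- 0
      tStar <- abs(M) / sqrt(v / n)
      tStar[v == 0 & M == 0] <- 0
      cnt <- cnt + colSums(sweep(tStar, 2, thr, ">="))
      done <- done + nb
    }
    p <- if (exhaustive) cnt / total else (1 + cnt) / (total + 1)
  } else {
    Z <- rbind(A, B)
    n1 <- nrow(A); n2 <- nrow(B); n <- n1 + n2
    tObs <- vapply(seq_len(E), function(e) .pooledT(A[, e], B[, e]), numeric(1))
    thr <- abs(tObs) - 1e-12
    totS <- colSums(Z); totSS <- colSums(Z^2)
    nDistinct <- choose(n, n1)
    exhaustive <- is.finite(nDistinct) && nDistinct <= nPerm
    combos <- if (exhaustive) combn(n, n1) else NULL
    total <- if (exhaustive) as.integer(nDistinct) else as.integer(nPerm)
    cnt <- numeric(E)
    done <- 0L
    while (done < total) {
      nb <- min(chunk, total - done)
      I <- matrix(0, nb, n)
      for (b in seq_len(nb)) {
        idx <- if (exhaustive) combos[, done + b] else sample.int(n, n1)
        I[b, idx] <- 1
      }
      SA <- I %*% Z; SSA <- I %*% Z^2
      m1 <- SA / n1
      m2 <- sweep(-SA, 2, totS, "+") / n2
      sp2 <- (SSA - n1 * m1^2 +
                sweep(-SSA, 2, totSS, "+") - n2 * m2^2) / (n - 2)
      sp2[sp2 < 0] <- 0
      denom <- sqrt(sp2 * (1 / n1 + 1 / n2))
      tStar <- abs(m1 - m2) / denom
      tStar[denom == 0 & m1 == m2] <- 0
      cnt <- cnt + colSums(sweep(tStar, 2, thr, ">="))
      done <- done + nb
    }
    p <- if (exhaustive) cnt / total else (1 + cnt) / (total + 1)
  }
  list(tObs = tObs, p = p)
}

#' Edgewise group contrast with FDR thresholding
#'
#' Computes the per-edge mean difference (A - B) between two stacks of FC
#' matrices, tests every unique edge with a permutation t-test (paired
#' sign-flipping or unpaired label shuffling, permutations shared across
#' edges), applies Benjamini-Hochberg FDR over the N(N-1)/2 edges, and zeroes
#' all non-surviving edges.
#'
#' @param stackA,stackB lists of [FCMatrix-class] (or plain matrices), one
#'   per subject, matching dimension.
#' @param paired logical; paired requires equal stack lengths.
#' @param alpha FDR level (default 0.05).
#' @param nPerm permutation budget per edge (default 10000).
#' @param seed optional RNG seed.
#' @return an [FCMatrix-class] with provenance "mean_difference"; attribute
#'   `"nSignificant"` carries the surviving-edge count and `"qValues"` the
#'   per-edge q-values (upper-triangle order).
#' @export
edgewiseContrast <- function(stackA, stackB, paired = FALSE, alpha = 0.05,
                             nPerm = 10000L, seed = NULL) {
  if (length(stackA) == 0L || length(stackB) == 0L) stop("empty stack")
  if (paired && length(stackA) != length(stackB))
    stop("paired stacks must have equal length")
  if (!is.null(seed)) set.seed(seed)
  A <- .edgeStack(stackA)
  B <- .edgeStack(stackB)
  if (ncol(A) != ncol(B)) stop("FC stacks differ in dimension")
  meanDiff <- colMeans(A) - colMeans(B)
  res <- .edgewisePerm(A, B, paired, nPerm)
  fdr <- bhFdr(res$p, alpha = alpha)
  keep <- fdr$reject
  proto <- if (is(stackA[[1]], "FCMatrix")) stackA[[1]]@weights else as.matrix(stackA[[1]])
  N <- nrow(proto)
  out <- matrix(0, N, N, dimnames = dimnames(proto))
  out[upper.tri(out)] <- ifelse(keep, meanDiff, 0)
  out <- out + t(out)
  fc <- FCMatrix(out, provenance = "mean_difference")
  attr(fc, "nSignificant") <- sum(keep)
  attr(fc, "qValues") <- fdr$qValues
  fc
}

#' Combine two thresholded contrasts into common differences
#'
#' Elementwise rule for building the matrix of connectivity differences
#' common to two datasets: where both inputs are positive the output is the
#' minimum of the two; where both are negative it is the maximum (the
#' smaller absolute value); everywhere else it is 0. A nonzero output edge
#' therefore marks a change consistent in sign across datasets, with weight
#' equal to the minimum extent of the alteration.
#'
#' @param matA,matB thresholded mean-difference [FCMatrix-class] objects of
#'   equal dimension.
#' @return an [FCMatrix-class] with provenance "common_difference".
#' @export
combineCommonDifferences <- function(matA, matB) {
  A <- if (is(matA, "FCMatrix")) matA@weights else as.matrix(matA)
  B <- if (is(matB, "FCMatrix")) matB@weights else as.matrix(matB)
  if (!identical(dim(A), dim(B))) stop("matrices differ in dimension")
  out <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  bothPos <- A > 0 & B > 0
  bothNeg <- A < 0 & B < 0
  out[bothPos] <- pmin(A[bothPos], B[bothPos])
  out[bothNeg] <- pmax(A[bothNeg], B[bothNeg])
  FCMatrix(out, provenance = "common_difference")
}
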