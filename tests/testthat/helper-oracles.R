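# Independent reference implementations used as oracles. Deliberately naive
# (double loops, exhaustive enumeration) and kept free of any package code
# beyond base R.

# O(T^2) sample entropy: unordered pairs of the first T - m templates at both
# lengths, Chebyshev distance, closed inequality, population-SD tolerance.
sampenOracle <- function(x, m = 3, rFactor = 0.6) {
  T <- length(x)
  r <- rFactor * sqrt(mean((x - mean(x))^2))
  n <- T - m
  A <- 0L; B <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(dm, abs(x[i + m] - x[j + m])) <= r) A <- A + 1L
      }
    }
  }
  list(A = A, B = B, value = if (A > 0 && B > 0) -log(A / B) else NA_real_)
}

# dense Floyd-Warshall all-pairs shortest paths on a length matrix
# (0 / missing edge = Inf)
floydWarshallOracle <- function(len) {
  n <- nrow(len)
  d <- ifelse(len > 0, len, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# all set partitions of n elements as integer assignment vectors (1-based,
# first-occurrence labelling); Bell(8) = 4140
allPartitions <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in allPartitions(n - 1)) {
    m <- max(p)
    for (g in seq_len(m + 1)) out[[length(out) + 1L]] <- c(p, g)
  }
  out
}

# direct evaluation of the asymmetric signed modularity used as a
# cross-check formula (written independently of the package's own function)
qOracle <- function(W, a, gamma = 1) {
  diag(W) <- 0
  Wp <- pmax(W, 0); Wn <- -pmin(W, 0)
  sp <- rowSums(Wp); sn <- rowSums(Wn)
  vp <- sum(sp); vn <- sum(sn)
  qp <- 0; qn <- 0
  n <- nrow(W)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (a[i] != a[j]) next
    qp <- qp + (if (i != j) Wp[i, j] else 0) - gamma * sp[i] * sp[j] / max(vp, 1e-300)
    qn <- qn + (if (i != j) Wn[i, j] else 0) - gamma * sn[i] * sn[j] / max(vn, 1e-300)
  }
  (if (vp > 0) qp / vp else 0) - (if (vn > 0) qn / (vp + vn) else 0)
}

# random correlation-like symmetric matrix with unit diagonal
randomFC <- function(N, Tn = 4 * N, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cor(matrix(rnorm(Tn * N), Tn, N))
}

# small modular FC matrix: two positive cliques, weak negative links between
twoCliqueFC <- function(sizes = c(3, 3), within = 1, between = -0.2) {
  n <- sum(sizes)
  a <- rep(seq_along(sizes), sizes)
  W <- ifelse(outer(a, a, "=="), within, between)
  diag(W) <- 0
  W
}

# quick synthetic subject at reduced size (fast helper for unit tests)
smallSubject <- function(T = 120, N = 20, nModules = 4, seed = 7,
                         switchProb = 0.03) {
  spec <- cohortSpec(nRegions = N, nModules = nModules, switchProb = switchProb)
  reg <- simulateStateSequence(T, switchProb, seed = seed)
  list(ts = simulateSubjectTimeseries(spec, reg, seed + 1), regimes = reg,
       spec = spec)
}
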