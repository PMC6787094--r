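#' Synthetic cohort specification
#'
#' Parameters of the synthetic BOLD-like cohorts used as planted ground
#' truth: two cohorts (a paired conscious/unconscious cohort of 16 subjects,
#' and an unpaired patient cohort of 22 subjects compared against the 16
#' conscious controls) of modular, temporally autocorrelated regional
#' timeseries that switch between a high between-module-coupling (integrated)
#' regime and a high within-module-coupling (segregated) regime. Group
#' effects are planted on entropy (higher temporal autocorrelation in the
#' unconscious cohort lowers sample entropy), integration (reduced
#' between-module coupling in the integrated regime) and, through those, on
#' edge weights.
#'
#' @param nSubjectsA paired-cohort size (default 16).
#' @param nSubjectsB patient-cohort size (default 22).
#' @param nRegions regions (default 90, split evenly into modules).
#' @param nTimepoints named vector of timepoints per cohort
#'   (default c(A = 251, B = 295)).
#' @param trSeconds repetition time (default 2).
#' @param nModules number of planted modules (default 5).
#' @param withinR within-module correlation (default 0.5).
#' @param betweenRIntegrated between-module correlation in the integrated
#'   regime (default 0.35).
#' @param betweenRSegregated between-module correlation in the segregated
#'   regime (default 0.05).
#' @param arCoefficient named AR(1) coefficients
#'   (default c(conscious = 0.2, unconscious = 0.5)).
#' @param switchProb per-TR regime switching probability (default 0.02).
#' @param effectIntegration reduction of `betweenRIntegrated` in the
#'   unconscious conditions (default 0.15).
#' @param seed master seed (default 1).
#' @return list of class `CohortSpec`.
#' @export
cohortSpec <- function(nSubjectsA = 16L, nSubjectsB = 22L, nRegions = 90L,
                       nTimepoints = c(A = 251L, B = 295L), trSeconds = 2,
                       nModules = 5L, withinR = 0.5,
                       betweenRIntegrated = 0.35, betweenRSegregated = 0.05,
                       arCoefficient = c(conscious = 0.2, unconscious = 0.5),
                       switchProb = 0.02, effectIntegration = 0.15, seed = 1L) {
  spec <- list(nSubjectsA = as.integer(nSubjectsA),
               nSubjectsB = as.integer(nSubjectsB),
               nRegions = as.integer(nRegions),
               nTimepoints = nTimepoints, trSeconds = trSeconds,
               nModules = as.integer(nModules), withinR = withinR,
               betweenRIntegrated = betweenRIntegrated,
               betweenRSegregated = betweenRSegregated,
               arCoefficient = arCoefficient, switchProb = switchProb,
               effectIntegration = effectIntegration, seed = as.integer(seed))
  if (spec$switchProb <= 0 || spec$switchProb >= 1)
    stop("switchProb must lie in (0, 1)")
  class(spec) <- "CohortSpec"
  spec
}

# module labels 1..M over regions, as equal blocks
.moduleAssignment <- function(nRegions, nModules) {
  rep(seq_len(nModules), length.out = nRegions, each = ceiling(nRegions / nModules))[
    seq_len(nRegions)]
}

# block-structured correlation matrix: withinR inside modules, betweenR across
.blockCorr <- function(modules, withinR, betweenR) {
  same <- outer(modules, modules, "==")
  S <- ifelse(same, withinR, betweenR)
  diag(S) <- 1
  S
}

.cholOrFail <- function(S, label) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(ch))
    stop("non-positive-definite block covariance for regime '", label,
         "' (check withinR/betweenR parameters)")
  ch
}

#' Simulate a two-state regime sequence
#'
#' Symmetric two-state Markov chain over TRs with uniform start: each TR the
#' regime switches with probability `switchProb`.
#'
#' @param T number of timepoints.
#' @param switchProb per-TR switching probability in (0, 1).
#' @param seed optional RNG seed.
#' @return character vector of "integrated"/"segregated" labels, length T.
#' @export
simulateStateSequence <- function(T, switchProb, seed = NULL) {
  if (switchProb <= 0 || switchProb >= 1) stop("switchProb must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  states <- c("integrated", "segregated")
  s <- integer(T)
  s[1] <- sample(1:2, 1)
  if (T > 1) {
    flips <- runif(T - 1) < switchProb
    for (t in 2:T) s[t] <- if (flips[t - 1]) 3L - s[t - 1] else s[t - 1]
  }
  states[s]
}

#' Simulate one subject's regional timeseries
#'
#' Per TR, a region vector is drawn from the active regime's block-structured
#' Gaussian (within-module correlation `withinR`; between-module correlation
#' `betweenRIntegrated` or `betweenRSegregated`), then temporally mixed with
#' an AR(1) filter (`x_t = phi x_{t-1} + sqrt(1 - phi^2) e_t`) and
#' standardised per region.
#'
#' @param spec a `CohortSpec` (its `arCoefficient["conscious"]` is used
#'   unless overridden).
#' @param regimeSeq regime label sequence from [simulateStateSequence()].
#' @param subjectSeed RNG seed for this subject.
#' @param arCoefficient AR(1) coefficient override.
#' @param betweenRIntegrated override (e.g. reduced for unconscious
#'   conditions).
#' @param subjectId,condition labels for the returned object.
#' @return a [RoiTimeseries-class].
#' @export
simulateSubjectTimeseries <- function(spec, regimeSeq, subjectSeed,
                                      arCoefficient = spec$arCoefficient[["conscious"]],
                                      betweenRIntegrated = spec$betweenRIntegrated,
                                      subjectId = "sim", condition = "unspecified") {
  set.seed(subjectSeed)
  Tn <- length(regimeSeq)
  N <- spec$nRegions
  modules <- .moduleAssignment(N, spec$nModules)
  chInt <- .cholOrFail(.blockCorr(modules, spec$withinR, betweenRIntegrated),
                       "integrated")
  chSeg <- .cholOrFail(.blockCorr(modules, spec$withinR, spec$betweenRSegregated),
                       "segregated")
  Z <- matrix(rnorm(Tn * N), Tn, N)
  E <- matrix(0, Tn, N)
  isInt <- regimeSeq == "integrated"
  if (any(isInt)) E[isInt, ] <- Z[isInt, , drop = FALSE] %*% chInt
  if (any(!isInt)) E[!isInt, ] <- Z[!isInt, , drop = FALSE] %*% chSeg
  phi <- arCoefficient
  X <- E
  if (phi != 0) {
    scale <- sqrt(1 - phi^2)
    X[1, ] <- E[1, ]
    for (t in 2:Tn) X[t, ] <- phi * X[t - 1, ] + scale * E[t, ]
  }
  X <- scale(X)
  colnames(X) <- sprintf("R%03d", seq_len(N))
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  RoiTimeseries(X, spec$trSeconds, subjectId = subjectId, condition = condition)
}

#' Simulate both cohorts with planted group effects
#'
#' Cohort A: paired conscious ("awake") and unconscious ("deep") runs for
#' `nSubjectsA` subjects; cohort B: `nSubjectsB` unconscious "patient" runs.
#' Unconscious conditions use `betweenRIntegrated - effectIntegration` and
#' the higher `arCoefficient["unconscious"]`. All randomness derives from
#' `spec$seed`.
#'
#' @param spec a `CohortSpec`.
#' @param nullEffects if TRUE, all conditions use the conscious parameters
#'   (no planted effect) — a null cohort for calibration.
#' @return list with `cohortA` (lists `awake`, `deep` of
#'   [RoiTimeseries-class]), `cohortB` (list of [RoiTimeseries-class]), and
#'   `groundTruth` (regime label sequences per run, module assignment,
#'   planted effect descriptions).
#' @export
simulateCohorts <- function(spec, nullEffects = FALSE) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  nA <- spec$nSubjectsA; nB <- spec$nSubjectsB
  seeds <- sample.int(.Machine$integer.max - 1L, 2L * nA + nB)
  tA <- spec$nTimepoints[["A"]]; tB <- spec$nTimepoints[["B"]]
  arC <- spec$arCoefficient[["conscious"]]
  arU <- if (nullEffects) arC else spec$arCoefficient[["unconscious"]]
  betC <- spec$betweenRIntegrated
  betU <- if (nullEffects) betC else betC - spec$effectIntegration
  regimes <- list(awake = vector("list", nA), deep = vector("list", nA),
                  patient = vector("list", nB))
  awake <- deep <- vector("list", nA)
  patients <- vector("list", nB)
  for (i in seq_len(nA)) {
    regimes$awake[[i]] <- simulateStateSequence(tA, spec$switchProb)
    awake[[i]] <- simulateSubjectTimeseries(
      spec, regimes$awake[[i]], seeds[i], arCoefficient = arC,
      betweenRIntegrated = betC, subjectId = sprintf("A%02d", i),
      condition = "awake")
    regimes$deep[[i]] <- simulateStateSequence(tA, spec$switchProb)
    deep[[i]] <- simulateSubjectTimeseries(
      spec, regimes$deep[[i]], seeds[nA + i], arCoefficient = arU,
      betweenRIntegrated = betU, subjectId = sprintf("A%02d", i),
      condition = "deep")
  }
  for (i in seq_len(nB)) {
    regimes$patient[[i]] <- simulateStateSequence(tB, spec$switchProb)
    patients[[i]] <- simulateSubjectTimeseries(
      spec, regimes$patient[[i]], seeds[2L * nA + i], arCoefficient = arU,
      betweenRIntegrated = betU, subjectId = sprintf("B%02d", i),
      condition = "patient")
  }
  modules <- .moduleAssignment(spec$nRegions, spec$nModules)
  planted <- if (nullEffects) list() else list(
    betweenModuleIntegratedFC = list(direction = "decrease",
                                     magnitude = spec$effectIntegration),
    sampleEntropy = list(direction = "decrease",
                         magnitude = arU - arC),
    integration = list(direction = "decrease",
                       magnitude = spec$effectIntegration))
  list(cohortA = list(awake = awake, deep = deep), cohortB = patients,
       groundTruth = list(regimeLabels = regimes, moduleAssignment = modules,
                          plantedEffects = planted, nullEffects = nullEffects))
}

#' Simulate a voxel phantom with a connected hub
#'
#' Background voxels are i.i.d. Gaussian noise plus a weak shared signal;
#' voxels in the hub mask receive an additional strong shared component
#' scaled by `hubCoupling`. Exercises ICC/SampEn mapping and overlap logic
#' with known spatial ground truth.
#'
#' @param gridDim length-3 grid dimensions.
#' @param hubMask logical 3D array marking hub voxels.
#' @param T number of timepoints.
#' @param hubCoupling hub shared-signal strength (0 = null phantom).
#' @param seed optional RNG seed.
#' @param voxelSizeMm,trSeconds geometry metadata.
#' @return a [VolumeSeries-class] (full-grid mask).
#' @export
simulateVoxelPhantom <- function(gridDim, hubMask, T = 100L, hubCoupling = 1,
                                 seed = NULL, voxelSizeMm = c(2, 2, 2),
                                 trSeconds = 2) {
  if (!identical(dim(hubMask), as.integer(gridDim)))
    stop("hubMask dimensions must match gridDim")
  if (!any(hubMask)) stop("empty hub mask")
  if (!is.null(seed)) set.seed(seed)
  V <- prod(gridDim)
  weak <- rnorm(T)
  strong <- rnorm(T)
  mat <- matrix(rnorm(V * T), V, T)
  mat <- mat + matrix(0.3 * weak, V, T, byrow = TRUE)
  hub <- which(hubMask)
  mat[hub, ] <- mat[hub, , drop = FALSE] +
    matrix(hubCoupling * strong, length(hub), T, byrow = TRUE)
  VolumeSeries(array(mat, c(gridDim, T)), voxelSizeMm = voxelSizeMm,
               trSeconds = trSeconds)
}
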