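#' Pipeline configuration
#'
#' Assembles and validates the configuration for [runPipeline()]. Every
#' analysis parameter has the field-standard default; compute-heavy stages
#' (dynamic states, graph metrics, entropy) can be toggled so that targeted
#' analyses stay affordable.
#'
#' @param spec a `CohortSpec` from [cohortSpec()] describing the synthetic
#'   cohorts, or NULL when `data` supplies pre-built cohorts.
#' @param data optional pre-built cohort list shaped like the output of
#'   [simulateCohorts()] (fields `cohortA$awake`, `cohortA$deep`, `cohortB`).
#' @param denoise apply [denoiseTimeseries()] to every run first?
#' @param bandHz band-pass edges in Hz when denoising.
#' @param taperRect,taperSigma sliding-window taper parameters.
#' @param gamma Louvain resolution.
#' @param louvainRepeats Louvain restarts per window.
#' @param kmeansRestarts k-means restarts per subject.
#' @param densities proportional-threshold grid for graph metrics.
#' @param nNulls rewired nulls per density.
#' @param swapsPerEdge rewiring swaps per edge.
#' @param entropyBins connectivity-entropy bins.
#' @param nPerm permutations for group tests and edgewise contrasts.
#' @param alpha FDR level.
#' @param doStates,doGraph,doEntropy stage toggles.
#' @param networkLabels optional per-region resting-state-network labels.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(spec = cohortSpec(), data = NULL, denoise = FALSE,
                           bandHz = c(0.008, 0.09), taperRect = 22L,
                           taperSigma = 3, gamma = 1, louvainRepeats = 100L,
                           kmeansRestarts = 500L,
                           densities = c(0.10, 0.15, 0.20, 0.25),
                           nNulls = 100L, swapsPerEdge = 100L,
                           entropyBins = 10L, nPerm = 10000L, alpha = 0.05,
                           doStates = TRUE, doGraph = TRUE, doEntropy = TRUE,
                           networkLabels = NULL, seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

# deterministic child seeds below 2^31
.childSeed <- function(seed, k) (as.integer(seed) * 1009L + k * 101L) %% 2000000011L

.analyseRun <- function(ts, cfg, runSeed) {
  if (cfg$denoise) ts <- denoiseTimeseries(ts, bandHz = cfg$bandHz)
  out <- list(subjectId = ts@subjectId, condition = ts@condition)
  out$staticFC <- staticFC(ts)
  mats <- list(static = out$staticFC)
  if (cfg$doStates) {
    dfc <- dynamicFC(ts, buildTaper(cfg$taperRect, cfg$taperSigma))
    st <- deriveStates(dfc, gamma = cfg$gamma, nRepeats = cfg$louvainRepeats,
                       nRestarts = cfg$kmeansRestarts, seed = runSeed)
    out$states <- st
    out$fractionIntegrated <- st@fractionIntegrated
    mats$integrated <- st@centroidIntegrated
    mats$segregated <- st@centroidSegregated
  }
  if (cfg$doGraph) {
    out$graph <- lapply(mats, function(m)
      smallWorldness(m, densities = cfg$densities, nNulls = cfg$nNulls,
                     swapsPerEdge = cfg$swapsPerEdge))
  }
  if (cfg$doEntropy) {
    out$entropy <- lapply(mats, function(m) {
      e <- connectivityEntropyNodes(m, nBins = cfg$entropyBins)
      if (!is.null(cfg$networkLabels))
        e$networkMeans <- summarizeByNetwork(e, cfg$networkLabels)
      e
    })
  }
  out$matrices <- mats
  out
}

.scalarTable <- function(runs, what) {
  vapply(runs, function(r) {
    v <- switch(what,
                fractionIntegrated = r$fractionIntegrated,
                swStatic = r$graph$static$sValue,
                swIntegrated = r$graph$integrated$sValue,
                swSegregated = r$graph$segregated$sValue,
                entropyStatic = r$entropy$static$globalMean,
                entropyIntegrated = r$entropy$integrated$globalMean,
                entropySegregated = r$entropy$segregated$globalMean)
    if (is.null(v)) NA_real_ else v
  }, numeric(1))
}

.groupTest <- function(runsX, runsY, what, paired, nPerm, seed) {
  x <- .scalarTable(runsX, what)
  y <- .scalarTable(runsY, what)
  if (anyNA(x) || anyNA(y)) return(NULL)
  permutationTTest(x, y, paired = paired, nPerm = nPerm, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Per subject and condition: (optional) denoising, static FC, dynamic FC,
#' cartographic state decomposition with centroids and occupancy, graph
#' metrics averaged over the density grid for the static and both state
#' matrices, and connectivity entropy. At group level: paired tests of
#' awake vs deep (cohort A), unpaired tests of the awake controls vs the
#' patients (cohort B), a patient subgroup comparison (first vs second half,
#' an aetiology-like split with no planted difference), and the
#' common-difference matrices (static, integrated, segregated) combining the
#' FDR-thresholded edgewise contrasts of the two datasets. All randomness
#' derives from `cfg$seed`; rerunning with the same config reproduces every
#' number.
#'
#' @param cfg a `PipelineConfig` from [pipelineConfig()].
#' @param outDir optional directory; if given, summary JSON and TSV matrices
#'   are written there.
#' @return list of class `PipelineReport` with elements `runs` (per-run
#'   results), `groupStats`, `commonDifferences`, `config`, `seeds`.
#' @export
runPipeline <- function(cfg, outDir = NULL) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  data <- cfg$data
  if (is.null(data)) {
    if (is.null(cfg$spec)) stop("config needs either a cohort spec or data")
    data <- simulateCohorts(cfg$spec)
  }
  nA <- length(data$cohortA$awake)
  nB <- length(data$cohortB)
  runs <- list(awake = vector("list", nA), deep = vector("list", nA),
               patient = vector("list", nB))
  k <- 0L
  for (i in seq_len(nA)) {
    runs$awake[[i]] <- .analyseRun(data$cohortA$awake[[i]], cfg,
                                   .childSeed(cfg$seed, k <- k + 1L))
    runs$deep[[i]] <- .analyseRun(data$cohortA$deep[[i]], cfg,
                                  .childSeed(cfg$seed, k <- k + 1L))
  }
  for (i in seq_len(nB))
    runs$patient[[i]] <- .analyseRun(data$cohortB[[i]], cfg,
                                     .childSeed(cfg$seed, k <- k + 1L))

  measures <- c(if (cfg$doStates) "fractionIntegrated",
                if (cfg$doGraph) c("swStatic", "swIntegrated", "swSegregated"),
                if (cfg$doEntropy) c("entropyStatic", "entropyIntegrated",
                                     "entropySegregated"))
  groupStats <- list()
  for (m in measures) {
    groupStats[[m]] <- list(
      awakeVsDeep = .groupTest(runs$awake, runs$deep, m, TRUE, cfg$nPerm,
                               .childSeed(cfg$seed, 9001L)),
      controlVsPatient = .groupTest(runs$awake, runs$patient, m, FALSE,
                                    cfg$nPerm, .childSeed(cfg$seed, 9002L)))
    if (nB >= 4L) {
      half <- seq_len(nB %/% 2L)
      groupStats[[m]]$patientSubgroups <- .groupTest(
        runs$patient[half], runs$patient[-half], m, FALSE, cfg$nPerm,
        .childSeed(cfg$seed, 9003L))
    }
  }

  matKinds <- c("static", if (cfg$doStates) c("integrated", "segregated"))
  commonDifferences <- list()
  contrasts <- list()
  for (kind in matKinds) {
    stackAw <- lapply(runs$awake, function(r) r$matrices[[kind]])
    stackDp <- lapply(runs$deep, function(r) r$matrices[[kind]])
    stackPt <- lapply(runs$patient, function(r) r$matrices[[kind]])
    cA <- edgewiseContrast(stackAw, stackDp, paired = TRUE, alpha = cfg$alpha,
                           nPerm = cfg$nPerm, seed = .childSeed(cfg$seed, 9100L))
    cB <- if (nB > 0) edgewiseContrast(stackAw, stackPt, paired = FALSE,
                                       alpha = cfg$alpha, nPerm = cfg$nPerm,
                                       seed = .childSeed(cfg$seed, 9101L)) else NULL
    contrasts[[kind]] <- list(anaesthesia = cA, doc = cB)
    if (!is.null(cB))
      commonDifferences[[kind]] <- combineCommonDifferences(cA, cB)
  }

  report <- structure(list(runs = runs, groupStats = groupStats,
                           contrasts = contrasts,
                           commonDifferences = commonDifferences,
                           config = cfg, seeds = list(master = cfg$seed)),
                      class = "PipelineReport")
  if (!is.null(outDir)) .writeReport(report, outDir)
  report
}

.writeReport <- function(report, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seed = report$seeds$master,
                  nRuns = vapply(report$runs, length, integer(1)))
  for (m in names(report$groupStats)) {
    for (cmp in names(report$groupStats[[m]])) {
      st <- report$groupStats[[m]][[cmp]]
      if (!is.null(st))
        summary[[paste(m, cmp, sep = ".")]] <-
          list(t = st$tObserved, p = st$pValue, g = st$effectG)
    }
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (kind in names(report$commonDifferences)) {
    w <- fcWeights(report$commonDifferences[[kind]])
    write.table(w, file.path(outDir, sprintf("common_difference_%s.tsv", kind)),
                sep = "\t", quote = FALSE)
  }
  invisible(outDir)
}

#' @export
print.PipelineReport <- function(x, ...) {
  cat(sprintf("PipelineReport: %d awake + %d deep + %d patient runs (seed %d)\n",
              length(x$runs$awake), length(x$runs$deep), length(x$runs$patient),
              x$seeds$master))
  for (kind in names(x$commonDifferences)) {
    w <- fcWeights(x$commonDifferences[[kind]])
    cat(sprintf("  common differences (%s): %d nonzero edges\n", kind,
                sum(w[upper.tri(w)] != 0)))
  }
  invisible(x)
}
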