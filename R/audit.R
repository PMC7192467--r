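# End-to-end audit pipeline: goodness of fit -> lack-of-fit fraction ->
# zero-inflation screen -> mock relabelling study, with file outputs.

#' Audit the NB assumption for a count dataset
#'
#' Runs the full pipeline on a count set: the matrix-wide smooth
#' goodness-of-fit test, the lack-of-fit fraction and q-values, the
#' zero-inflation LR screen, and the mock relabelling study.  When
#' \code{outPrefix} is given, per-feature TSV tables, a JSON summary
#' (including the configuration, its hash and the seed) and a plain-text
#' recommendation are written.
#'
#' The recommendation follows the lack-of-fit fraction: when more than
#' \code{recommendCutoff} of the tested features deviate from the NB, the
#' nonparametric route (rank-based tests) is recommended over NB-based
#' parametric tests.
#'
#' @param object an \linkS4class{NBCountSet}.
#' @param J,B,maxPhi,qCutoff,alpha,mockReps,seed pipeline parameters, see
#'   \code{\link{gofTest}}, \code{\link{estimatePi0}},
#'   \code{\link{runMockStudy}}.
#' @param recommendCutoff lack-of-fit fraction above which nonparametric
#'   tests are recommended (default 0.1).
#' @param runMock set \code{FALSE} to skip the (relatively expensive) mock
#'   study stage.
#' @param outPrefix optional path prefix for output files.
#' @return list with components \code{gof}, \code{pi0}, \code{qvalues},
#'   \code{zinb}, \code{mock} (or NULL), \code{recommendation} and
#'   \code{configHash}.
#' @export
nbAudit <- function(object, J = 4L, B = 1000L, maxPhi = 10, qCutoff = 0.1,
                    alpha = 0.1, mockReps = 50L, seed = 1L,
                    recommendCutoff = 0.1, runMock = TRUE, outPrefix = NULL) {
  stopifnot(methods::is(object, "NBCountSet"))
  cfg <- list(J = J, B = B, maxPhi = maxPhi, qCutoff = qCutoff,
              alpha = alpha, mockReps = mockReps, seed = seed,
              nFeatures = nrow(object), nSamples = ncol(object))
  cfgHash <- .fnv1a(paste(names(cfg), unlist(cfg), sep = "=", collapse = ";"))

  gof <- gofTest(object, J = J, B = B, maxPhi = maxPhi, seed = seed)
  pv <- gof$pBootstrap
  tested <- !is.na(pv)
  if (sum(tested) < 10)
    stop("audit stage 'pi0': fewer than 10 testable features")
  pi0 <- estimatePi0(pv[tested], seed = .substreamSeed(seed, 101L))
  q <- rep(NA_real_, nrow(object))
  q[tested] <- qValues(pv[tested], pi0 = pi0@pi0)

  zinb <- zinbScreen(object, seed = .substreamSeed(seed, 102L))
  mock <- NULL
  if (runMock)
    mock <- runMockStudy(object, q, nReps = mockReps, alpha = alpha,
                         qCutoff = qCutoff, seed = .substreamSeed(seed, 103L))

  recommendation <- if (pi0@fraction > recommendCutoff) {
    sprintf(paste0("An estimated %.1f%% of the tested features are poorly fit ",
                   "by the negative binomial distribution. NB-based parametric ",
                   "tests may not control the type I error on these data; ",
                   "nonparametric tests (e.g. the Prentice/Wilcoxon rank-sum ",
                   "family) are recommended."), 100 * pi0@fraction)
  } else {
    sprintf(paste0("An estimated %.1f%% of the tested features are poorly fit ",
                   "by the negative binomial distribution. The NB assumption ",
                   "appears adequate for most features; parametric NB-based ",
                   "tests are reasonable."), 100 * pi0@fraction)
  }

  if (!is.null(outPrefix)) {
    writeGofResults(gof, paste0(outPrefix, "_gof.tsv"))
    utils::write.table(
      data.frame(featureId = rownames(object), p = pv, q = q,
                 poorlyFit = !is.na(q) & q < qCutoff),
      paste0(outPrefix, "_qvalues.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(as.data.frame(zinb$table),
                       paste0(outPrefix, "_zinb.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(mock))
      utils::write.table(mock@proportions, paste0(outPrefix, "_mock.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    summary <- list(
      config = cfg, configHash = cfgHash,
      pi0 = pi0@pi0, lackOfFitFraction = pi0@fraction, se = pi0@se,
      pc = pi0@pc, nTested = sum(tested), nSkipped = sum(gof$skipped),
      zeroFreeProportion = zinb$zeroFreeProportion,
      zeroInflatedFraction = zinb$fraction,
      recommendation = recommendation)
    jsonlite::write_json(summary, paste0(outPrefix, "_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(recommendation, paste0(outPrefix, "_recommendation.txt"))
  }
  list(gof = gof, pi0 = pi0, qvalues = q, zinb = zinb, mock = mock,
       recommendation = recommendation, configHash = cfgHash)
}
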