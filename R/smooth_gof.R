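# The smooth goodness-of-fit test: components, statistic, asymptotic and
# parametric-bootstrap p-values, per feature and matrix-wide.

#' Smooth-test components from an evaluated basis
#'
#' \eqn{V_k = n^{-1/2} \sum_i H[i,k]}; under the null the vector V is
#' asymptotically standard multivariate normal (the Fisher information of
#' the embedding parameters reduces to n times the identity under the
#' orthonormality constraints).
#'
#' @param H evaluated basis matrix (samples x components).
#' @return Numeric vector of components.
#' @export
computeComponents <- function(H) {
  if (!is.matrix(H)) H <- matrix(H, ncol = 1)
  if (any(!is.finite(H))) stop("'H' must be finite")
  colSums(H) / sqrt(nrow(H))
}

#' Smooth test statistic
#'
#' \eqn{T_J = \sum_k V_k^2} with df equal to the number of retained
#' components.  An empty component vector (all components degenerate)
#' yields an untestable-feature result rather than an error.
#'
#' @param V component vector.
#' @return list with \code{statistic}, \code{df} and \code{untestable}.
#' @export
smoothStatistic <- function(V) {
  if (length(V) == 0)
    return(list(statistic = NA_real_, df = 0L, untestable = TRUE))
  if (any(!is.finite(V))) stop("'V' must be finite")
  list(statistic = sum(V^2), df = length(V), untestable = FALSE)
}

#' Asymptotic p-value of the smooth statistic
#'
#' Upper tail of the chi-square distribution with \code{df} degrees of
#' freedom.  For the sample sizes typical of sequencing studies this
#' reference is anticonservative; prefer the parametric bootstrap.
#'
#' @param statistic non-negative statistic.
#' @param df positive integer degrees of freedom.
#' @return p-value in [0, 1].
#' @export
asymptoticPvalue <- function(statistic, df) {
  if (any(df < 1)) stop("df must be >= 1")
  if (any(statistic < 0)) stop("statistic must be non-negative")
  stats::pchisq(statistic, df = df, lower.tail = FALSE)
}

#' Parametric-bootstrap p-value for one feature
#'
#' Draws B datasets from the fitted null NB (independently per sample at
#' \eqn{(\hat\mu_i, \hat\phi)}), refits the full regression on each (warm
#' start at the observed fit, cold restart on failure, redraw if both fail,
#' capped at 10\% of B), rebuilds the orthonormal basis at the refitted
#' parameters and recomputes the statistic.  The p-value is
#' \eqn{(1 + \#\{T^*_b \ge T_{obs}\})/(B + 1)}.
#'
#' @param y,x,offset the feature data (0/1 group codes).
#' @param fit the observed \linkS4class{NBFit} (must be converged).
#' @param J smooth-test order.
#' @param B number of bootstrap replicates.
#' @param seed optional seed for reproducibility.
#' @param returnStatistics also return the bootstrap statistics.
#' @param refitDispersion refit the dispersion in every replicate (the
#'   full parametric bootstrap, default) or hold it at the observed
#'   estimate and refit only the regression coefficients.  Both modes
#'   give null-uniform p-values for the features they can test; the full
#'   refit is the default as it also accounts for dispersion-estimation
#'   variability in the null distribution.
#' @return An \linkS4class{SmoothTestResult}, with \code{Tstar} attached as
#'   an attribute when \code{returnStatistics} is \code{TRUE}.
#' @export
bootstrapPvalue <- function(y, x, offset, fit, J = 4L, B = 1000L,
                            seed = NULL, returnStatistics = FALSE,
                            refitDispersion = TRUE) {
  if (!fit@converged) stop("bootstrap requires a converged fit")
  if (B < 1) stop("B must be >= 1")
  X <- if (is.matrix(x)) x else cbind(1, x)
  res <- .withSeed(seed,
    .gofBootstrapCpp(as.numeric(y), X, as.numeric(offset),
                     as.numeric(fit@beta), fit@phi, as.integer(J),
                     as.integer(B), returnTstar = returnStatistics,
                     refitDispersion = refitDispersion))
  if (!isTRUE(res$ok))
    stop("bootstrap failed for this feature: ", res$reason)
  out <- methods::new("SmoothTestResult",
    components = res$components, statistic = res$statistic,
    df = as.integer(res$df),
    pAsymptotic = asymptoticPvalue(res$statistic, res$df),
    pBootstrap = res$pBootstrap, nBootstrap = as.integer(B),
    phiHat = fit@phi, skipped = FALSE, reason = NA_character_)
  if (returnStatistics) attr(out, "Tstar") <- res$Tstar
  out
}

setMethod("show", "SmoothTestResult", function(object) {
  if (object@skipped) {
    cat("SmoothTestResult: skipped (", object@reason, ")\n", sep = "")
    return(invisible(NULL))
  }
  cat("SmoothTestResult: T =", format(object@statistic, digits = 4),
      " df =", object@df, "\n")
  cat("  components:", paste(format(object@components, digits = 3), collapse = ", "), "\n")
  cat("  p (asymptotic chi-square):", format(object@pAsymptotic, digits = 4), "\n")
  if (!is.na(object@pBootstrap))
    cat("  p (bootstrap, B = ", object@nBootstrap, "): ",
        format(object@pBootstrap, digits = 4), "\n", sep = "")
})

#' Matrix-wide smooth goodness-of-fit test
#'
#' Runs the smooth test for every feature of a count set.  Features with
#' an estimated overdispersion of \code{maxPhi} (default 10) or larger are
#' marked skipped — the bootstrap null cannot be trusted there — but keep
#' their dispersion estimate and asymptotic results in the table.  All-zero
#' features are marked degenerate.  Results are deterministic given
#' \code{seed}: every feature draws from its own substream, so the table
#' is invariant to feature order.
#'
#' @param object an \linkS4class{NBCountSet}.
#' @param J smooth-test order (default 4).
#' @param B bootstrap replicates (default 1000); \code{B = 0} skips the
#'   bootstrap and reports only asymptotic p-values.
#' @param maxPhi dispersion cutoff above which features are not
#'   bootstrap-tested; use \code{Inf} to test everything.
#' @param seed master seed for the per-feature bootstrap substreams.
#' @param refitDispersion see \code{\link{bootstrapPvalue}}.
#' @return A \linkS4class{SmoothGofResults} table with one row per feature:
#'   dispersion estimate, df, statistic, asymptotic and bootstrap p-values,
#'   and skip flags with reasons.
#' @examples
#' sim <- simulateDataset(simulationConfig(nFeatures = 20, nSamples = 20, seed = 7))
#' res <- gofTest(countSet(sim), B = 49, seed = 1)
#' head(as.data.frame(res))
#' @export
gofTest <- function(object, J = 4L, B = 1000L, maxPhi = 10, seed = 1L,
                    refitDispersion = TRUE) {
  stopifnot(methods::is(object, "NBCountSet"))
  cnt <- counts(object)
  x <- groupCodes(object)
  off <- computeOffsets(object)
  p <- nrow(cnt)
  J <- as.integer(J); B <- as.integer(B)
  X <- cbind(1, as.numeric(x))

  phiHat <- statistic <- pAsym <- pBoot <- rep(NA_real_, p)
  df <- nFail <- rep(NA_integer_, p)
  converged <- rep(NA, p)
  skipped <- rep(FALSE, p)
  reason <- rep(NA_character_, p)

  for (j in seq_len(p)) {
    y <- as.numeric(cnt[j, ])
    if (sum(y) == 0) {
      skipped[j] <- TRUE; reason[j] <- "degenerate: all counts zero"
      next
    }
    fj <- .nbFitCpp(y, X, off)
    if (!fj$ok) {
      skipped[j] <- TRUE; reason[j] <- "fit failed"
      next
    }
    phiHat[j] <- fj$phi
    converged[j] <- fj$converged
    if (!fj$converged) {
      skipped[j] <- TRUE; reason[j] <- "fit not converged"
      next
    }
    st <- .gofStatCpp(y, fj$mu, fj$phi, J)
    if (!isTRUE(st$ok)) {
      skipped[j] <- TRUE; reason[j] <- "untestable: no retained components"
      next
    }
    statistic[j] <- st$statistic
    df[j] <- st$df
    pAsym[j] <- asymptoticPvalue(st$statistic, st$df)
    if (fj$phi >= maxPhi) {
      skipped[j] <- TRUE; reason[j] <- "dispersion at or above cutoff"
      next
    }
    if (B > 0) {
      # substream keyed on the feature id, so results are invariant to
      # feature order and amenable to parallel execution
      bt <- .withSeed(.substreamSeed(seed, .strHash(rownames(cnt)[j])),
        .gofBootstrapCpp(y, X, off, fj$beta, fj$phi, J, B,
                         returnTstar = FALSE,
                         refitDispersion = refitDispersion))
      if (!isTRUE(bt$ok)) {
        skipped[j] <- TRUE; reason[j] <- bt$reason
        next
      }
      pBoot[j] <- bt$pBootstrap
      nFail[j] <- bt$nFail
    }
  }
  out <- S4Vectors::DataFrame(
    featureId = rownames(cnt), phiHat = phiHat, converged = converged,
    df = df, statistic = statistic, pAsymptotic = pAsym,
    pBootstrap = pBoot, nBootFail = nFail, skipped = skipped,
    reason = reason, row.names = rownames(cnt))
  out <- methods::new("SmoothGofResults", out)
  S4Vectors::metadata(out) <- list(J = J, B = B, maxPhi = maxPhi, seed = seed,
                                   refitDispersion = refitDispersion,
                                   nSamples = ncol(cnt))
  out
}

setMethod("show", "SmoothGofResults", function(object) {
  md <- S4Vectors::metadata(object)
  cat("SmoothGofResults:", nrow(object), "features (J =", md$J,
      ", B =", md$B, ", maxPhi =", md$maxPhi, ")\n")
  cat("  tested:", sum(!object$skipped),
      " skipped:", sum(object$skipped), "\n")
  if (any(object$skipped)) {
    tab <- table(object$reason[object$skipped])
    for (r in names(tab)) cat("    -", r, ":", tab[[r]], "\n")
  }
  callNextMethod()
})

#' Export goodness-of-fit results as tab-separated text
#'
#' @param results a \linkS4class{SmoothGofResults}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGofResults <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
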