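# The mock relabelling study: random two-group allocation, NB Wald and
# Prentice stratified rank-sum p-values per feature, and type-I-error
# proportions split by poorly/well fit status.

#' Random two-group allocation
#'
#' i.i.d. Bernoulli(1/2) labels over the samples; allocations leaving
#' fewer than two samples in either group are redrawn (the redraw count is
#' attached as an attribute).
#'
#' @param sampleIds sample identifiers (or an integer count).
#' @param seed optional seed.
#' @return Named 0/1 integer vector.
#' @export
randomAllocation <- function(sampleIds, seed = NULL) {
  if (length(sampleIds) == 1 && is.numeric(sampleIds))
    sampleIds <- paste0("sample", seq_len(sampleIds))
  n <- length(sampleIds)
  if (n < 4) stop("need at least 4 samples for a random two-group allocation")
  .withSeed(seed, {
    redraws <- 0L
    repeat {
      g <- stats::rbinom(n, 1, 0.5)
      if (min(sum(g), n - sum(g)) >= 2) break
      redraws <- redraws + 1L
    }
    names(g) <- sampleIds
    attr(g, "redraws") <- redraws
    g
  })
}

# observed information over (beta, phi) via central differences of the
# analytic score; returns the variance matrix of beta-hat (or NULL)
.nbObservedVcov <- function(y, X, off, beta, phi) {
  q <- length(beta)
  th <- c(beta, phi)
  sc <- function(t) {
    s <- .nbScoreCpp(as.numeric(y), X, as.numeric(off), t[seq_len(q)], t[q + 1])
    c(s$scoreBeta, s$scorePhi)
  }
  Jm <- matrix(NA_real_, q + 1, q + 1)
  for (k in seq_len(q + 1)) {
    h <- 1e-5 * max(abs(th[k]), 1e-2)
    tp <- th; tp[k] <- th[k] + h
    tm <- th; tm[k] <- th[k] - h
    if (k == q + 1 && tm[k] <= 0) tm[k] <- th[k] / 2
    Jm[, k] <- (sc(tp) - sc(tm)) / (tp[k] - tm[k])
  }
  info <- -(Jm + t(Jm)) / 2
  V <- try(solve(info), silent = TRUE)
  if (!inherits(V, "try-error") && all(diag(V)[seq_len(q)] > 0))
    return(V[seq_len(q), seq_len(q), drop = FALSE])
  # fall back to the beta block (asymptotically block-diagonal)
  Vb <- try(solve(info[seq_len(q), seq_len(q)]), silent = TRUE)
  if (inherits(Vb, "try-error") || any(diag(Vb) <= 0)) return(NULL)
  Vb
}

#' NB Wald test for a random grouping variable
#'
#' Fits the NB regression with offset, the original grouping variable and
#' the random grouping variable as regressors, and returns the two-sided
#' Wald p-value for the random-group coefficient, with the standard error
#' taken from the observed information at the MLE and a standard normal
#' reference.
#'
#' @param y counts; \code{offset} log library sizes.
#' @param originalGroup,randomGroup 0/1 codes.
#' @return p-value, or \code{NA} on rank deficiency or non-convergence.
#' @export
waldTestRandomGroup <- function(y, offset, originalGroup, randomGroup) {
  X <- cbind(intercept = 1, original = as.numeric(originalGroup),
             random = as.numeric(randomGroup))
  if (qr(X)$rank < ncol(X)) {
    warning("rank-deficient design (random group collinear with original)")
    return(NA_real_)
  }
  if (sum(y) == 0) return(NA_real_)
  f <- .nbFitCpp(as.numeric(y), X, as.numeric(offset))
  if (!f$ok || !f$converged) return(NA_real_)
  V <- .nbObservedVcov(y, X, offset, f$beta, f$phi)
  if (is.null(V)) return(NA_real_)
  z <- f$beta[3] / sqrt(V[3, 3])
  2 * stats::pnorm(-abs(z))
}

#' Prentice stratified rank-sum test
#'
#' Stratified extension of the Wilcoxon rank-sum test (the family that
#' also contains the Friedman test): within each stratum the counts are
#' midranked, the centred rank sum of the tested group is computed with
#' its permutation variance (midrank tie correction), strata are combined
#' with van Elteren weights \eqn{1/(N_s + 1)}, and the standardised sum is
#' referred to the standard normal, two-sided.  With a single stratum this
#' reduces exactly to the normal-approximation Wilcoxon test.
#'
#' @param y response values.
#' @param group 0/1 codes of the tested grouping variable.
#' @param strata optional stratification factor (e.g. the original group);
#'   strata lacking either group label are dropped (count attached as an
#'   attribute).
#' @return Two-sided p-value (1 when every stratum is degenerate, NA when
#'   no stratum is usable).
#' @export
prenticeRankTest <- function(y, group, strata = NULL) {
  if (is.null(strata)) strata <- rep(1L, length(y))
  if (length(y) != length(group) || length(y) != length(strata))
    stop("'y', 'group' and 'strata' must be conformable")
  num <- 0; den <- 0
  dropped <- 0L
  usable <- 0L
  for (s in unique(strata)) {
    idx <- strata == s
    gs <- group[idx]
    if (length(unique(gs)) < 2) { dropped <- dropped + 1L; next }
    usable <- usable + 1L
    ys <- y[idx]
    N <- length(ys)
    n1 <- sum(gs == 1)
    r <- rank(ys)                      # midranks
    W <- sum(r[gs == 1]) - n1 * (N + 1) / 2
    v <- n1 * (N - n1) / (N * (N - 1)) * sum((r - (N + 1) / 2)^2)
    w <- 1 / (N + 1)                   # van Elteren weight
    num <- num + w * W
    den <- den + w^2 * v
  }
  if (usable == 0L) return(NA_real_)
  p <- if (den <= 0) 1 else 2 * stats::pnorm(-abs(num / sqrt(den)))
  attr(p, "droppedStrata") <- dropped
  p
}

#' Run the mock relabelling study
#'
#' Repeats \code{nReps} times: allocate the samples at random to two
#' pseudo-groups, then for every feature compute the NB Wald p-value for
#' the random group (adjusting for the original group) and the Prentice
#' rank-sum p-value (stratified by the original group).  Because the
#' random labels carry no signal, every small p-value is a false positive;
#' the proportions of p < alpha, tabulated separately for features with
#' poor (q < \code{qCutoff}) and good fit, measure each test's type-I
#' error on real-data-like features.
#'
#' @param object an \linkS4class{NBCountSet}.
#' @param gof matrix-wide results from \code{\link{gofTest}} (bootstrap
#'   p-values are used for the q-value split), or a precomputed q-value
#'   vector aligned with the features.
#' @param nReps number of random allocations (default 50).
#' @param alpha nominal level for the tabulated proportions (default 0.1).
#' @param qCutoff q-value threshold for the poorly fit group.
#' @param seed master seed (per-repetition substreams).
#' @return A \linkS4class{MockStudyResult}.
#' @export
runMockStudy <- function(object, gof, nReps = 50L, alpha = 0.1,
                         qCutoff = 0.1, seed = 1L) {
  stopifnot(methods::is(object, "NBCountSet"))
  cnt <- counts(object)
  p <- nrow(cnt)
  off <- computeOffsets(object)
  orig <- groupCodes(object)

  if (methods::is(gof, "SmoothGofResults")) {
    pv <- gof$pBootstrap
    if (all(is.na(pv))) pv <- gof$pAsymptotic
    ok <- !is.na(pv)
    q <- rep(NA_real_, p)
    if (sum(ok) >= 10) q[ok] <- qValues(pv[ok])
  } else {
    q <- as.numeric(gof)
    if (length(q) != p) stop("q-value vector must align with the features")
  }
  fitGroup <- factor(ifelse(is.na(q), NA,
                            ifelse(q < qCutoff, "poorly fit", "well fit")),
                     levels = c("poorly fit", "well fit"))

  pW <- matrix(NA_real_, p, nReps, dimnames = list(rownames(cnt), NULL))
  pP <- matrix(NA_real_, p, nReps)
  for (r in seq_len(nReps)) {
    rg <- randomAllocation(colnames(cnt), seed = .substreamSeed(seed, r))
    for (j in seq_len(p)) {
      y <- as.numeric(cnt[j, ])
      if (sum(y) == 0) next
      pW[j, r] <- suppressWarnings(waldTestRandomGroup(y, off, orig, rg))
      pP[j, r] <- as.numeric(prenticeRankTest(y, rg, strata = orig))
    }
  }
  props <- do.call(rbind, lapply(levels(fitGroup), function(gr) {
    idx <- which(fitGroup == gr)
    data.frame(fitGroup = gr,
               test = c("Wald", "Prentice"),
               proportion = c(mean(pW[idx, ] < alpha, na.rm = TRUE),
                              mean(pP[idx, ] < alpha, na.rm = TRUE)),
               nFeatures = length(idx))
  }))
  methods::new("MockStudyResult", pWald = pW, pPrentice = pP,
               fitGroup = fitGroup, alpha = alpha,
               nReps = as.integer(nReps), proportions = props)
}

setMethod("show", "MockStudyResult", function(object) {
  cat("MockStudyResult:", nrow(object@pWald), "features x", object@nReps,
      "random allocations (alpha =", object@alpha, ")\n")
  cat("  proportions of p <", object@alpha, "by test and fit group:\n")
  print(object@proportions, row.names = FALSE)
})
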