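#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importClassesFrom S4Vectors DFrame
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Count matrix with two-group design for goodness-of-fit testing
#'
#' \code{NBCountSet} extends \linkS4class{SummarizedExperiment}: the single
#' \code{"counts"} assay holds the non-negative integer feature-by-sample
#' matrix, and \code{colData} carries the two-level grouping factor
#' (\code{group}) and the per-sample library sizes (\code{libSize}).  All
#' model fitting in the package uses the natural log of the library size as
#' an offset.
#'
#' Validity requires: integer-valued finite non-negative counts, unique
#' feature and sample identifiers, exactly two observed group levels with
#' at least two samples each, and strictly positive library sizes (samples
#' whose column sum is zero are rejected, not dropped — filter explicitly).
#'
#' @seealso \code{\link{NBCountSet}} (constructor), \code{\link{gofTest}}
#' @export
setClass("NBCountSet", contains = "SummarizedExperiment")

setValidity("NBCountSet", function(object) {
  msg <- NULL
  if (!("counts" %in% SummarizedExperiment::assayNames(object)))
    return("assay 'counts' is required")
  m <- SummarizedExperiment::assay(object, "counts")
  if (anyNA(m) || any(!is.finite(m)))
    msg <- c(msg, "counts must be finite and non-missing")
  else if (any(m < 0) || any(m != floor(m)))
    msg <- c(msg, "counts must be non-negative integers")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature ids must be present and unique")
  if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be present and unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "libSize") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'group' and 'libSize'")
  } else {
    g <- cd$group
    if (!is.factor(g) || nlevels(g) != 2L)
      msg <- c(msg, "'group' must be a factor with exactly 2 levels")
    else if (min(table(g)) < 2L)
      msg <- c(msg, "need at least 2 samples per group")
    ls <- cd$libSize
    if (anyNA(ls) || any(!is.finite(ls)) || any(ls <= 0))
      msg <- c(msg, "library sizes must be positive (remove all-zero samples explicitly)")
  }
  if (is.null(msg)) TRUE else msg
})

#' Maximum-likelihood fit of the two-group negative binomial regression
#'
#' Holds the ML estimates of the regression coefficients and the
#' overdispersion parameter phi (variance \eqn{\mu(1+\phi\mu)}), the fitted
#' per-sample means, and convergence diagnostics.  \code{scoreNorm} is the
#' maximum absolute component of the score evaluated at the optimum (the
#' beta score and the score with respect to log phi).
#'
#' @slot beta named numeric vector of regression coefficients (intercept
#'   first; the offset has a fixed unit coefficient and is not included).
#' @slot phi positive overdispersion estimate.
#' @slot mu fitted per-sample means.
#' @slot loglik maximised log-likelihood.
#' @slot converged logical convergence flag (honest: \code{FALSE} when the
#'   iteration limit or the upper dispersion bound was hit).
#' @slot nIter number of outer iterations used.
#' @slot scoreNorm max absolute score component at the optimum.
#' @slot atBound -1/0/1: phi at the lower bound (Poisson limit), interior,
#'   or at the upper bound.
#' @export
setClass("NBFit", representation(
  beta = "numeric", phi = "numeric", mu = "numeric", loglik = "numeric",
  converged = "logical", nIter = "integer", scoreNorm = "numeric",
  atBound = "integer"))

#' Orthonormal h-function system for the smooth embedding
#'
#' For each sample, the h-functions are orthonormal under the fitted
#' negative binomial at that sample's (mu_i, phi) and orthogonal to the
#' nuisance score functions (the beta scores and the dispersion score).
#' They are represented as coefficients over the raw function system
#' \{1, t, g, t^2, ..., t^(J+2)\} with t = (y - mu_i)/sigma_i standardised
#' and g(y) = digamma(y + 1/phi), which spans the dispersion score.
#'
#' @slot order requested order J of the smooth test.
#' @slot coefs per-sample coefficient matrices (raw functions x retained
#'   components), aligned to the global \code{degrees}.
#' @slot degrees monomial degrees of the globally retained components
#'   (retained in every sample).
#' @slot sigma per-sample standard deviations used for the t scaling.
#' @slot mu per-sample fitted means; \code{phi} fitted dispersion;
#'   \code{group} the 0/1 design codes.
#' @export
setClass("OrthonormalBasis", representation(
  order = "integer", coefs = "list", degrees = "integer", sigma = "numeric",
  mu = "numeric", phi = "numeric", group = "numeric"))

#' Result of the smooth goodness-of-fit test for one feature
#'
#' The statistic is the sum of squared components, each component being a
#' standardised sum of one h-function over samples; under the null it is
#' asymptotically chi-square with \code{df} (the number of retained
#' components) degrees of freedom.  The bootstrap p-value uses the
#' (1+m)/(B+1) convention.
#'
#' @export
setClass("SmoothTestResult", representation(
  components = "numeric", statistic = "numeric", df = "integer",
  pAsymptotic = "numeric", pBootstrap = "numeric", nBootstrap = "integer",
  phiHat = "numeric", skipped = "logical", reason = "character"))

#' Per-feature results of the matrix-wide goodness-of-fit test
#'
#' A \linkS4class{DFrame} with one row per feature and metadata recording
#' the run configuration (J, B, maxPhi, seed).
#'
#' @export
setClass("SmoothGofResults", contains = "DFrame")

#' Modified Grenander estimate of a p-value density
#'
#' The least concave majorant of the empirical distribution function on
#' [0, 1]; its left derivative is the monotone non-increasing density
#' estimate.
#'
#' @slot knots x-coordinates of the majorant knots (starts at 0, ends at 1).
#' @slot cdf majorant values at the knots (0 to 1).
#' @slot slopes density value on each inter-knot interval (non-increasing).
#' @export
setClass("GrenanderFit", representation(
  knots = "numeric", cdf = "numeric", slopes = "numeric"))

#' Estimated fraction of features with lack of fit
#'
#' @slot pi0 estimated proportion of features consistent with the null
#'   (well fit); \code{fraction} = 1 - pi0 is the lack-of-fit fraction.
#' @slot se nonparametric bootstrap standard error of \code{fraction}.
#' @slot pc the p-value cutoff above which the alternative density is
#'   assumed to vanish.
#' @slot grenander the underlying \linkS4class{GrenanderFit}.
#' @slot nTested number of p-values used.
#' @export
setClass("Pi0Estimate", representation(
  pi0 = "numeric", fraction = "numeric", se = "numeric", pc = "numeric",
  grenander = "GrenanderFit", nTested = "integer"))

#' Zero-inflated negative binomial fit
#'
#' Mixture of a point mass at zero (probability \code{piZero}) and a
#' negative binomial with the same two-group regression mean structure.
#' Features without any zero observation leave \code{piZero} unidentified
#' at the boundary and are flagged \code{fittable = FALSE}.
#'
#' @export
setClass("ZINBFit", representation(
  beta = "numeric", phi = "numeric", piZero = "numeric", mu = "numeric",
  loglik = "numeric", converged = "logical", fittable = "logical"))

#' Likelihood-ratio test of NB against ZINB
#'
#' @slot statistic 2 * (loglik ZINB - loglik NB), floored at zero.
#' @slot p p-value under the null convention in \code{dfConvention}
#'   (boundary-corrected mixture 0.5 chi2_0 + 0.5 chi2_1 by default).
#' @export
setClass("LRResult", representation(
  statistic = "numeric", p = "numeric", dfConvention = "character"))

#' Mock relabelling study results
#'
#' Per repetition and feature, p-values of the NB Wald test and the
#' Prentice stratified rank-sum test for a randomly allocated grouping
#' variable, with features split into poorly and well fit groups by the
#' goodness-of-fit q-values.
#'
#' @slot pWald,pPrentice feature x repetition p-value matrices.
#' @slot fitGroup factor "poorly fit"/"well fit" per feature (NA when the
#'   feature had no usable goodness-of-fit p-value).
#' @slot proportions data.frame of proportions of p < alpha by test and
#'   fit group.
#' @export
setClass("MockStudyResult", representation(
  pWald = "matrix", pPrentice = "matrix", fitGroup = "factor",
  alpha = "numeric", nReps = "integer", proportions = "data.frame"))

#' Synthetic-data simulation configuration
#'
#' Defaults reproduce the package's reference simulation design: p = 500
#' features by n = 50 samples balanced over two groups; log library-size
#' offsets normal with mean 9.21 and sd 1.15 (natural-log scale, i.e.
#' typical depth around exp(9.21) ~ 10^4); feature baselines uniform on
#' [-13.8, -6.91]; group log-fold change 2; a single overdispersion phi for
#' all features.  Misfit variants perturb a fraction of features: structural
#' zero inflation with probability \code{misfitProb}, per-sample dispersion
#' heterogeneity, or multiplicative outliers.
#'
#' @export
setClass("SimulationConfig", representation(
  nFeatures = "integer", nSamples = "integer", phi = "numeric",
  offsetMean = "numeric", offsetSd = "numeric",
  baselineLow = "numeric", baselineHigh = "numeric", beta2 = "numeric",
  misfit = "character", misfitProb = "numeric", misfitFraction = "numeric",
  seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- NULL
  if (object@nFeatures < 1) msg <- c(msg, "nFeatures must be >= 1")
  if (object@nSamples < 4 || object@nSamples %% 2 != 0)
    msg <- c(msg, "nSamples must be even and >= 4 (balanced design)")
  if (any(object@phi <= 0)) msg <- c(msg, "phi must be positive")
  if (object@offsetSd <= 0) msg <- c(msg, "offsetSd must be positive")
  if (object@baselineHigh < object@baselineLow)
    msg <- c(msg, "baseline interval is empty")
  if (!object@misfit %in% c("none", "zero_inflation", "dispersion_heterogeneity", "outliers"))
    msg <- c(msg, "unknown misfit variant")
  if (object@misfitProb < 0 || object@misfitProb >= 1)
    msg <- c(msg, "misfitProb must be in [0, 1)")
  if (object@misfitFraction < 0 || object@misfitFraction > 1)
    msg <- c(msg, "misfitFraction must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Simulated dataset with generating truth
#'
#' @slot countSet the simulated \linkS4class{NBCountSet} (library sizes are
#'   the generating depths, so offsets match the generating model).
#' @slot truth per-feature DataFrame of generating parameters and misfit
#'   flags; per-sample log-depths are in \code{colData(countSet)$beta0}.
#' @slot config the \linkS4class{SimulationConfig} used.
#' @export
setClass("SimulatedDataset", representation(
  countSet = "NBCountSet", truth = "DFrame", config = "SimulationConfig"))
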