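# Estimating the proportion of poorly fit features from the vector of
# goodness-of-fit p-values: p-value mixture g(p) = pi0 g0(p) + (1-pi0) gA(p)
# with g0 uniform, via the modified Grenander density estimator, plus
# q-values for the poorly/well-fit split.

#' Modified Grenander estimate of the p-value density
#'
#' Computes the least concave majorant of the empirical CDF of the
#' p-values on [0, 1]; its left derivative is the monotone non-increasing
#' density estimate (the p-value density is a mixture of a uniform and a
#' decreasing alternative density, hence itself decreasing).
#'
#' @param p p-values in [0, 1]; at least 10 are required.
#' @return A \linkS4class{GrenanderFit}.
#' @examples
#' g <- grenanderFit(runif(200))
#' grenanderDensity(g, c(0.1, 0.9))
#' @export
grenanderFit <- function(p) {
  if (length(p) < 10) stop("need at least 10 p-values")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (length(unique(p)) == 1) stop("degenerate input: all p-values identical")
  n <- length(p)
  sp <- sort(p)
  u <- unique(sp)
  Fu <- cumsum(tabulate(match(sp, u))) / n
  x <- c(0, u)
  Fx <- c(0, Fu)
  if (max(u) < 1) { x <- c(x, 1); Fx <- c(Fx, 1) }
  Fx[length(Fx)] <- 1
  # least concave majorant via an upper-hull scan (slopes non-increasing)
  keep <- c(1L, 2L)
  for (i in 3:length(x)) {
    repeat {
      k <- length(keep)
      if (k < 2) break
      s1 <- (Fx[keep[k]] - Fx[keep[k - 1]]) / (x[keep[k]] - x[keep[k - 1]])
      s2 <- (Fx[i] - Fx[keep[k]]) / (x[i] - x[keep[k]])
      if (s2 <= s1) break
      keep <- keep[-k]
    }
    keep <- c(keep, i)
  }
  kx <- x[keep]; kF <- Fx[keep]
  slopes <- diff(kF) / diff(kx)
  methods::new("GrenanderFit", knots = kx, cdf = kF, slopes = slopes)
}

#' @describeIn grenanderFit evaluate the density estimate.
#' @param object a \code{GrenanderFit}; \code{at} evaluation points.
#' @param at numeric vector in [0, 1].
#' @export
grenanderDensity <- function(object, at) {
  idx <- findInterval(at, object@knots, left.open = TRUE, all.inside = TRUE)
  object@slopes[idx]
}

#' @describeIn grenanderFit evaluate the CDF estimate (piecewise linear,
#'   with G(1) = 1).
#' @export
grenanderCdf <- function(object, at) {
  idx <- findInterval(at, object@knots, left.open = TRUE, all.inside = TRUE)
  object@cdf[idx] + object@slopes[idx] * (at - object@knots[idx])
}

setMethod("show", "GrenanderFit", function(object) {
  cat("GrenanderFit:", length(object@slopes), "pieces; density at 0:",
      format(object@slopes[1], digits = 4), " at 1:",
      format(object@slopes[length(object@slopes)], digits = 4), "\n")
})

#' Estimate the proportion of features with lack of fit
#'
#' Assuming the alternative p-value density vanishes above some cutoff
#' \eqn{p_c}, the p-values beyond the cutoff are pure null (uniform), so
#' the null proportion is estimated from the tail count,
#' \deqn{\hat\pi_0 = \min\!\left(1, \frac{\#\{p_k > p_c\}}{n}\,
#'   \frac{1}{1 - p_c}\right),}
#' and the reported lack-of-fit fraction is \eqn{1 - \hat\pi_0}, with a
#' nonparametric bootstrap standard error (resampling the p-vector).
#'
#' The default cutoff is 0.75, a conservative quantile in the fdrtool
#' tradition that is robust both to alternative densities with heavy right
#' tails (which bias the estimate when the cutoff is early) and to the
#' spurious late crossings a data-driven rule can produce under a pure
#' null.  \code{pcMethod = "crossing"} instead uses the first point where
#' the modified Grenander density drops to the uniform level 1 — the
#' earliest cutoff compatible with an exhausted alternative; if that lies
#' at or beyond the largest p-value, the fallback \eqn{p_c = 0.75} is used
#' with a warning.
#'
#' Precise p-values are not needed here: the estimate is driven by the
#' shape of the p-value distribution, so a small bootstrap B upstream
#' suffices.
#'
#' @param p p-values of the tested (unskipped) features.
#' @param pc optional fixed cutoff overriding the automatic rule.
#' @param pcMethod \code{"conservative"} (default, floor at 0.75) or
#'   \code{"crossing"} (first Grenander crossing of the uniform level).
#' @param tail \code{"count"} (default; the empirical tail count) or
#'   \code{"grenander"} (the Grenander CDF tail mass \eqn{1-\hat G(p_c)}
#'   in the numerator, a smoothed variant).
#' @param nBootSe bootstrap resamples for the standard error.
#' @param seed optional seed for the standard-error bootstrap.
#' @return A \linkS4class{Pi0Estimate}.
#' @examples
#' p <- c(runif(700), rbeta(300, 0.1, 1))
#' estimatePi0(p, seed = 1)
#' @export
estimatePi0 <- function(p, pc = NULL, pcMethod = c("conservative", "crossing"),
                        tail = c("count", "grenander"), nBootSe = 200L,
                        seed = NULL) {
  pcMethod <- match.arg(pcMethod)
  tail <- match.arg(tail)
  g <- grenanderFit(p)
  n <- length(p)
  .pi0once <- function(pv, gg, cut) {
    if (is.null(cut)) {
      if (pcMethod == "conservative") {
        cut <- 0.75
      } else {
        below <- which(gg@slopes <= 1)
        cut <- if (length(below)) gg@knots[below[1]] else NA_real_
        if (is.na(cut) || cut >= max(pv)) {
          warning("automatic cutoff at or beyond max(p); falling back to p_c = 0.75")
          cut <- 0.75
        }
      }
    }
    tailMass <- if (tail == "grenander") 1 - grenanderCdf(gg, cut) else mean(pv > cut)
    pi0 <- min(1, tailMass / (1 - cut))
    list(pi0 = pi0, pc = cut)
  }
  est <- .pi0once(p, g, pc)
  if (nBootSe < 2L) {
    return(methods::new("Pi0Estimate", pi0 = est$pi0, fraction = 1 - est$pi0,
                        se = NA_real_, pc = est$pc, grenander = g,
                        nTested = n))
  }
  se <- .withSeed(seed, {
    reps <- vapply(seq_len(nBootSe), function(b) {
      pb <- sample(p, n, replace = TRUE)
      gb <- try(grenanderFit(pb), silent = TRUE)
      if (inherits(gb, "try-error")) return(NA_real_)
      suppressWarnings(.pi0once(pb, gb, pc)$pi0)
    }, numeric(1))
    stats::sd(1 - reps, na.rm = TRUE)
  })
  methods::new("Pi0Estimate", pi0 = est$pi0, fraction = 1 - est$pi0,
               se = se, pc = est$pc, grenander = g, nTested = n)
}

setMethod("show", "Pi0Estimate", function(object) {
  cat("Pi0Estimate: pi0 =", format(object@pi0, digits = 4),
      " lack-of-fit fraction =", format(object@fraction, digits = 4),
      "(se", format(object@se, digits = 2), ")\n")
  cat("  cutoff p_c =", format(object@pc, digits = 4),
      " from", object@nTested, "p-values\n")
})

#' q-values for the poorly/well-fit split
#'
#' Benjamini-Hochberg adjusted p-values scaled by \eqn{\hat\pi_0}
#' (estimated from the same p-vector unless supplied), monotone
#' non-decreasing in p and capped at 1.  Features with q below 10\% are
#' conventionally grouped as poorly fit.
#'
#' @param p p-values.
#' @param pi0 optional null proportion; estimated via
#'   \code{\link{estimatePi0}} when missing.
#' @return Numeric q-values aligned with \code{p}.
#' @export
qValues <- function(p, pi0 = NULL) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  if (is.null(pi0)) {
    pi0 <- if (length(unique(p)) == 1) 1
           else suppressWarnings(estimatePi0(p, nBootSe = 0L)@pi0)
  }
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  q <- pmin(1, cummin(n * pi0 * p[o] / rank(p, ties.method = "max")[o]))[ro]
  q
}
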