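# Zero-inflated negative binomial fit and the likelihood-ratio screen for
# zero inflation relative to the plain NB.

.zinbLoglik <- function(par, y, X, off) {
  beta <- par[seq_len(ncol(X))]
  phi <- exp(par[ncol(X) + 1])
  pi0 <- stats::plogis(par[ncol(X) + 2])
  mu <- exp(pmin(pmax(off + drop(X %*% beta), -40), 40))
  lf <- stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE)
  ll <- numeric(length(y))
  z <- y == 0
  # log(pi0 + (1 - pi0) f0) computed stably
  ll[z] <- log(pi0 + exp(log1p(-pi0) + lf[z]))
  ll[!z] <- log1p(-pi0) + lf[!z]
  sum(ll)
}

#' Fit the zero-inflated negative binomial
#'
#' Mixture pmf \eqn{\pi 1\{y=0\} + (1-\pi) f(y;\mu,\phi)} with the same
#' two-group log-linear mean (offset + intercept + group effect) as the
#' plain NB and a covariate-free structural-zero probability on the logit
#' scale.  Direct maximisation (BFGS from the NB fit, zero-excess moment
#' start for pi) with an EM fallback on failure.  Features without any
#' zero observation leave pi unidentified at the boundary and are returned
#' with \code{fittable = FALSE}.
#'
#' @param y,x,offset feature data (0/1 group codes).
#' @param nbFit optional \linkS4class{NBFit} to warm-start from.
#' @return A \linkS4class{ZINBFit}.
#' @export
fitZINB <- function(y, x, offset, nbFit = NULL) {
  .assertCountVector(y)
  X <- if (is.matrix(x)) x else cbind(1, x)
  if (sum(y) == 0) stop("degenerate feature: all counts are zero")
  if (!any(y == 0))
    return(methods::new("ZINBFit", beta = rep(NA_real_, ncol(X)),
                        phi = NA_real_, piZero = NA_real_, mu = numeric(0),
                        loglik = NA_real_, converged = FALSE, fittable = FALSE))
  if (is.null(nbFit)) nbFit <- fitNB(y, x, offset)
  # moment start for pi: observed excess of zeros over the NB prediction
  p0 <- mean(stats::dnbinom(0, size = 1 / nbFit@phi, mu = nbFit@mu))
  piStart <- min(max((mean(y == 0) - p0) / max(1 - p0, 1e-6), 0.01), 0.9)
  par0 <- c(nbFit@beta, log(max(nbFit@phi, 1e-6)), stats::qlogis(piStart))
  opt <- try(stats::optim(par0, .zinbLoglik, y = y, X = X, off = offset,
                          method = "BFGS",
                          control = list(fnscale = -1, maxit = 500,
                                         reltol = 1e-12)),
             silent = TRUE)
  ok <- !inherits(opt, "try-error") && is.finite(opt$value)
  if (!ok || opt$convergence != 0) {
    em <- .zinbEM(y, X, offset, nbFit)
    if (!is.null(em) && (!ok || em$value >= opt$value)) opt <- em
    ok <- !is.null(opt) && !inherits(opt, "try-error") && is.finite(opt$value)
  }
  if (!ok)
    return(methods::new("ZINBFit", beta = rep(NA_real_, ncol(X)),
                        phi = NA_real_, piZero = NA_real_, mu = numeric(0),
                        loglik = NA_real_, converged = FALSE, fittable = TRUE))
  # the ZINB supremum is attained on the closure: pi -> 0 recovers the NB
  # fit exactly, so never report less than that boundary value
  bnd <- c(nbFit@beta, log(max(nbFit@phi, 1e-8)), -30)
  if (opt$value < .zinbLoglik(bnd, y, X, offset)) {
    opt <- list(par = bnd, value = .zinbLoglik(bnd, y, X, offset),
                convergence = 0)
  }
  par <- opt$par
  beta <- par[seq_len(ncol(X))]
  names(beta) <- colnames(X)
  mu <- exp(offset + drop(X %*% beta))
  methods::new("ZINBFit", beta = beta, phi = exp(par[ncol(X) + 1]),
               piZero = stats::plogis(par[ncol(X) + 2]), mu = mu,
               loglik = opt$value,
               converged = is.null(opt$convergence) || opt$convergence == 0,
               fittable = TRUE)
}

# EM fallback: E-step assigns structural-zero responsibilities, M-step
# maximises the weighted NB log-likelihood by BFGS over (beta, log phi).
.zinbEM <- function(y, X, off, nbFit, maxit = 100) {
  beta <- nbFit@beta; phi <- max(nbFit@phi, 1e-6)
  pi0 <- 0.1
  wll <- function(par, w) {
    b <- par[seq_len(ncol(X))]; ph <- exp(par[ncol(X) + 1])
    mu <- exp(pmin(pmax(off + drop(X %*% b), -40), 40))
    sum(w * stats::dnbinom(y, size = 1 / ph, mu = mu, log = TRUE))
  }
  llOld <- -Inf
  for (it in seq_len(maxit)) {
    mu <- exp(off + drop(X %*% beta))
    lf0 <- stats::dnbinom(0, size = 1 / phi, mu = mu, log = TRUE)
    z <- numeric(length(y))
    z[y == 0] <- pi0 / (pi0 + exp(log1p(-pi0) + lf0[y == 0]))
    pi0 <- max(min(mean(z), 0.99), 1e-8)
    opt <- try(stats::optim(c(beta, log(phi)), wll, w = 1 - z, method = "BFGS",
                            control = list(fnscale = -1, maxit = 200)),
               silent = TRUE)
    if (inherits(opt, "try-error")) return(NULL)
    beta <- opt$par[seq_len(ncol(X))]
    phi <- exp(opt$par[ncol(X) + 1])
    ll <- .zinbLoglik(c(beta, log(phi), stats::qlogis(pi0)), y, X, off)
    if (is.finite(ll) && abs(ll - llOld) < 1e-8 * (1 + abs(ll))) break
    llOld <- ll
  }
  list(par = c(beta, log(phi), stats::qlogis(pi0)), value = ll, convergence = 0)
}

setMethod("show", "ZINBFit", function(object) {
  if (!object@fittable) {
    cat("ZINBFit: not fittable (no zero observations)\n")
    return(invisible(NULL))
  }
  cat("ZINBFit: pi_zero =", format(object@piZero, digits = 4),
      " phi =", format(object@phi, digits = 4),
      " loglik =", format(object@loglik, digits = 6),
      if (object@converged) "(converged)\n" else "(NOT converged)\n")
})

#' Likelihood-ratio test of the NB against the ZINB
#'
#' Statistic \eqn{\max(0, 2(\ell_{ZINB} - \ell_{NB}))}.  Because
#' \eqn{\pi = 0} lies on the boundary of the parameter space, the default
#' null reference is the mixture \eqn{\tfrac12\chi^2_0 + \tfrac12\chi^2_1};
#' a plain \eqn{\chi^2_1} convention is available for comparison.
#'
#' @param nb a converged \linkS4class{NBFit}.
#' @param zi the corresponding \linkS4class{ZINBFit}.
#' @param convention \code{"boundary"} (default) or \code{"chisq1"}.
#' @return An \linkS4class{LRResult}; \code{NA} p-value when the ZINB was
#'   not fittable or either fit did not converge.
#' @export
lrTestZINB <- function(nb, zi, convention = c("boundary", "chisq1")) {
  convention <- match.arg(convention)
  if (!zi@fittable || !zi@converged || !nb@converged)
    return(methods::new("LRResult", statistic = NA_real_, p = NA_real_,
                        dfConvention = convention))
  stat <- max(0, 2 * (zi@loglik - nb@loglik))
  p <- if (convention == "boundary") {
    if (stat <= 0) 1 else 0.5 * stats::pchisq(stat, 1, lower.tail = FALSE)
  } else {
    stats::pchisq(stat, 1, lower.tail = FALSE)
  }
  methods::new("LRResult", statistic = stat, p = p, dfConvention = convention)
}

setMethod("show", "LRResult", function(object) {
  cat("LRResult: statistic =", format(object@statistic, digits = 4),
      " p =", format(object@p, digits = 4),
      " (", object@dfConvention, ")\n")
})

#' Matrix-wide zero-inflation screen
#'
#' Fits NB and ZINB to every feature, runs the likelihood-ratio test, and
#' estimates the fraction of zero-inflated features from the LR results
#' with the same tail-count/Grenander machinery used for the
#' goodness-of-fit fractions — adapted to the boundary null.  Because
#' \eqn{\pi = 0} lies on the boundary, about half of all null features
#' have an LR statistic of exactly zero and the remainder follow
#' \eqn{\chi^2_1}; p-values are therefore uniform only \emph{conditional
#' on a positive statistic}.  The screen applies \code{\link{estimatePi0}}
#' to \eqn{p' = P(\chi^2_1 > LR)} among positive-statistic features and
#' scales the resulting alternative fraction by the positive-statistic
#' proportion.
#'
#' Features without zeros are unfittable and are excluded (their relative
#' frequency is reported via \code{zeroFreeProportion}); the fraction
#' refers to the ZINB-fittable features only and may overestimate the
#' dataset-wide prevalence of zero inflation.
#'
#' @param object an \linkS4class{NBCountSet}.
#' @param convention LR null convention for the reported per-feature
#'   p-values, see \code{\link{lrTestZINB}}.
#' @param seed seed for the fraction's standard-error bootstrap
#'   (resampling features).
#' @param nBootSe bootstrap resamples for the standard error.
#' @return list with \code{table} (per-feature DFrame), \code{fraction}
#'   (estimated fraction of zero-inflated features, NA if fewer than 10
#'   positive-statistic features), \code{fractionSe}, \code{nTestable}
#'   and \code{zeroFreeProportion}.
#' @export
zinbScreen <- function(object, convention = c("boundary", "chisq1"), seed = 1L,
                       nBootSe = 200L) {
  stopifnot(methods::is(object, "NBCountSet"))
  convention <- match.arg(convention)
  cnt <- counts(object)
  x <- groupCodes(object)
  off <- computeOffsets(object)
  p <- nrow(cnt)
  piZero <- statLR <- pLR <- rep(NA_real_, p)
  fittable <- rep(FALSE, p)
  for (j in seq_len(p)) {
    y <- as.numeric(cnt[j, ])
    if (sum(y) == 0) next
    nb <- try(fitNB(y, x, off), silent = TRUE)
    if (inherits(nb, "try-error") || !nb@converged) next
    zi <- fitZINB(y, x, off, nbFit = nb)
    fittable[j] <- zi@fittable
    if (!zi@fittable || !zi@converged) next
    piZero[j] <- zi@piZero
    lr <- lrTestZINB(nb, zi, convention)
    statLR[j] <- lr@statistic
    pLR[j] <- lr@p
  }
  tab <- S4Vectors::DataFrame(
    featureId = rownames(cnt), fittable = fittable, piZero = piZero,
    statistic = statLR, p = pLR, row.names = rownames(cnt))

  .zifrac <- function(st, withSe = FALSE) {
    st <- st[!is.na(st)]
    pos <- st > 1e-4        # numerically-zero statistics sit on the boundary
    if (sum(pos) < 10) return(NA_real_)
    pp <- stats::pchisq(st[pos], 1, lower.tail = FALSE)
    pi0p <- suppressWarnings(estimatePi0(pp, nBootSe = 0L)@pi0)
    mean(pos) * (1 - pi0p)
  }
  frac <- .zifrac(statLR)
  se <- NA_real_
  if (!is.na(frac) && nBootSe >= 2) {
    st0 <- statLR[!is.na(statLR)]
    se <- .withSeed(seed, {
      reps <- vapply(seq_len(nBootSe), function(b)
        .zifrac(sample(st0, length(st0), replace = TRUE)), numeric(1))
      stats::sd(reps, na.rm = TRUE)
    })
  }
  list(table = tab, fraction = frac, fractionSe = se,
       nTestable = sum(!is.na(statLR)),
       zeroFreeProportion = zeroFreeProportion(object))
}
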