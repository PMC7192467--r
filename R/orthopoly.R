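# Orthonormal h-functions of the smooth embedding: per sample, polynomials
# (plus a digamma direction spanning the dispersion score) that are
# orthonormal under the fitted NB and orthogonal to the nuisance scores.

#' Inner product under a negative binomial distribution
#'
#' \eqn{\langle f_1, f_2 \rangle = \sum_{y=0}^{Q} f_1(y) f_2(y) f(y;\mu,\phi)}
#' with truncation point Q at the 1 - 1e-12 quantile, extended until the
#' remaining terms are negligible so that polynomial integrands up to
#' degree 12 are resolved to high relative accuracy.
#'
#' @param f1,f2 vectorised functions of the count y.
#' @param mu,phi NB parameters.
#' @return The inner product (a scalar).
#' @examples
#' nbInnerProduct(function(y) y, function(y) 1, mu = 3, phi = 0.5)  # = 3
#' @export
nbInnerProduct <- function(f1, f2, mu, phi) {
  if (mu <= 0 || phi <= 0) stop("'mu' and 'phi' must be positive")
  Q <- stats::qnbinom(1 - 1e-12, size = 1 / phi, mu = mu)
  if (!is.finite(Q) || Q > 1e7)
    stop("truncation support exceeds the hard cap; consider rescaling or filtering extreme dispersion")
  # extend past Q until the weight is negligible for degree-12 integrands
  ext <- Q
  repeat {
    ext <- ceiling(ext * 1.5) + 50
    if (stats::dnbinom(ext, size = 1 / phi, mu = mu) *
        max(1, abs((ext - mu)))^12 < 1e-18 || ext > 1e7) break
  }
  y <- 0:min(ext, 1e7)
  w <- stats::dnbinom(y, size = 1 / phi, mu = mu)
  v <- f1(y) * f2(y) * w
  if (any(!is.finite(v)))
    stop("overflow in integrand evaluation; rescale the functions")
  sum(v)
}

#' Build the orthonormal basis of the smooth test
#'
#' For each sample, candidate monomials in the standardised count are
#' orthogonalised (Gram-Schmidt in a function space that also contains the
#' nuisance score functions) against the constant, the span of the beta
#' scores and the dispersion score, and previously accepted components,
#' then normalised, all under the fitted NB at that sample's
#' \eqn{(\hat\mu_i, \hat\phi)}.  Since the dispersion score contains
#' \eqn{\psi(y + 1/\phi)}, retained components may carry a digamma term.
#' Candidates whose post-projection squared norm falls below 1e-10 times
#' the pre-projection norm are degenerate and dropped; the retained set
#' (aligned across samples) has at most \code{J} components with monomial
#' degrees between 2 and J + 2.
#'
#' Inner products among polynomial terms use exact NB central moments (a
#' stable positive-coefficient recursion); only products involving the
#' digamma direction are computed by truncated summation.
#'
#' @param fit a converged \linkS4class{NBFit}.
#' @param x 0/1 group codes (stored for downstream symmetry checks).
#' @param J order of the smooth test (number of components; default 4).
#' @return An \linkS4class{OrthonormalBasis}.
#' @export
buildBasis <- function(fit, x, J = 4L) {
  if (!methods::is(fit, "NBFit")) stop("'fit' must be an NBFit")
  if (!fit@converged) stop("basis requires a converged fit")
  J <- as.integer(J)
  if (J < 1L) stop("J must be >= 1")
  raw <- .buildBasisCpp(fit@mu, fit@phi, J)
  # global retained degrees: those accepted in every sample, first J
  degTab <- table(unlist(raw$degrees))
  n <- length(fit@mu)
  degrees <- as.integer(names(degTab)[degTab == n])
  degrees <- sort(degrees)[seq_len(min(J, length(degrees)))]
  coefs <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- match(degrees, raw$degrees[[i]])
    coefs[[i]] <- raw$coefs[[i]][, keep, drop = FALSE]
  }
  methods::new("OrthonormalBasis", order = J, coefs = coefs,
               degrees = degrees, sigma = raw$sigma, mu = fit@mu,
               phi = fit@phi, group = as.numeric(x))
}

#' @rdname retainedComponents
#' @export
setMethod("retainedComponents", "OrthonormalBasis", function(object) object@degrees)

#' @rdname retainedComponents
#' @export
setMethod("basisOrder", "OrthonormalBasis", function(object) object@order)

# raw function values [1, t, g2, t^2..t^(J+2)] for one sample at counts y;
# g2 is the digamma direction with its affine bulk removed (matches the
# compiled construction): g2(y) = digamma(y+a) - digamma(a) - trigamma(a) y
.rawBasisValues <- function(y, mu, phi, sigma, J) {
  t <- (y - mu) / sigma
  m <- J + 4L
  a <- 1 / phi
  out <- matrix(0, length(y), m)
  out[, 1] <- 1
  out[, 2] <- t
  out[, 3] <- digamma(y + a) - digamma(a) - trigamma(a) * y
  tp <- t
  for (j in 4:m) {
    tp <- tp * t
    out[, j] <- tp
  }
  out
}

#' Evaluate the basis at observed counts
#'
#' Returns the matrix \eqn{H[i,k] = h_k(y_i; \hat\mu_i, \hat\phi)} whose
#' standardised column sums are the smooth-test components.  Counts beyond
#' the truncation support are evaluated anyway (the h-functions are global)
#' with a warning.
#'
#' @param basis an \linkS4class{OrthonormalBasis}.
#' @param y counts, one per sample.
#' @return numeric matrix, samples x retained components.
#' @export
evaluateBasis <- function(basis, y) {
  n <- length(basis@mu)
  if (length(y) != n) stop("'y' must have one count per sample")
  K <- length(basis@degrees)
  H <- matrix(0, n, K)
  Qmax <- stats::qnbinom(1 - 1e-12, size = 1 / basis@phi, mu = max(basis@mu))
  if (any(y > Qmax))
    warning("counts beyond the truncation support; h-functions evaluated globally")
  for (i in seq_len(n)) {
    raw <- .rawBasisValues(y[i], basis@mu[i], basis@phi, basis@sigma[i], basis@order)
    H[i, ] <- drop(raw %*% basis@coefs[[i]])
  }
  colnames(H) <- paste0("h", basis@degrees)
  H
}

setMethod("show", "OrthonormalBasis", function(object) {
  cat("OrthonormalBasis: J =", object@order,
      " retained degrees:", paste(object@degrees, collapse = ", "), "\n")
  cat("  ", length(object@mu), "samples, phi =",
      format(object@phi, digits = 4), "\n")
  if (length(object@degrees) < object@order)
    cat("  NOTE:", object@order - length(object@degrees),
        "component(s) degenerate and dropped; df =", length(object@degrees), "\n")
})
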