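# Shared fixtures, all generated in code.

# one simulated feature under the two-group NB regression
makeFeature <- function(n = 50, beta1 = -9, beta2 = 2, phi = 1, seed = 1,
                        offsetMean = 9.21, offsetSd = 1.15) {
  set.seed(seed)
  x <- rep(0:1, each = n / 2)
  off <- rnorm(n, offsetMean, offsetSd)
  mu <- exp(off + beta1 + beta2 * x)
  y <- rpois(n, rgamma(n, shape = 1 / phi, scale = phi * mu))
  list(y = y, x = x, off = off, mu = mu, phi = phi)
}

# small count matrix with metadata for container-level tests
makeCountSet <- function(p = 8, n = 10, seed = 1, mu = 5) {
  set.seed(seed)
  counts <- matrix(rpois(p * n, mu), p, n,
                   dimnames = list(paste0("f", seq_len(p)),
                                   paste0("s", seq_len(n))))
  NBCountSet(counts, group = rep(c("a", "b"), each = n / 2))
}

# an NBFit at chosen (mu, phi) without fitting, for basis-level checks
dummyFit <- function(mu, phi, n = length(mu)) {
  if (length(mu) == 1) mu <- rep(mu, n)
  methods::new("NBFit", beta = c(0, 0), phi = phi, mu = mu,
               loglik = 0, converged = TRUE, nIter = 1L,
               scoreNorm = 0, atBound = 0L)
}

# brute-force truncated NB expectation oracle (independent of the C++
# path); the support is extended well past the extreme quantile so that
# even twelfth-degree integrands are resolved
nbExpect <- function(f, mu, phi, tail = 1e-14) {
  Q <- qnbinom(1 - tail, size = 1 / phi, mu = mu)
  y <- 0:max(4 * Q + 1000, 400)
  sum(f(y) * dnbinom(y, size = 1 / phi, mu = mu))
}
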