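test_that("nbInnerProduct reproduces moments of the fitted NB", {
  expect_equal(nbInnerProduct(function(y) rep(1, length(y)),
                              function(y) rep(1, length(y)), 2, 0.5), 1)
  expect_equal(nbInnerProduct(function(y) y, function(y) rep(1, length(y)),
                              3, 0.5), 3, tolerance = 1e-10)
  # second raw moment = variance + mean^2 = 110 + 100
  expect_equal(nbInnerProduct(function(y) y^2, function(y) rep(1, length(y)),
                              10, 1), 210, tolerance = 1e-8)
})

test_that("exact central moments agree with brute-force summation", {
  for (mu in c(0.4, 7, 60)) for (phi in c(0.05, 1, 8)) {
    mom <- smoothNB:::.nbCentralMomentsCpp(mu, phi, 8)
    brute <- vapply(0:8, function(k) nbExpect(function(y) (y - mu)^k, mu, phi),
                    numeric(1))
    expect_equal(mom[-2], brute[-2], tolerance = 1e-7)
  }
})

test_that("basis is orthonormal and score-orthogonal on a parameter grid", {
  grid <- expand.grid(mu = c(0.3, 1.5, 8, 40, 150),
                      phi = c(0.25, 2))
  for (i in seq_len(nrow(grid))) {
    mu <- grid$mu[i]; phi <- grid$phi[i]
    fit <- dummyFit(mu, phi, n = 1)
    b <- buildBasis(fit, x = 0, J = 4)
    K <- length(retainedComponents(b))
    expect_gte(K, 3)
    hAll <- function(y)
      smoothNB:::.rawBasisValues(y, mu, phi, b@sigma[1], 4L) %*% b@coefs[[1]]
    hfun <- function(k) function(y) hAll(y)[, k]
    # unit function, orthonormality (Gram = identity)
    one <- function(y) rep(1, length(y))
    for (k in seq_len(K)) {
      expect_lt(abs(nbInnerProduct(hfun(k), one, mu, phi)), 1e-8)
      for (l in seq_len(K)) {
        g <- nbInnerProduct(hfun(k), hfun(l), mu, phi)
        expect_lt(abs(g - as.numeric(k == l)), 1e-8)
      }
    }
    # orthogonality to the nuisance scores
    sBeta <- function(y) (y - mu) / (1 + phi * mu)
    sPhi <- function(y) {
      (log1p(phi * mu) + digamma(1 / phi) - digamma(y + 1 / phi)) / phi^2 +
        (y - mu) / (phi * (1 + phi * mu))
    }
    for (k in seq_len(K)) {
      expect_lt(abs(nbInnerProduct(hfun(k), sBeta, mu, phi)), 1e-8)
      expect_lt(abs(nbInnerProduct(hfun(k), sPhi, mu, phi)), 1e-8)
    }
  }
})

test_that("evaluateBasis components are mean-zero unit-variance under the model", {
  set.seed(5)
  mu <- 6; phi <- 0.8
  fit <- dummyFit(mu, phi, n = 1)
  b <- buildBasis(fit, x = 0, J = 4)
  y <- rnbinom(1e5, size = 1 / phi, mu = mu)
  H <- t(smoothNB:::.rawBasisValues(y, mu, phi, b@sigma[1], 4L) %*% b@coefs[[1]])
  m <- rowMeans(H); v <- apply(H, 1, var)
  expect_true(all(abs(m) < 4 / sqrt(1e5) * 1.5))
  # unit variance checked by Monte Carlo only for the low components:
  # the variance of the higher ones is carried by rare tail counts that a
  # finite sample systematically under-represents (the deterministic Gram
  # identity above is the exact check)
  seV <- sqrt(pmax(rowMeans(H^4) - 1, 0) / 1e5)
  expect_true(all(abs(v[1:2] - 1) < 5 * seV[1:2]))
})

test_that("basis construction is deterministic and degree-bounded", {
  f <- makeFeature(seed = 19)
  fit <- fitNB(f$y, f$x, f$off)
  b1 <- buildBasis(fit, f$x, J = 4)
  b2 <- buildBasis(fit, f$x, J = 4)
  expect_identical(b1@coefs, b2@coefs)
  # retained component k has monomial degree <= k + 2
  degs <- retainedComponents(b1)
  expect_true(all(degs <= seq_along(degs) + 2))
  # evaluation reproduces direct polynomial arithmetic
  y0 <- round(fit@mu[1])
  raw <- smoothNB:::.rawBasisValues(y0, fit@mu[1], fit@phi, b1@sigma[1], 4L)
  expect_equal(evaluateBasis(b1, c(y0, round(fit@mu[-1])))[1, ],
               drop(raw %*% b1@coefs[[1]]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("third-moment tilting moves the degree-3 component most", {
  mu <- 5; phi <- 0.5
  fit <- dummyFit(mu, phi, n = 1)
  b <- buildBasis(fit, x = 0, J = 4)
  # exponentially tilt the NB in the standardised third power
  Q <- qnbinom(1 - 1e-13, size = 1 / phi, mu = mu)
  y <- 0:(Q + 100)
  f0 <- dnbinom(y, size = 1 / phi, mu = mu)
  t <- (y - mu) / sqrt(nbVariance(mu, phi))
  w <- f0 * exp(0.05 * pmin(pmax(t^3, -5), 5))   # clipped tilt, renormalised
  w <- w / sum(w)
  H <- t(smoothNB:::.rawBasisValues(y, mu, phi, b@sigma[1], 4L) %*% b@coefs[[1]])
  drift <- abs(H %*% w)
  degs <- retainedComponents(b)
  expect_gt(drift[degs == 3], drift[degs == 2])
  expect_gt(drift[degs == 3], drift[degs == 4])
})
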