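test_that("nbLogPmf matches closed forms and normalises", {
  # y = 0 closed form
  for (mu in c(0.5, 3)) for (phi in c(0.2, 2)) {
    expect_equal(nbLogPmf(0, mu, phi), -log1p(mu * phi) / phi)
  }
  # hand evaluation at y=1, mu=1, phi=1: Gamma(2)/1!Gamma(1) * (1/2)(1/2)
  expect_equal(nbLogPmf(1, 1, 1), log(0.25))
  # normalisation over the truncated support
  for (mu in c(1, 100)) for (phi in c(0.1, 1, 5)) {
    Q <- qnbinom(1 - 1e-12, size = 1 / phi, mu = mu)
    s <- sum(exp(nbLogPmf(0:Q, mu, phi)))
    expect_lt(abs(s - 1), 1e-10)
  }
  expect_error(nbLogPmf(1, -1, 1), "positive")
  expect_error(nbLogPmf(1, 1, 0), "positive")
})

test_that("nbVariance matches the truncated-sum second moment", {
  expect_equal(nbVariance(10, 1), 110)
  expect_equal(nbVariance(2, 0.5), 4)
  for (mu in c(2, 10)) for (phi in c(0.5, 1)) {
    m2 <- nbExpect(function(y) (y - mu)^2, mu, phi)
    expect_equal(nbVariance(mu, phi), m2, tolerance = 1e-9)
  }
  # Poisson limit
  expect_equal(nbVariance(7, 1e-10), 7, tolerance = 1e-8)
})

test_that("scores vanish at the mean and match finite differences", {
  # residual term vanishes when mu_i = y_i exactly (offset = log y, beta = 0)
  y <- c(2, 5, 1, 7)
  off <- log(y)
  sc <- nbScore(y, c(0, 0, 1, 1), off, beta = c(0, 0), phi = 0.7)
  expect_equal(sc$scoreBeta, c(0, 0))

  # central-difference oracle at random parameter points
  set.seed(42)
  for (i in 1:20) {
    n <- 30
    x <- rep(0:1, each = 15)
    off <- rnorm(n, 6, 0.5)
    y <- rpois(n, rgamma(n, 1, scale = exp(off - 5)))
    b <- c(runif(1, -6, -4), runif(1, -1, 1))
    phi <- exp(runif(1, log(0.05), log(5)))
    ll <- function(b1, b2, ph)
      sum(dnbinom(y, size = 1 / ph, mu = exp(off + b1 + b2 * x), log = TRUE))
    h <- 1e-6
    fd <- c((ll(b[1] + h, b[2], phi) - ll(b[1] - h, b[2], phi)) / (2 * h),
            (ll(b[1], b[2] + h, phi) - ll(b[1], b[2] - h, phi)) / (2 * h),
            (ll(b[1], b[2], phi + h * phi) - ll(b[1], b[2], phi - h * phi)) / (2 * h * phi))
    sc <- nbScore(y, x, off, beta = b, phi = phi)
    expect_equal(c(sc$scoreBeta, sc$scorePhi), fd,
                 tolerance = 1e-6 * max(1, max(abs(fd))))
  }
})

test_that("fitNB reaches the first-order condition and agrees with glm.nb", {
  skip_if_not_installed("MASS")
  set.seed(7)
  for (i in 1:8) {
    f <- makeFeature(seed = 100 + i, phi = c(0.3, 1, 3)[1 + i %% 3])
    fit <- fitNB(f$y, f$x, f$off)
    expect_true(fit@converged)
    expect_lt(fit@scoreNorm, 1e-6)
    g <- suppressWarnings(MASS::glm.nb(y ~ x + offset(off),
                                       data = data.frame(y = f$y, x = f$x, off = f$off)))
    expect_equal(unname(coef(fit)), unname(coef(g)), tolerance = 1e-4)
    expect_equal(fit@phi, 1 / g$theta, tolerance = 1e-3)
    expect_equal(logLik(fit), as.numeric(logLik(g)), tolerance = 1e-6)
  }
})

test_that("fitNB is invariant to sample permutation and group relabelling", {
  f <- makeFeature(seed = 11)
  fit <- fitNB(f$y, f$x, f$off)
  p <- sample(length(f$y))
  fitP <- fitNB(f$y[p], f$x[p], f$off[p])
  expect_equal(coef(fitP), coef(fit), tolerance = 1e-7)
  fitR <- fitNB(f$y, 1 - f$x, f$off)
  expect_equal(unname(coef(fitR)[2]), -unname(coef(fit)[2]), tolerance = 1e-6)
  expect_equal(logLik(fitR), logLik(fit), tolerance = 1e-9)
})

test_that("fitNB handles symmetric and degenerate inputs", {
  # constant counts, equal groups, equal offsets: no group effect
  y <- rep(5L, 20)
  x <- rep(0:1, each = 10)
  fit <- fitNB(y, x, rep(0, 20))
  expect_lt(abs(coef(fit)[2]), 1e-6)
  expect_error(fitNB(rep(0L, 20), x, rep(0, 20)), "all counts are zero")
})

test_that("the optimum dominates a local parameter grid", {
  f <- makeFeature(seed = 13)
  fit <- fitNB(f$y, f$x, f$off)
  ll <- function(b1, b2, ph)
    sum(dnbinom(f$y, size = 1 / ph, mu = exp(f$off + b1 + b2 * f$x), log = TRUE))
  b <- coef(fit)
  for (d1 in c(-0.05, 0, 0.05)) for (d2 in c(-0.05, 0, 0.05))
    for (dp in c(0.9, 1, 1.1)) {
      expect_lte(ll(b[1] + d1, b[2] + d2, fit@phi * dp), logLik(fit) + 1e-8)
    }
})

test_that("fitNB is consistent at large n", {
  set.seed(17)
  n <- 10000
  x <- rep(0:1, each = n / 2)
  off <- rnorm(n, 9.21, 1.15)
  mu <- exp(off - 9 + 2 * x)
  y <- rpois(n, rgamma(n, 1, scale = mu))
  fit <- fitNB(y, x, off)
  # within ~3 Monte-Carlo standard errors of the truth
  expect_lt(abs(coef(fit)[1] - (-9)), 0.1)
  expect_lt(abs(coef(fit)[2] - 2), 0.1)
  expect_lt(abs(fit@phi - 1), 0.1)
})
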