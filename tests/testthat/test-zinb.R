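test_that("ZINB fitting recovers boundary and interior inflation", {
  # plain-NB data: structural-zero probability near 0
  set.seed(71)
  pis <- rep(NA_real_, 60)
  for (i in 1:60) {
    f <- makeFeature(seed = 700 + i, beta1 = -7)
    if (!any(f$y == 0)) next
    zi <- fitZINB(f$y, f$x, f$off)
    if (zi@fittable && zi@converged) pis[i] <- zi@piZero
  }
  expect_lt(median(pis, na.rm = TRUE), 0.02)

  # pi = 0.3 structural zeros, large n: recovered within 0.03
  set.seed(72)
  n <- 10000
  x <- rep(0:1, each = n / 2)
  off <- rep(log(5000), n)
  mu <- exp(off - 7 + 2 * x)
  y <- rpois(n, rgamma(n, 1, scale = mu))
  y[runif(n) < 0.3] <- 0L
  zi <- fitZINB(y, x, off)
  expect_true(zi@converged)
  expect_lt(abs(zi@piZero - 0.3), 0.03)
})

test_that("features without zeros are flagged unfittable without crashing", {
  y <- rpois(20, 50) + 1L
  x <- rep(0:1, each = 10)
  zi <- fitZINB(y, x, rep(0, 20))
  expect_false(zi@fittable)
  lr <- lrTestZINB(dummyFit(5, 1, 20), zi)
  expect_true(is.na(lr@p))
})

test_that("the ZINB nests the NB in likelihood", {
  for (i in 1:25) {
    f <- makeFeature(seed = 800 + i, beta1 = c(-9, -7)[1 + i %% 2],
                     phi = c(0.5, 2)[1 + i %% 2])
    if (!any(f$y == 0) || sum(f$y) == 0) next
    nb <- fitNB(f$y, f$x, f$off)
    if (!nb@converged) next
    zi <- fitZINB(f$y, f$x, f$off, nbFit = nb)
    if (!zi@fittable || !zi@converged) next
    expect_gte(zi@loglik, nb@loglik - 1e-6)
  }
})

test_that("LR p-values follow the boundary-mixture convention", {
  nb <- dummyFit(5, 1); nb@loglik <- -100
  zi <- methods::new("ZINBFit", beta = c(0, 0), phi = 1, piZero = 0.1,
                     mu = rep(5, 10), loglik = -100, converged = TRUE,
                     fittable = TRUE)
  r0 <- lrTestZINB(nb, zi)
  expect_equal(r0@statistic, 0)
  expect_equal(r0@p, 1)
  zi@loglik <- -100 + 2.706 / 2
  r1 <- lrTestZINB(nb, zi)
  expect_equal(r1@statistic, 2.706)
  expect_equal(r1@p, 0.05, tolerance = 1e-3)
  # plain chi-square-1 convention for comparison
  r1c <- lrTestZINB(nb, zi, convention = "chisq1")
  expect_equal(r1c@p, 2 * r1@p, tolerance = 1e-10)
  # monotone decreasing in the statistic
  zi@loglik <- -95
  expect_lt(lrTestZINB(nb, zi)@p, r1@p)
})

test_that("LR statistic is invariant to group relabelling", {
  f <- makeFeature(seed = 81, beta1 = -7)
  nb <- fitNB(f$y, f$x, f$off)
  zi <- fitZINB(f$y, f$x, f$off, nbFit = nb)
  nbR <- fitNB(f$y, 1 - f$x, f$off)
  ziR <- fitZINB(f$y, 1 - f$x, f$off, nbFit = nbR)
  expect_equal(lrTestZINB(nb, zi)@statistic,
               lrTestZINB(nbR, ziR)@statistic, tolerance = 1e-4)
})

test_that("the screen is null-calibrated and guards all-positive matrices", {
  # NB-simulated matrix at moderate abundance: near-nominal LR size and a
  # zero-inflated fraction within noise of zero
  sim <- simulateDataset(simulationConfig(
    nFeatures = 150, baselineLow = -9.21, baselineHigh = -4.61, seed = 73))
  zs <- zinbScreen(countSet(sim), seed = 2)
  pv <- zs$table$p
  expect_lt(mean(pv < 0.05, na.rm = TRUE), 0.12)
  expect_lt(zs$fraction, 0.05 + 2 * zs$fractionSe + 0.02)

  # all-positive matrix: nothing fittable, fraction NA, proportion reported
  cntAllPos <- matrix(rpois(200, 60) + 1L, 10, 20,
                      dimnames = list(paste0("f", 1:10), paste0("s", 1:20)))
  csAP <- NBCountSet(cntAllPos, group = rep(c("a", "b"), each = 10))
  zsAP <- zinbScreen(csAP)
  expect_true(all(!zsAP$table$fittable))
  expect_true(is.na(zsAP$fraction))
  expect_equal(zsAP$zeroFreeProportion, 1)
})
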