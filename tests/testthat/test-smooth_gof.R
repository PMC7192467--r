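test_that("components and statistic follow their defining arithmetic", {
  expect_equal(computeComponents(matrix(0, 5, 3)), c(0, 0, 0))
  expect_equal(computeComponents(matrix(2, 1, 1)), 2)
  H <- matrix(c(1, 2, 3, 0), 4, 1)
  expect_equal(computeComponents(H), 3)

  expect_equal(smoothStatistic(c(0, 0))$statistic, 0)
  st <- smoothStatistic(c(1, -1, 2))
  expect_equal(st$statistic, 6)
  expect_equal(st$df, 3L)
  expect_false(st$untestable)
  empty <- smoothStatistic(numeric(0))
  expect_true(empty$untestable)
  expect_equal(empty$df, 0L)
})

test_that("asymptotic p-values are chi-square upper tails, monotone", {
  expect_equal(asymptoticPvalue(0, 4), 1)
  expect_equal(asymptoticPvalue(3.841459, 1), 0.05, tolerance = 1e-6)
  Ts <- seq(0, 30, by = 0.5)
  p <- asymptoticPvalue(Ts, 4)
  expect_true(all(diff(p) < 0))
  expect_lt(asymptoticPvalue(1e4, 4), 1e-12)
  expect_error(asymptoticPvalue(1, 0), "df")
})

test_that("the statistic decomposes into squared components and is label-symmetric", {
  f <- makeFeature(seed = 23)
  fit <- fitNB(f$y, f$x, f$off)
  st <- smoothNB:::.gofStatCpp(f$y, fit@mu, fit@phi, 4L)
  expect_equal(st$statistic, sum(st$components^2), tolerance = 1e-10)
  expect_equal(st$df, length(st$components))
  # agreement with the R-level basis route
  b <- buildBasis(fit, f$x, J = 4)
  H <- evaluateBasis(b, f$y)
  V <- computeComponents(H)
  expect_equal(unname(V), st$components, tolerance = 1e-8)
  # relabelling the groups leaves T unchanged (same fitted means)
  fitR <- fitNB(f$y, 1 - f$x, f$off)
  stR <- smoothNB:::.gofStatCpp(f$y, fitR@mu, fitR@phi, 4L)
  expect_equal(stR$statistic, st$statistic, tolerance = 1e-6)
})

test_that("under the null the statistic has the chi-square moments", {
  # large n, fixed true parameters, basis held at the truth
  set.seed(31)
  mu <- 4; phi <- 0.6; n <- 2000; reps <- 400
  b <- buildBasis(dummyFit(mu, phi, n = 1), x = 0, J = 4)
  C <- b@coefs[[1]]
  Tv <- replicate(reps, {
    y <- rnbinom(n, size = 1 / phi, mu = mu)
    H <- smoothNB:::.rawBasisValues(y, mu, phi, b@sigma[1], 4L) %*% C
    sum(colSums(H)^2) / n
  })
  df <- length(b@degrees)
  # E T = df within Monte-Carlo error (sd(T) ~ sqrt(2 df))
  expect_lt(abs(mean(Tv) - df), 4 * sqrt(2 * df / reps) + 0.15)
})

test_that("bootstrap p-values respect the (1+m)/(B+1) convention", {
  f <- makeFeature(seed = 29)
  fit <- fitNB(f$y, f$x, f$off)
  B <- 39
  r <- bootstrapPvalue(f$y, f$x, f$off, fit, J = 4, B = B, seed = 3,
                       returnStatistics = TRUE)
  expect_true(r@pBootstrap %in% ((1:(B + 1)) / (B + 1)))
  Tstar <- attr(r, "Tstar")
  expect_length(Tstar, B)
  expect_equal(r@pBootstrap, (1 + sum(Tstar >= r@statistic)) / (B + 1))
  # reproducible under the same seed
  r2 <- bootstrapPvalue(f$y, f$x, f$off, fit, J = 4, B = B, seed = 3)
  expect_equal(r2@pBootstrap, r@pBootstrap)
})

test_that("gofTest isolates degenerate features and is order-invariant", {
  sim <- simulateDataset(simulationConfig(nFeatures = 12, nSamples = 30, seed = 77))
  cs <- countSet(sim)
  cnt <- counts(cs)
  cnt[3, ] <- 0L
  cs0 <- NBCountSet(cnt, data.frame(sample_id = colnames(cnt),
                                    group = as.character(groupFactor(cs)),
                                    library_size = libSizes(cs)))
  res <- gofTest(cs0, B = 19, seed = 9)
  expect_true(res$skipped[3])
  expect_match(res$reason[3], "all counts zero")
  expect_true(all(!res$skipped[c(1, 2, 4)] | !is.na(res$phiHat[c(1, 2, 4)])))
  # identical rerun
  res2 <- gofTest(cs0, B = 19, seed = 9)
  expect_identical(as.data.frame(res), as.data.frame(res2))
  # feature-order invariance: substreams are keyed on feature identity
  perm <- c(5, 1, 2, 3, 4, 6:12)
  csP <- cs0[perm, ]
  resP <- gofTest(csP, B = 19, seed = 9)
  expect_equal(as.data.frame(resP[rownames(cs0), ]), as.data.frame(res))
})

test_that("features above the dispersion cutoff are skipped but keep their fit", {
  sim <- simulateDataset(simulationConfig(nFeatures = 30, phi = 30, seed = 55))
  res <- gofTest(countSet(sim), B = 19, maxPhi = 10, seed = 4)
  hi <- which(!is.na(res$phiHat) & res$phiHat >= 10)
  expect_gt(length(hi), 0)
  expect_true(all(res$skipped[hi]))
  expect_true(all(is.na(res$pBootstrap[hi])))
  expect_true(all(!is.na(res$phiHat[hi])))
})
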