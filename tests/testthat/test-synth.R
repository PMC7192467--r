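test_that("the default design matches the reference simulation layout", {
  cfg <- simulationConfig()
  expect_equal(cfg@nFeatures, 500L)
  expect_equal(cfg@nSamples, 50L)
  expect_equal(cfg@offsetMean, 9.21)
  expect_equal(cfg@offsetSd, 1.15)
  expect_equal(c(cfg@baselineLow, cfg@baselineHigh), c(-13.8, -6.91))
  expect_equal(cfg@beta2, 2)
  sim <- simulateDataset(simulationConfig(seed = 1))
  expect_equal(dim(counts(countSet(sim))), c(500L, 50L))
  expect_equal(unname(table(groupFactor(countSet(sim)))), c(25L, 25L),
               ignore_attr = TRUE)
})

test_that("config validation rejects impossible settings", {
  expect_error(simulationConfig(nSamples = 51), "even")
  expect_error(simulationConfig(phi = 0), "positive")
  expect_error(simulationConfig(misfit = "bogus"), "misfit")
  expect_error(simulationConfig(baselineLow = -5, baselineHigh = -6), "empty")
})

test_that("simulation is bit-reproducible and consistent with its truth", {
  cfg <- simulationConfig(nFeatures = 40, nSamples = 20, seed = 123)
  s1 <- simulateDataset(cfg)
  s2 <- simulateDataset(cfg)
  expect_identical(counts(countSet(s1)), counts(countSet(s2)))
  expect_identical(as.data.frame(simTruth(s1)), as.data.frame(simTruth(s2)))
  # library sizes are the generating depths
  expect_equal(unname(computeOffsets(countSet(s1))),
               SummarizedExperiment::colData(countSet(s1))$beta0,
               tolerance = 1e-12)
})

test_that("the Poisson limit and moment recovery hold", {
  # near-constant offsets so the within-group means are homogeneous and
  # the variance/mean ratio reflects the count distribution alone
  sim <- simulateDataset(simulationConfig(nFeatures = 200, phi = 1e-6,
                                          offsetSd = 0.01,
                                          baselineLow = -8, baselineHigh = -6,
                                          seed = 7))
  cnt <- counts(countSet(sim))
  # per-feature variance/mean ratio near 1 for high-count features,
  # computed within group to avoid the group effect
  g <- groupCodes(countSet(sim)) == 1
  m <- rowMeans(cnt[, g]); v <- apply(cnt[, g], 1, var)
  hi <- m > 20
  expect_gt(sum(hi), 10)
  # per-feature ratios are noisy at 25 samples; the ensemble centres on 1
  ratios <- v[hi] / m[hi]
  expect_gt(median(ratios), 0.8)
  expect_lt(median(ratios), 1.25)
  expect_lt(abs(mean(ratios) - 1), 0.1)

  # phi = 1: method-of-moments dispersion across features centred near 1
  sim2 <- simulateDataset(simulationConfig(nFeatures = 300, phi = 1,
                                           offsetSd = 0.01, baselineLow = -8,
                                           baselineHigh = -6, seed = 8))
  cnt2 <- counts(countSet(sim2))
  g2 <- groupCodes(countSet(sim2)) == 1
  m2 <- rowMeans(cnt2[, g2]); v2 <- apply(cnt2[, g2], 1, var)
  phiMom <- (v2 - m2) / m2^2
  expect_lt(abs(median(phiMom[m2 > 5]) - 1), 0.25)
})

test_that("misfit variants flag the configured fraction and perturb counts", {
  cfg <- simulationConfig(nFeatures = 40, nSamples = 20,
                          misfit = "zero_inflation", misfitProb = 0.5,
                          misfitFraction = 0.5, baselineLow = -7,
                          baselineHigh = -6, seed = 9)
  sim <- simulateDataset(cfg)
  tr <- simTruth(sim)
  expect_equal(sum(tr$misfit), 20)
  cnt <- counts(countSet(sim))
  # inflated features carry visibly more zeros
  expect_gt(mean(cnt[tr$misfit, ] == 0), mean(cnt[!tr$misfit, ] == 0) + 0.2)
})

test_that("the dispersion estimator study reproduces known sampling behaviour", {
  st <- dispersionSamplingStudy(phiGrid = c(0.01, 1), reps = 500, seed = 3)
  expect_equal(nrow(st), 2)
  # phi = 1: near-unbiased in the median (the population median bias at
  # n = 50 is just under 5%; allow the Monte-Carlo error of its estimate)
  seMed <- 1.253 * st$sd[st$phi == 1] / sqrt(st$nFits[st$phi == 1])
  expect_lt(abs(st$relMedianBias[st$phi == 1]), 0.05 + 2 * seMed)
  # phi = 0.01: visibly biased and right-skewed
  expect_gt(abs(st$relMedianBias[st$phi == 0.01]), 0.05)
  expect_gt(st$skewness[st$phi == 0.01], 0.5)
})
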