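test_that("random allocation is seeded, balanced on average, and guarded", {
  a1 <- randomAllocation(20, seed = 5)
  a2 <- randomAllocation(20, seed = 5)
  expect_identical(a1, a2)
  set.seed(9)
  fr <- replicate(10000, mean(randomAllocation(10)))
  expect_lt(abs(mean(fr) - 0.5), 0.02)
  expect_error(randomAllocation(3), "at least 4")
  # redrawn allocations always leave >= 2 per group
  for (i in 1:50) {
    a <- randomAllocation(6, seed = i)
    expect_gte(min(sum(a), 6 - sum(a)), 2)
  }
})

test_that("single-stratum Prentice equals the Wilcoxon normal approximation", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(10:30, 1)
    g <- rbinom(n, 1, 0.5)
    if (min(sum(g), n - sum(g)) < 2) next
    y <- rpois(n, 5) + round(runif(n), 1)     # some ties
    pP <- as.numeric(prenticeRankTest(y, g))
    w <- suppressWarnings(wilcox.test(y[g == 1], y[g == 0],
                                      exact = FALSE, correct = FALSE))
    expect_equal(pP, w$p.value, tolerance = 1e-10)
  }
})

test_that("Prentice handles ties, degenerate strata and monotone transforms", {
  # constant response: statistic 0 under the tie correction
  y <- rep(3, 16)
  g <- rep(0:1, 8)
  expect_equal(as.numeric(prenticeRankTest(y, g)), 1)
  # strata missing a group label are dropped
  set.seed(92)
  y <- rpois(20, 10)
  g <- c(rep(0:1, 8), rep(1L, 4))
  s <- rep(c("a", "b"), c(16, 4))
  p <- prenticeRankTest(y, g, s)
  expect_equal(attr(p, "droppedStrata"), 1L)
  # rank-based: invariant to strictly monotone transforms
  set.seed(93)
  y <- rgamma(24, 2, 1)
  g <- rep(0:1, 12)
  s <- rep(c("a", "b"), each = 12)
  p1 <- as.numeric(prenticeRankTest(y, g, s))
  p2 <- as.numeric(prenticeRankTest(log(y + 1), g, s))
  p3 <- as.numeric(prenticeRankTest(rank(y), g, s))
  expect_equal(p1, p2)
  expect_equal(p1, p3)
})

test_that("Prentice controls the type-I error on null NB data", {
  set.seed(94)
  hits <- 0; total <- 0
  for (i in 1:400) {
    f <- makeFeature(seed = 900 + i, beta1 = -8)
    rg <- randomAllocation(length(f$y))
    p <- as.numeric(prenticeRankTest(f$y, rg, strata = f$x))
    hits <- hits + (p < 0.1); total <- total + 1
  }
  expect_lt(abs(hits / total - 0.1), 3 * sqrt(0.1 * 0.9 / total) + 0.01)
})

test_that("the Wald test flags collinearity and detects real effects", {
  f <- makeFeature(seed = 95)
  expect_warning(pw <- waldTestRandomGroup(f$y, f$off, f$x, f$x), "collinear")
  expect_true(is.na(pw))
  # injected effect on the random grouping variable
  set.seed(96)
  ps <- vapply(1:30, function(i) {
    n <- 50
    orig <- rep(0:1, each = 25)
    rg <- randomAllocation(n, seed = 960 + i)
    off <- rnorm(n, 9.21, 1.15)
    mu <- exp(off - 9 + 1 * orig + 2 * rg)
    y <- rpois(n, rgamma(n, 1, scale = mu))
    suppressWarnings(waldTestRandomGroup(y, off, orig, rg))
  }, numeric(1))
  expect_lt(median(ps, na.rm = TRUE), 0.001)
})

test_that("Wald p-values are approximately uniform under random labels", {
  set.seed(97)
  ps <- rep(NA_real_, 150)
  for (i in 1:150) {
    f <- makeFeature(seed = 1100 + i, beta1 = -8, phi = 0.8)
    rg <- randomAllocation(length(f$y))
    ps[i] <- suppressWarnings(waldTestRandomGroup(f$y, f$off, f$x, rg))
  }
  ps <- ps[!is.na(ps)]
  # no gross departure from uniformity (the Wald test is mildly
  # anticonservative at n = 50, so test at a strict KS level)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 1e-4)
})

test_that("the mock study runs end-to-end and tabulates complete results", {
  sim <- simulateDataset(simulationConfig(nFeatures = 15, nSamples = 30, seed = 98))
  cs <- countSet(sim)
  gof <- gofTest(cs, B = 19, seed = 1)
  mk <- runMockStudy(cs, gof, nReps = 1, seed = 2)
  expect_equal(dim(mk@pWald), c(15, 1))
  expect_equal(dim(mk@pPrentice), c(15, 1))
  expect_equal(nrow(mk@proportions), 4)
  expect_true(all(mk@proportions$proportion >= 0 & mk@proportions$proportion <= 1,
                  na.rm = TRUE))
  # every feature with a q-value sits in exactly one fit group
  expect_true(all(table(mk@fitGroup, useNA = "no") >= 0))
  expect_equal(sum(!is.na(mk@fitGroup)) + sum(is.na(mk@fitGroup)), 15)
  # deterministic rerun
  mk2 <- runMockStudy(cs, gof, nReps = 1, seed = 2)
  expect_identical(mk@pWald, mk2@pWald)
})
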