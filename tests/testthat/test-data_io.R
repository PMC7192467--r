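test_that("tsv counts round-trip bit-identically with ids preserved", {
  m <- matrix(0:3, 2, 2, dimnames = list(c("fA", "fB"), c("s1", "s2")))
  tf <- tempfile(fileext = ".tsv")
  writeCounts(m, tf)
  r1 <- readCounts(tf)
  expect_identical(unname(r1), matrix(0:3, 2, 2))
  expect_identical(dimnames(r1), dimnames(m))
  tf2 <- tempfile(fileext = ".tsv")
  writeCounts(r1, tf2)
  expect_identical(readLines(tf), readLines(tf2))
})

test_that("invalid entries are rejected naming the offending cell", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("feature_id\ts1\ts2", "fA\t0\t-1", "fB\t2\t3"), tf)
  expect_error(readCounts(tf), "fA.*s2")
  writeLines(c("feature_id\ts1\ts2", "fA\t0\t1.5", "fB\t2\t3"), tf)
  expect_error(readCounts(tf), "1.5")
  writeLines(c("feature_id\ts1\ts2", "fA\t0\tNA", "fB\t2\t3"), tf)
  expect_error(readCounts(tf), "NA")
  expect_error(readCounts(tempfile()), "not found")
})

test_that("MatrixMarket input converts to dense counts with sidecar ids", {
  tf <- tempfile(fileext = ".mtx")
  Matrix::writeMM(Matrix::Diagonal(3, x = c(1, 2, 3)), tf)
  writeLines(paste0("f", 1:3), paste0(tf, ".rows"))
  writeLines(paste0("s", 1:3), paste0(tf, ".cols"))
  m <- readCounts(tf, format = "mtx")
  expect_identical(unname(m), diag(1:3))
  expect_equal(sum(m == 0), 6)
  expect_identical(rownames(m), paste0("f", 1:3))
})

test_that("offsets are log library sizes and permute with the samples", {
  counts <- matrix(c(4, 6, 60, 40, 3, 7, 30, 20), 2, 4,
                   dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  cs <- NBCountSet(counts, group = c("a", "a", "b", "b"))
  expect_equal(unname(computeOffsets(cs)), log(c(10, 100, 10, 50)))
  # explicit library sizes override column sums
  meta <- data.frame(sample_id = paste0("s", 1:4), group = c("a", "a", "b", "b"),
                     library_size = c(1, exp(2), 10, 10))
  cs2 <- NBCountSet(counts, meta)
  expect_equal(unname(computeOffsets(cs2))[1:2], c(0, 2))
  # permutation equivariance
  p <- c(3, 1, 4, 2)
  expect_equal(computeOffsets(cs)[p], computeOffsets(cs[, p]))
})

test_that("all-zero samples are rejected rather than dropped", {
  counts <- matrix(c(1, 2, 0, 0, 3, 4, 5, 6), 2, 4,
                   dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  expect_error(NBCountSet(counts, group = c("a", "a", "b", "b")),
               "zero library size.*s2")
})

test_that("container validity catches bad designs", {
  counts <- matrix(rpois(12, 3), 3, 4,
                   dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  expect_error(NBCountSet(counts, group = c("a", "b", "c", "a")), "2 observed levels")
  expect_error(NBCountSet(counts + 0.5, group = c("a", "a", "b", "b")),
               "non-negative integers")
  expect_error(NBCountSet(counts, group = c("a", "a", "a", "b")),
               "at least 2 samples")
})

test_that("zeroFreeProportion counts rows without zeros", {
  m1 <- matrix(1:20, 5, 4)
  expect_equal(zeroFreeProportion(m1), 1)
  m2 <- m1; m2[, 2] <- 0
  expect_equal(zeroFreeProportion(m2), 0)
  m3 <- rbind(c(1, 2, 3), c(0, 1, 2), c(3, 0, 1), c(1, 0, 0))
  expect_equal(zeroFreeProportion(m3), 0.25)
  expect_error(zeroFreeProportion(matrix(numeric(0), 0, 3)), "empty")
})

test_that("sample metadata reader joins cleanly with the count matrix", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tgroup\tlibrary_size",
               "s1\tctrl\t100", "s2\tctrl\t200",
               "s3\ttrt\t150", "s4\ttrt\t250"), tf)
  meta <- readSampleMetadata(tf)
  expect_identical(rownames(meta), paste0("s", 1:4))
  counts <- matrix(rpois(8, 5), 2, 4,
                   dimnames = list(c("f1", "f2"), paste0("s", 1:4)))
  cs <- NBCountSet(counts, meta)
  # first observed level is the reference
  expect_identical(levels(groupFactor(cs)), c("ctrl", "trt"))
  expect_equal(unname(groupCodes(cs)), c(0L, 0L, 1L, 1L))
  expect_equal(unname(libSizes(cs)), c(100, 200, 150, 250))
})
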