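test_that("count matrices survive a TSV round trip and reject bad input", {
  m <- randomCounts(3, 2, seed = 1)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(m, f)
  back <- readCountMatrix(f)
  expect_identical(back, m)

  bad <- m
  rownames(bad) <- c("gX", "gX", "gZ")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeCountMatrix(bad, f2)
  expect_error(readCountMatrix(f2), "gX")

  neg <- m
  neg[2, 1] <- -1L
  f3 <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(gene = rownames(neg), neg, check.names = FALSE)
  write.table(df, f3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(readCountMatrix(f3), rownames(neg)[2])
})

test_that("MTX triplet input equals the equivalent TSV", {
  m <- randomCounts(20, 6, seed = 2, lambda = 3)  # sparse-ish
  fT <- withr::local_tempfile(fileext = ".tsv")
  fM <- withr::local_tempfile(fileext = ".mtx")
  writeCountMatrix(m, fT, format = "tsv")
  writeCountMatrix(m, fM, format = "mtx")
  expect_identical(readCountMatrix(fM, format = "mtx"),
                   readCountMatrix(fT, format = "tsv"))
})

test_that("depth filter keeps the inclusive 500k-2M window", {
  totals <- c(400000, 500000, 2000000, 2000001)
  m <- matrix(as.integer(totals), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  kept <- filterSamplesByDepth(m)
  expect_identical(colnames(kept), c("s2", "s3"))

  inside <- matrix(as.integer(c(600000, 1999999)), nrow = 1,
                   dimnames = list("g1", c("a", "b")))
  expect_identical(filterSamplesByDepth(inside), inside)

  tiny <- matrix(1L, 1, 1, dimnames = list("g1", "s1"))
  expect_error(filterSamplesByDepth(tiny), "empty cohort")
})

test_that("depth filter matches a brute-force recount on a wide-range cohort", {
  cfg <- CohortConfig(nPatients = 200, nGenes = 800,
                      nMarkersPerSubtype = 20,
                      nPlantedCrosstalkPerSubtype = 5, nLrPairs = 100,
                      librarySizeRange = c(400000L, 2100000L), seed = 7)
  coh <- generateCohort(cfg)
  m <- tissueCounts(coh, "cartilage")
  totals <- colSums(m)
  expected <- sum(totals >= 5e5 & totals <= 2e6)
  expect_gt(expected, 0)
  expect_lt(expected, ncol(m))  # the wide range exercises the filter
  expect_equal(ncol(filterSamplesByDepth(m)), expected)
})

test_that("CPM normalization is exact, scaled to a million, scale-invariant", {
  m <- matrix(c(1L, 3L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(computeCPM(m)[, 1]), c(250000, 750000))

  m2 <- randomCounts(30, 5, seed = 3)
  expect_equal(unname(colSums(computeCPM(m2))), rep(1e6, 5))

  m3 <- m2
  m3[, 2] <- m3[, 2] * 10L
  expect_equal(computeCPM(m3)[, 2], computeCPM(m2)[, 2])

  z <- m2
  z[, 1] <- 0L
  expect_error(computeCPM(z), colnames(z)[1])
})

test_that("control-variance gene filter follows the log2 variance rule", {
  cpmMat <- matrix(0, 3, 4,
                   dimnames = list(c("const", "spread", "mid"),
                                   c("c1", "c2", "o1", "o2")))
  cpmMat["const", ] <- 100
  cpmMat["spread", c("c1", "c2")] <- c(0, 15)  # log2(CPM+1) = 0 and 4
  cpmMat["mid", c("c1", "c2")] <- c(10, 14)
  out <- filterGenesControlVariance(cpmMat, c("c1", "c2"))
  expect_true("const" %in% rownames(out))   # variance 0 retained
  expect_false("spread" %in% rownames(out)) # variance 8 > 3 removed
  expect_error(filterGenesControlVariance(cpmMat, "c1"), "2 control")

  set.seed(9)
  rnd <- matrix(runif(200 * 6, 0, 40), 200, 6,
                dimnames = list(sprintf("g%03d", 1:200),
                                sprintf("s%d", 1:6)))
  ctrl <- c("s1", "s2", "s3")
  keptOracle <- vapply(seq_len(200), function(i)
    var(log2(rnd[i, ctrl] + 1)) <= 3, logical(1))
  expect_identical(rownames(filterGenesControlVariance(rnd, ctrl)),
                   rownames(rnd)[keptOracle])
})

test_that("minimum-expression filter uses a strict CPM floor", {
  cpmMat <- matrix(5, 2, 20,
                   dimnames = list(c("at5", "above"),
                                   sprintf("s%02d", 1:20)))
  cpmMat["above", 1:15] <- 6
  out <- filterGenesMinExpression(cpmMat, colnames(cpmMat))
  expect_false("at5" %in% rownames(out))  # CPM == 5.0 everywhere: removed
  expect_true("above" %in% rownames(out)) # CPM 6 in exactly 15 samples

  set.seed(11)
  rnd <- matrix(runif(300 * 25, 0, 12), 300, 25,
                dimnames = list(sprintf("g%03d", 1:300),
                                sprintf("s%02d", 1:25)))
  oa <- sprintf("s%02d", 1:20)
  oracle <- vapply(seq_len(300), function(i)
    sum(rnd[i, oa] > 5) >= 15, logical(1))
  expect_identical(rownames(filterGenesMinExpression(rnd, oa)),
                   rownames(rnd)[oracle])
})

test_that("highly variable gene selection matches a brute-force SD sort", {
  set.seed(13)
  cpmMat <- matrix(runif(120 * 8, 0, 100), 120, 8,
                   dimnames = list(sprintf("g%03d", 1:120),
                                   sprintf("s%d", 1:8)))
  out <- selectHVG(cpmMat, n = 50)
  sds <- apply(log2(cpmMat + 1), 1, sd)
  oracle <- names(sort(sds, decreasing = TRUE))[1:50]
  expect_setequal(rownames(out), oracle)

  expect_setequal(rownames(selectHVG(cpmMat, n = 120)), rownames(cpmMat))

  two <- rbind(const = rep(10, 8), vary = c(1, 50, 2, 60, 3, 70, 4, 80))
  colnames(two) <- sprintf("s%d", 1:8)
  expect_identical(rownames(selectHVG(two, 1)), "vary")
  expect_error(selectHVG(two, 3), "exceeds")
})

test_that("filters commute with permutation and are idempotent", {
  m <- randomCounts(60, 10, seed = 15, lambda = 40)
  m[, 3] <- m[, 3] * 50L  # push one sample out of a narrow window
  f1 <- filterSamplesByDepth(m, low = 100, high = 3000)
  perm <- sample(ncol(m))
  f1p <- filterSamplesByDepth(m[, perm], low = 100, high = 3000)
  expect_identical(sort(colnames(f1)), sort(colnames(f1p)))
  expect_identical(filterSamplesByDepth(f1, low = 100, high = 3000), f1)

  cpmMat <- computeCPM(m)
  g1 <- filterGenesMinExpression(cpmMat, colnames(m), minCPM = 15000,
                                 minSamples = 5)
  expect_identical(filterGenesMinExpression(g1, colnames(m),
                                            minCPM = 15000,
                                            minSamples = 5), g1)
  gperm <- sample(nrow(m))
  g1p <- filterGenesMinExpression(cpmMat[gperm, ], colnames(m),
                                  minCPM = 15000, minSamples = 5)
  expect_setequal(rownames(g1), rownames(g1p))
})
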