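test_that("distance matrices agree with direct formulas", {
  X <- cbind(a = c(0, 0, 1), b = c(0, 1, 0))
  rownames(X) <- paste0("g", 1:3)
  D <- computeDistances(X, metrics = "euclidean")$euclidean
  expect_equal(D["a", "b"], sqrt(2))

  Xid <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  rownames(Xid) <- paste0("g", 1:3)
  for (D in computeDistances(Xid))
    expect_equal(unname(D), matrix(0, 2, 2))

  set.seed(21)
  Xr <- matrix(rnorm(5 * 6), 5, 6,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  sp <- computeDistances(Xr, metrics = "spearman")$spearman
  ranks <- apply(Xr, 2, rank)
  oracle <- 1 - cor(ranks, method = "pearson")
  expect_equal(unname(sp), unname(oracle))

  Xz <- Xr
  Xz[, 2] <- 7
  expect_error(computeDistances(Xz, metrics = "pearson"), "s2")
})

test_that("distance transformations behave as specified", {
  D0 <- matrix(0, 4, 4, dimnames = list(paste0("s", 1:4), paste0("s", 1:4)))
  expect_equal(unname(transformDistance(D0, "pca", 2)),
               matrix(0, 4, 2))

  # block-diagonal two-cluster distance: the Fiedler-like eigenvector
  # separates the blocks by sign
  D <- matrix(10, 6, 6)
  D[1:3, 1:3] <- 1; D[4:6, 4:6] <- 1
  diag(D) <- 0
  dimnames(D) <- list(paste0("s", 1:6), paste0("s", 1:6))
  emb <- transformDistance(D, "laplacian", 2)
  expect_true(all(sign(emb[1:3, 1]) == sign(emb[1, 1])))
  expect_true(all(sign(emb[4:6, 1]) == -sign(emb[1, 1])))
  # agreement with a dense eigendecomposition oracle (up to sign): the
  # second-smallest eigenvalue's eigenvector is the leading embedding axis
  A <- exp(-D / max(D))
  isq <- 1 / sqrt(rowSums(A))
  L <- diag(6) - (isq %o% isq) * A
  eig <- eigen(L, symmetric = TRUE)
  v2 <- eig$vectors[, 5]
  expect_equal(abs(unname(emb[, 1])), abs(v2), tolerance = 1e-8)

  expect_identical(transformDistance(D, "pca", 3),
                   transformDistance(D, "pca", 3))
  expect_error(transformDistance(D, "pca", 6), "out of range")
})

test_that("consensus clustering separates planted groups perfectly", {
  set.seed(31)
  # two distinct gene profiles separated by ~10 noise SDs: visible to the
  # Euclidean and to both correlation distances
  mu1 <- rnorm(30, 0, 10)
  mu2 <- rnorm(30, 0, 10)
  X <- cbind(mu1 + matrix(rnorm(30 * 10), 30),
             mu2 + matrix(rnorm(30 * 10), 30))
  dimnames(X) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:20))
  truth <- rep(1:2, each = 10)
  model <- consensusCluster(X, k = 2, seed = 5)
  cons <- consensusMatrix(model)
  expect_true(all(cons %in% c(0, 1)))
  expect_equal(adjustedRandIndex(clusterLabels(model), truth), 1)
  expect_equal(diag(cons), setNames(rep(1, 20), colnames(X)))
  expect_true(isSymmetric(cons))
  expect_true(model@silhouette >= -1 && model@silhouette <= 1)

  # two identical samples always co-cluster
  Xdup <- X
  Xdup[, 2] <- Xdup[, 1]
  m2 <- consensusCluster(Xdup, k = 2, seed = 5)
  expect_equal(consensusMatrix(m2)["s01", "s02"], 1)
  expect_equal(clusterLabels(m2)[["s01"]], clusterLabels(m2)[["s02"]])

  # permutation equivariance on well-separated data
  perm <- sample(20)
  mp <- consensusCluster(X[, perm], k = 2, seed = 5)
  expect_equal(consensusMatrix(mp)[colnames(X), colnames(X)], cons)

  expect_error(consensusCluster(X, k = 25, seed = 1), "exceeds")
  expect_error(consensusCluster(X, k = 1, seed = 1), "at least 2")
})

test_that("grid search picks the silhouette argmax and honors forceK", {
  coh <- smallCohort()
  cpmMat <- computeCPM(tissueCounts(coh, "cartilage"))
  lab <- truthSampleLabels(coh)
  single <- gridSearch(cpmMat, samples = names(lab), nGrid = 150,
                       kGrid = 3, seed = 2)
  expect_equal(single$chosen, 1L)
  expect_equal(nrow(single$table), 1L)

  grid <- gridSearch(cpmMat, samples = names(lab), nGrid = c(150, 300),
                     kGrid = 2:5, seed = 2)
  expect_equal(nrow(grid$table), 8L)
  expect_true(all(grid$table$silhouette >= -1 & grid$table$silhouette <= 1))
  expect_equal(grid$table$silhouette[grid$chosen],
               max(grid$table$silhouette))
  forced <- gridSearch(cpmMat, samples = names(lab), nGrid = c(150, 300),
                       kGrid = 2:5, seed = 2, forceK = 4)
  expect_equal(forced$table$k[forced$chosen], 4)
  expect_error(gridSearch(cpmMat, samples = names(lab), nGrid = 150,
                          kGrid = 2:3, seed = 2, forceK = 7),
               "forceK")
  expect_error(gridSearch(cpmMat, samples = names(lab), nGrid = 5000,
                          kGrid = 2, seed = 2), "gene count")
})

test_that("subtype recovery improves with planted effect size", {
  meanAri <- function(fc) {
    mean(vapply(1:5, function(s) {
      cfg <- CohortConfig(nPatients = 40, nGenes = 400,
                          nMarkersPerSubtype = 20, markerLog2fc = fc,
                          nPlantedCrosstalkPerSubtype = 0, nLrPairs = 50,
                          nControls = 0, seed = 200 + s)
      coh <- generateCohort(cfg)
      lab <- truthSampleLabels(coh)
      cpmMat <- computeCPM(tissueCounts(coh, "cartilage"))
      X <- log2(selectHVG(cpmMat, 150,
                          samples = names(lab))[, names(lab)] + 1)
      model <- consensusCluster(X, k = 4, seed = s)
      adjustedRandIndex(clusterLabels(model)[names(lab)], lab)
    }, numeric(1)))
  }
  aris <- vapply(c(0, 1, 2), meanAri, numeric(1))
  expect_true(all(diff(aris) >= 0) || (aris[3] > aris[1] + 0.3))
  expect_lt(aris[1], 0.2)
  expect_gt(aris[3], 0.8)
})

test_that("consensus is crisper with planted structure than without", {
  silAt <- function(fc) {
    cfg <- CohortConfig(nPatients = 40, nGenes = 400,
                        nMarkersPerSubtype = 20, markerLog2fc = fc,
                        nPlantedCrosstalkPerSubtype = 0, nLrPairs = 50,
                        nControls = 0, seed = 300)
    coh <- generateCohort(cfg)
    lab <- truthSampleLabels(coh)
    cpmMat <- computeCPM(tissueCounts(coh, "cartilage"))
    X <- log2(selectHVG(cpmMat, 150, samples = names(lab))[, names(lab)] + 1)
    consensusCluster(X, k = 4, seed = 1)@silhouette
  }
  expect_lt(silAt(0), silAt(2))
})

test_that("in-package ARI agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(41)
  for (i in 1:20) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b),
                 mclust::adjustedRandIndex(a, b))
  }
  expect_equal(adjustedRandIndex(1:10, 1:10), 1)
})
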