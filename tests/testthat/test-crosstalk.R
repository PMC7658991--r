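# Small two-tissue fixture with patient-id columns, asymmetric by design.
.ctFixture <- function() {
  pats <- paste0("P", 1:4)
  src <- matrix(c(
    10, 10, 10, 0,    # L1: expressed in 3/4 patients
    0,  0,  0,  0),   # L2: never expressed
    nrow = 2, byrow = TRUE,
    dimnames = list(c("L1", "L2"), pats))
  tgt <- matrix(c(
    5, 5, 5, 5,       # R1: always expressed
    5, 0, 0, 0),      # R2
    nrow = 2, byrow = TRUE,
    dimnames = list(c("R1", "R2"), pats))
  list(src = src, tgt = tgt, pats = pats)
}

test_that("pair evaluation computes occurrence ratios per evaluable patient", {
  fx <- .ctFixture()
  ev <- evaluatePair(fx$src, fx$tgt, "L1", "R1", fx$pats)
  expect_equal(ev$n_evaluable, 4L)
  expect_equal(ev$occurrence_ratio, 0.75)

  expect_equal(evaluatePair(fx$src, fx$tgt, "L2", "R1",
                            fx$pats)$occurrence_ratio, 0)

  # only patients sampled in both tissues are evaluable
  ev2 <- evaluatePair(fx$src[, 1:3], fx$tgt[, 2:4], "L1", "R1", fx$pats)
  expect_equal(ev2$n_evaluable, 2L)

  none <- evaluatePair(fx$src[, 1:2], fx$tgt[, 3:4], "L1", "R1", fx$pats)
  expect_true(is.na(none$occurrence_ratio))

  expect_error(evaluatePair(fx$src, fx$tgt, "nope", "R1", fx$pats), "nope")

  set.seed(71)
  S <- matrix(runif(6 * 5, 0, 3), 6, 5,
              dimnames = list(paste0("L", 1:6), paste0("P", 1:5)))
  T_ <- matrix(runif(6 * 5, 0, 3), 6, 5,
               dimnames = list(paste0("R", 1:6), paste0("P", 1:5)))
  for (i in 1:6) {
    ev <- evaluatePair(S, T_, paste0("L", i), paste0("R", i), paste0("P", 1:5))
    oracle <- (S[i, ] >= 1) & (T_[i, ] >= 1)
    expect_equal(unname(ev$indicator), unname(oracle))
  }
})

test_that("expressed-pair counting and high-pair selection follow the OR thresholds", {
  pats <- paste0("P", 1:5)
  genes <- c(paste0("L", 1:10), paste0("R", 1:10))
  hot <- matrix(100, 20, 5, dimnames = list(genes, pats))
  db <- data.frame(ligand = paste0("L", 1:10), receptor = paste0("R", 1:10))
  cpmByTissue <- list(cartilage = hot, synovium = hot)
  res <- countExpressedPairs(cpmByTissue, pats, db, "cartilage", "synovium")
  expect_equal(res@expressedPairs, 10L)

  resHigh <- selectHighPairs(res, tauOR = 0)
  expect_equal(resHigh@highPairs, res@expressedPairs)
  resOne <- selectHighPairs(res, tauOR = 1)
  expect_equal(resOne@highPairs,
               sum(res@pairs$occurrence_ratio == 1 & res@pairs$expressed))
  for (tau in c(0.9, 0.5, 0.1))
    expect_gte(selectHighPairs(res, tau)@highPairs,
               selectHighPairs(res, tau + 0.09)@highPairs)

  # asymmetric fixture: reversing direction changes the result
  fx <- .ctFixture()
  both <- list(A = rbind(fx$src, fx$tgt * 0), B = rbind(fx$src * 0, fx$tgt))
  db1 <- data.frame(ligand = "L1", receptor = "R1")
  ab <- countExpressedPairs(both, fx$pats, db1, "A", "B")
  ba <- countExpressedPairs(both, fx$pats, db1, "B", "A")
  expect_equal(ab@pairs$occurrence_ratio, 0.75)
  expect_equal(ba@pairs$occurrence_ratio, 0)

  # invariants: 0 <= high <= expressed <= |db|; OR invariant to patient
  # order and to rescaling above the threshold
  expect_true(res@highPairs <= res@expressedPairs &&
              res@expressedPairs <= nrow(db))
  shuf <- sample(pats)
  res2 <- countExpressedPairs(cpmByTissue, shuf, db, "cartilage", "synovium")
  expect_equal(res2@pairs$occurrence_ratio, res@pairs$occurrence_ratio)
  res3 <- countExpressedPairs(list(cartilage = hot * 7, synovium = hot * 3),
                              pats, db, "cartilage", "synovium")
  expect_equal(res3@pairs$occurrence_ratio, res@pairs$occurrence_ratio)
})

test_that("planted crosstalk is recovered in its planted direction", {
  cfg <- smallConfig(seed = 5, nPatients = 50, nPlantedCrosstalkPerSubtype = 12)
  coh <- cachedCohort("ct5", cfg)
  tr <- cohortTruth(coh)
  meta <- sampleTable(coh)
  cpmByTissue <- lapply(tissueNames(coh), function(t) {
    m <- computeCPM(tissueCounts(coh, t))
    oa <- meta$sample_id[meta$tissue == t & meta$status == "OA"]
    m <- m[, intersect(colnames(m), oa), drop = FALSE]
    colnames(m) <- meta$patient_id[match(colnames(m), meta$sample_id)]
    m
  })
  names(cpmByTissue) <- tissueNames(coh)
  tissues <- tissueNames(coh)

  pl <- tr$planted_crosstalk
  st <- "C1"
  pats <- names(tr$patient_subtype)[tr$patient_subtype == st]
  plSt <- pl[pl$subtype == st, ]
  dirs <- unique(plSt[, c("source", "target")])
  for (i in seq_len(nrow(dirs))) {
    srcT <- dirs$source[i]; tgtT <- dirs$target[i]
    dbDir <- plSt[plSt$source == srcT & plSt$target == tgtT,
                  c("ligand", "receptor")]
    inDir <- countExpressedPairs(cpmByTissue, pats, dbDir, srcT, tgtT,
                                 subtype = st)
    offCounts <- vapply(tissues, function(a) vapply(tissues, function(b) {
      if (a == srcT && b == tgtT) return(NA_integer_)
      r <- countExpressedPairs(cpmByTissue, pats, dbDir, a, b, subtype = st)
      if (r@empty) NA_integer_ else r@expressedPairs
    }, integer(1)), integer(length(tissues)))
    expect_gt(inDir@expressedPairs, max(offCounts, na.rm = TRUE))
  }
})

test_that("network edges recount per-direction high pairs", {
  fx <- .ctFixture()
  hot <- matrix(100, 4, 4, dimnames = list(c("L1", "L2", "R1", "R2"),
                                           fx$pats))
  cold <- hot * 0
  cpmByTissue <- list(cartilage = hot, synovium = cold,
                      subchondral_bone = hot)
  db <- data.frame(ligand = c("L1", "L2"), receptor = c("R1", "R2"))
  tissues <- names(cpmByTissue)
  results <- list()
  for (a in tissues) for (b in tissues)
    results[[paste0(a, "->", b)]] <- selectHighPairs(
      countExpressedPairs(cpmByTissue, fx$pats, db, a, b), tauOR = 0.9)
  net <- buildNetwork(results)
  expect_equal(nrow(net), 9L)
  for (i in seq_len(nrow(net)))
    expect_equal(net$weight[i],
                 results[[paste0(net$source[i], "->", net$target[i])]]@highPairs)
  # directions through the cold tissue have zero high pairs; hot-hot has 2
  expect_equal(net$weight[net$source == "cartilage" &
                          net$target == "subchondral_bone"], 2L)
  expect_equal(net$weight[net$source == "synovium" &
                          net$target == "synovium"], 0L)
  # opposite directions are computed independently
  expect_equal(net$weight[net$source == "cartilage" &
                          net$target == "synovium"], 0L)
  expect_equal(net$weight[net$source == "subchondral_bone" &
                          net$target == "cartilage"], 2L)
})

test_that("hypergeometric enrichment matches exact tail enumeration", {
  background <- paste0("g", 1:10)
  sets <- list(hit = paste0("g", 1:5), other = paste0("g", 8:10))
  query <- data.frame(ligand = paste0("g", 1:2), receptor = paste0("g", 3:4))
  res <- enrichCrosstalkGenes(query, sets, background)
  # P(X >= 4) with 5 marked of 10, draw 4: choose(5,4)/choose(10,4)
  expect_equal(res$p[res$set == "hit"], 5 / 210, tolerance = 1e-12)
  # exact tail by enumeration oracle
  enum <- sum(vapply(4:4, function(k)
    choose(5, k) * choose(5, 4 - k), numeric(1))) / choose(10, 4)
  expect_equal(res$p[res$set == "hit"], enum)
  # disjoint set cannot beat an overlapping one on the same margins
  expect_gte(res$p[res$set == "other"], res$p[res$set == "hit"])
  expect_equal(res$p[res$set == "other"], 1, tolerance = 1e-12)
  expect_error(enrichCrosstalkGenes(
    data.frame(ligand = character(), receptor = character()),
    sets, background), "empty query")
})

test_that("the planted positive-control gene set ranks first", {
  cfg <- smallConfig(seed = 5, nPatients = 50, nPlantedCrosstalkPerSubtype = 12)
  coh <- cachedCohort("ct5", cfg)
  db <- generateLRDatabase(cfg)
  sets <- generateGeneSets(cfg)
  tr <- cohortTruth(coh)
  res <- runCrosstalk(coh, tr$patient_subtype, db, genesets = sets)
  enr <- res$C1$enrichment
  expect_false(is.null(enr))
  expect_equal(enr$set[1], "crosstalk_C1")
})

test_that("crosstalk vanishes when the expression threshold exceeds all CPM", {
  coh <- smallCohort()
  tr <- cohortTruth(coh)
  db <- generateLRDatabase(smallConfig())
  meta <- sampleTable(coh)
  cpmByTissue <- lapply(tissueNames(coh), function(t) {
    m <- computeCPM(tissueCounts(coh, t))
    colnames(m) <- meta$patient_id[match(colnames(m), meta$sample_id)]
    m
  })
  names(cpmByTissue) <- tissueNames(coh)
  tau <- max(vapply(cpmByTissue, max, numeric(1))) + 1
  pats <- names(tr$patient_subtype)
  for (dirn in list(c("cartilage", "synovium"),
                    c("subchondral_bone", "subchondral_bone"))) {
    r <- countExpressedPairs(cpmByTissue, pats, db, dirn[1], dirn[2],
                             tauExpr = tau)
    expect_equal(r@expressedPairs, 0L)
    expect_equal(selectHighPairs(r)@highPairs, 0L)
  }
})
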