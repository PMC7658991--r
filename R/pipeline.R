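#' End-to-end subtype discovery on a cohort
#'
#' QC (depth window, CPM, control-variance and minimum-expression gene
#' filters on cartilage), consensus clustering over an (n HVG, k) grid
#' (optionally at a fixed k), marker detection, all pairwise differential
#' expression contrasts between subtypes, and the clinical report. When
#' `outDir` is given, writes `labels.tsv`, `grid_report.tsv`,
#' `consensus.tsv`, `markers.tsv`, `de_<A>_vs_<B>.tsv`,
#' `clinical_tests.tsv` and a JSON run manifest.
#'
#' @param cohort an [OACohort-class] (from [generateCohort()] or
#'   [readCohort()]).
#' @param nGrid,kGrid grids for [gridSearch()].
#' @param seed integer seed driving every stochastic stage.
#' @param forceK optional fixed cluster number.
#' @param depthLow,depthHigh sample depth window.
#' @param maxControlVariance control-variance gene filter ceiling.
#' @param minCPM,minSamples minimum-expression gene filter.
#' @param pAdjMax,aurocMin marker thresholds.
#' @param fcMin,fdrMax differential-expression thresholds.
#' @param outDir optional output directory.
#' @return list with `labels` (per patient), `grid`, `model`, `markers`,
#'   `de` (per contrast), `clinical`, `cpm` (cartilage CPM after QC) and
#'   `oaSamples`.
#' @export
runDiscovery <- function(cohort,
                         nGrid = seq(2500, 5000, by = 500), kGrid = 2:8,
                         seed = 1L, forceK = NULL,
                         depthLow = 5e5, depthHigh = 2e6,
                         maxControlVariance = 3, minCPM = 5,
                         minSamples = 15,
                         pAdjMax = 0.05, aurocMin = 0.6,
                         fcMin = 4, fdrMax = 0.05,
                         outDir = NULL) {
  stopifnot(is(cohort, "OACohort"))
  if (!"cartilage" %in% tissueNames(cohort))
    stop("stage qc: cartilage counts are required for discovery")
  meta <- sampleTable(cohort)
  counts <- filterSamplesByDepth(tissueCounts(cohort, "cartilage"),
                                 low = depthLow, high = depthHigh)
  cpmMat <- computeCPM(counts)
  keptMeta <- meta[match(colnames(counts), meta$sample_id), ]
  ctrl <- keptMeta$sample_id[keptMeta$status == "control"]
  oa <- keptMeta$sample_id[keptMeta$status == "OA"]
  if (length(ctrl) >= 2)
    cpmMat <- filterGenesControlVariance(cpmMat, ctrl,
                                         maxVariance = maxControlVariance)
  cpmMat <- filterGenesMinExpression(cpmMat, oa, minCPM = minCPM,
                                     minSamples = minSamples)
  nGrid <- nGrid[nGrid <= nrow(cpmMat)]
  if (!length(nGrid))
    stop("stage cluster: no nGrid value fits the filtered gene count")

  grid <- gridSearch(cpmMat, samples = oa, nGrid = nGrid, kGrid = kGrid,
                     seed = seed, forceK = forceK)
  model <- grid$best
  sampleLabels <- sprintf("C%d", clusterLabels(model))
  names(sampleLabels) <- names(clusterLabels(model))
  patientLabels <- sampleLabels
  names(patientLabels) <-
    keptMeta$patient_id[match(names(sampleLabels), keptMeta$sample_id)]

  logX <- log2(cpmMat[, oa, drop = FALSE] + 1)
  markers <- findMarkers(logX, sampleLabels, pAdjMax = pAdjMax,
                         aurocMin = aurocMin)
  subtypes <- sort(unique(sampleLabels))
  de <- list()
  for (pr in utils::combn(subtypes, 2, simplify = FALSE)) {
    a <- names(sampleLabels)[sampleLabels == pr[2]]
    b <- names(sampleLabels)[sampleLabels == pr[1]]
    if (length(a) >= 2 && length(b) >= 2)
      de[[paste0(pr[2], "_vs_", pr[1])]] <-
        differentialExpression(counts, a, b, fcMin = fcMin, fdrMax = fdrMax)
  }
  clinical <- subtypeClinicalReport(keptMeta[keptMeta$status == "OA", ],
                                    patientLabels)

  out <- list(labels = patientLabels, sampleLabels = sampleLabels,
              grid = grid, model = model, markers = markers, de = de,
              clinical = clinical, cpm = cpmMat, oaSamples = oa)
  if (!is.null(outDir)) .writeDiscovery(out, outDir, seed)
  out
}

.writeDiscovery <- function(out, outDir, seed) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  write.table(data.frame(sample_id = names(out$sampleLabels),
                         cluster = unname(out$sampleLabels)),
              file.path(outDir, "labels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(out$grid$table, file.path(outDir, "grid_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cons <- consensusMatrix(out$model)
  write.table(data.frame(sample_id = rownames(cons), cons,
                         check.names = FALSE),
              file.path(outDir, "consensus.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(out$markers, file.path(outDir, "markers.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (nm in names(out$de))
    write.table(out$de[[nm]]$retained,
                file.path(outDir, paste0("de_", nm, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  write.table(out$clinical$tests, file.path(outDir, "clinical_tests.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(
    stage = "discovery", seed = seed,
    chosen = out$grid$table[out$grid$chosen, , drop = FALSE],
    package_version = as.character(utils::packageVersion("OAsubtypes")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outDir)
}

#' Directed tissue-crosstalk analysis per subtype
#'
#' Evaluates every available directed tissue pair (nine when all three
#' tissues are present, self-pairs included) for every subtype: per-pair
#' occurrence ratios, expressed and highly expressed pair counts, the
#' per-subtype network edge list, and (when gene sets are supplied)
#' hypergeometric enrichment of the crosstalk genes. Absent tissues and
#' directions without evaluable patients are flagged, not silently
#' skipped.
#'
#' @param cohort an [OACohort-class]; patients lacking a tissue are
#'   excluded pair-wise.
#' @param labels named subtype labels per patient.
#' @param db ligand-receptor `data.frame` (`ligand`, `receptor`); genes
#'   absent from a tissue matrix are dropped with a message.
#' @param tauExpr,minORExpressed,tauOR crosstalk thresholds.
#' @param genesets optional named list of gene sets for enrichment.
#' @param outDir optional output directory.
#' @return list per subtype: `results` (list of [CrosstalkResult-class]
#'   keyed `source->target`), `network` edge list, and `enrichment`.
#' @export
runCrosstalk <- function(cohort, labels, db, tauExpr = 1.0,
                         minORExpressed = 0.5, tauOR = 0.9,
                         genesets = NULL, outDir = NULL) {
  stopifnot(is(cohort, "OACohort"))
  tissues <- tissueNames(cohort)
  if (length(tissues) < 1) stop("no tissue matrices available")
  meta <- sampleTable(cohort)
  cpmByTissue <- lapply(tissues, function(t) {
    m <- computeCPM(tissueCounts(cohort, t))
    oa <- meta$sample_id[meta$tissue == t & meta$status == "OA"]
    m <- m[, intersect(colnames(m), oa), drop = FALSE]
    colnames(m) <- meta$patient_id[match(colnames(m), meta$sample_id)]
    m
  })
  names(cpmByTissue) <- tissues
  ## keep only database pairs whose genes exist in every tissue matrix
  sharedGenes <- Reduce(intersect, lapply(cpmByTissue, rownames))
  okPairs <- db$ligand %in% sharedGenes & db$receptor %in% sharedGenes
  if (!all(okPairs))
    message(sprintf("dropping %d ligand-receptor pair(s) with genes absent from a tissue matrix",
                    sum(!okPairs)))
  db <- db[okPairs, , drop = FALSE]
  subtypes <- sort(unique(as.character(labels)))
  allTissues <- c("cartilage", "synovium", "subchondral_bone")
  overlap <- FALSE
  out <- list()
  for (st in subtypes) {
    pats <- names(labels)[labels == st]
    results <- list()
    for (src in allTissues) for (tg in allTissues) {
      if (!src %in% tissues || !tg %in% tissues) {
        ## absent tissue: reported as a flagged empty direction
        results[[paste0(src, "->", tg)]] <-
          new("CrosstalkResult", subtype = st, source = src, target = tg,
              pairs = data.frame(ligand = db$ligand, receptor = db$receptor,
                                 n_evaluable = 0L,
                                 n_expressed = NA_integer_,
                                 occurrence_ratio = NA_real_,
                                 expressed = NA, high = NA,
                                 stringsAsFactors = FALSE),
              nEvaluable = 0L, expressedPairs = 0L, highPairs = 0L,
              empty = TRUE)
        next
      }
      r <- countExpressedPairs(cpmByTissue, pats, db, src, tg,
                               subtype = st, tauExpr = tauExpr,
                               minORExpressed = minORExpressed)
      results[[paste0(src, "->", tg)]] <- selectHighPairs(r, tauOR = tauOR)
      if (!r@empty) overlap <- TRUE
    }
    network <- buildNetwork(results)
    enrichment <- NULL
    if (!is.null(genesets)) {
      allHigh <- do.call(rbind, lapply(results, function(r)
        if (!r@empty) r@pairs[which(r@pairs$high), c("ligand", "receptor")]))
      if (!is.null(allHigh) && nrow(allHigh))
        enrichment <- enrichCrosstalkGenes(allHigh, genesets, sharedGenes)
    }
    out[[st]] <- list(results = results, network = network,
                      enrichment = enrichment)
  }
  if (!overlap)
    stop("no overlapping patients between tissues for any subtype")
  if (!is.null(outDir)) .writeCrosstalk(out, outDir)
  out
}

.writeCrosstalk <- function(out, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  for (st in names(out)) {
    for (key in names(out[[st]]$results)) {
      r <- out[[st]]$results[[key]]
      f <- file.path(outDir, sprintf("crosstalk_%s_%s_%s.tsv", st,
                                     r@source, r@target))
      write.table(r@pairs, f, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(out[[st]]$network,
                file.path(outDir, sprintf("network_%s.tsv", st)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(out[[st]]$enrichment))
      write.table(out[[st]]$enrichment,
                  file.path(outDir, sprintf("enrichment_%s.tsv", st)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(outDir)
}

#' Train on the discovery cohort and classify an external cohort
#'
#' Thin composition of [trainSubtypeModel()] and [predictSubtypes()]:
#' trains a seeded random forest on the discovery expression matrix and
#' marker genes, then reports the external cohort's subtype composition
#' with percentages at one decimal.
#'
#' @param discoveryExpr discovery expression matrix (genes x samples).
#' @param labels named subtype labels for the discovery samples.
#' @param markers marker table ([findMarkers()]).
#' @param externalExpr external expression matrix.
#' @param seed training seed.
#' @param outDir optional output directory (`predictions.tsv`,
#'   `composition.tsv`).
#' @return list with `model`, `labels`, `probabilities`, `composition`.
#' @export
runClassify <- function(discoveryExpr, labels, markers, externalExpr,
                        seed = 1L, outDir = NULL) {
  model <- trainSubtypeModel(discoveryExpr, labels, markers, seed = seed)
  pred <- predictSubtypes(model, externalExpr)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(data.frame(sample_id = names(pred$labels),
                           label = unname(pred$labels),
                           max_probability = apply(pred$probabilities, 1,
                                                   max)),
                file.path(outDir, "predictions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    comp <- pred$composition
    comp$percent <- sprintf("%.1f", comp$percent)
    write.table(comp, file.path(outDir, "composition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  c(list(model = model), pred)
}
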