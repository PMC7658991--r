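#' Generate a synthetic multi-tissue osteoarthritis cohort
#'
#' Simulates negative-binomial gene-by-sample count matrices for cartilage,
#' synovium and subchondral bone with known ground truth: four planted
#' molecular subtypes at uneven proportions (largest-remainder rounding of
#' the configured proportions), subtype-specific marker blocks elevated in
#' cartilage, directional ligand-receptor co-expression planted per subtype
#' across specific tissue pairs, low-variance non-OA control cartilage
#' samples, per-patient missing non-cartilage tissues, and ordered clinical
#' scores (KL grade, osteophyte, joint space narrowing, age) whose
#' distributions shift with subtype.
#'
#' Gene baseline abundances are log-normal (meanlog 3, sdlog 1.2), giving
#' the heavy-tailed abundance profile of bulk RNA-seq; marker genes are
#' drawn from a higher-abundance stratum so that, as in real cartilage
#' marker panels, they are well expressed. Planted crosstalk ligands and
#' receptors get a low baseline (about 0.3 CPM expected) and are elevated by
#' `2^(markerLog2fc + 3)` in the planted (tissue, subtype) combination only,
#' so their co-expression is detectable in the planted direction and rare
#' elsewhere. Counts for sample j of tissue t are NB with mean proportional
#' to the (subtype- and tissue-adjusted) gene abundance scaled to the
#' sample's target library size, and dispersion `nbDispersion` (controls:
#' dispersion / 5).
#'
#' The cohort *design* (which genes are markers, the planted crosstalk
#' pairs and directions, baseline gene abundances) is drawn from
#' `config@seed`; patient-level sampling (subject assignment, clinical
#' scores, tissue presence, library sizes, counts) is drawn from
#' `samplingSeed`, which defaults to the config seed. Passing a fresh
#' `samplingSeed` therefore yields an independent cohort with the *same
#' biology* — the natural stand-in for an external validation cohort.
#'
#' @param config a [CohortConfig-class].
#' @param samplingSeed integer seed for the patient-level draws (default:
#'   `config@seed`).
#' @return an [OACohort-class]; `cohortTruth()` returns `patient_subtype`
#'   (named character), `marker_genes` (list per subtype), `planted_crosstalk`
#'   (`data.frame`: ligand, receptor, source, target, subtype) and
#'   `clinical_effects`.
#' @examples
#' coh <- generateCohort(CohortConfig(nPatients = 30, nGenes = 800,
#'                                    nMarkersPerSubtype = 20, seed = 1))
#' coh
#' @export
generateCohort <- function(config, samplingSeed = config@seed) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  set.seed(config@seed)

  subtypes <- c("C1", "C2", "C3", "C4")
  tissues <- c("cartilage", "synovium", "subchondral_bone")
  nP <- config@nPatients
  nG <- config@nGenes
  genes <- sprintf("g%05d", seq_len(nG))
  patients <- sprintf("P%04d", seq_len(nP))

  sizes <- subtypeSizes(nP, config@subtypeProportions)
  patientSubtype <- rep(subtypes, sizes)
  names(patientSubtype) <- patients

  ## disjoint gene blocks: markers per subtype, then ligand/receptor genes
  ## reserved for planted crosstalk
  nM <- config@nMarkersPerSubtype
  nCT <- config@nPlantedCrosstalkPerSubtype
  blockGenes <- sample(genes, 4L * nM + 8L * nCT)
  markerGenes <- lapply(seq_along(subtypes), function(i)
    sort(blockGenes[((i - 1L) * nM + 1L):(i * nM)]))
  names(markerGenes) <- subtypes
  ctPool <- if (nCT > 0) blockGenes[(4L * nM + 1L):length(blockGenes)]
            else character(0)

  ## planted crosstalk: per subtype, nCT directed pairs over random directed
  ## tissue pairs (one direction per subtype keeps directionality testable)
  planted <- NULL
  if (nCT > 0) {
    dirGrid <- expand.grid(source = tissues, target = tissues,
                           stringsAsFactors = FALSE)
    planted <- do.call(rbind, lapply(seq_along(subtypes), function(i) {
      lig <- ctPool[((i - 1L) * 2L * nCT + 1L):((i - 1L) * 2L * nCT + nCT)]
      rec <- ctPool[((i - 1L) * 2L * nCT + nCT + 1L):(i * 2L * nCT)]
      dirs <- dirGrid[sample.int(nrow(dirGrid), nCT, replace = TRUE), ]
      data.frame(ligand = lig, receptor = rec,
                 source = dirs$source, target = dirs$target,
                 subtype = subtypes[i], stringsAsFactors = FALSE)
    }))
    rownames(planted) <- NULL
  } else {
    planted <- data.frame(ligand = character(), receptor = character(),
                          source = character(), target = character(),
                          subtype = character(), stringsAsFactors = FALSE)
  }

  ## baseline abundances (relative scale)
  baseMean <- rlnorm(nG, meanlog = 3, sdlog = 1.2)
  names(baseMean) <- genes
  ## markers from a higher-abundance stratum
  baseMean[unlist(markerGenes)] <-
    rlnorm(4L * nM, meanlog = 4, sdlog = 0.8)
  ## crosstalk genes near 0.3 CPM expected
  if (length(ctPool))
    baseMean[ctPool] <- sum(baseMean) * 0.3e-6  # ~0.3 CPM expected baseline
  ctBoost <- 2^(config@markerLog2fc + 3)

  ## design complete; patient-level sampling starts on its own stream
  set.seed(.deriveSeed(samplingSeed, 1L))

  ## tissue presence: cartilage always, others Bernoulli(1 - missing)
  present <- matrix(TRUE, nP, 3, dimnames = list(patients, tissues))
  if (config@tissueMissingRate > 0) {
    present[, "synovium"] <- runif(nP) >= config@tissueMissingRate
    present[, "subchondral_bone"] <- runif(nP) >= config@tissueMissingRate
  }

  ## clinical scores
  eff <- list(
    osteophyte_p = c(C1 = 0.40, C2 = 0.65, C3 = 0.40, C4 = 0.40),
    jsn_p = c(C1 = 0.40, C2 = 0.40, C3 = 0.40, C4 = 0.70),
    age_mean = c(C1 = 70, C2 = 70, C3 = 63, C4 = 70),
    age_sd = 6,
    kl3_p = c(C1 = 0.25, C2 = 0.25, C3 = 0.43, C4 = 0.25)
  )
  osteophyte <- rbinom(nP, 12, eff$osteophyte_p[patientSubtype])
  jsn <- rbinom(nP, 6, eff$jsn_p[patientSubtype])
  age <- as.integer(round(rnorm(nP, eff$age_mean[patientSubtype], eff$age_sd)))
  kl <- ifelse(runif(nP) < eff$kl3_p[patientSubtype], 3L, 4L)
  sex <- sample(c("F", "M"), nP, replace = TRUE)
  center <- sample(sprintf("center%d", 1:4), nP, replace = TRUE)

  dispOA <- config@nbDispersion
  drawSample <- function(mu, libSize, dispersion) {
    mu <- mu / sum(mu) * libSize
    as.integer(rnbinom(length(mu), mu = mu, size = 1 / dispersion))
  }

  tissueSEs <- list()
  metaRows <- list()
  for (t in tissues) {
    keep <- patients[present[, t]]
    if (!length(keep)) next
    sampleIds <- paste0(keep, "_", substr(t, 1, 4))
    libs <- round(runif(length(keep), config@librarySizeRange[1],
                        config@librarySizeRange[2]))
    counts <- matrix(0L, nG, length(keep), dimnames = list(genes, sampleIds))
    for (j in seq_along(keep)) {
      st <- patientSubtype[keep[j]]
      mu <- baseMean
      if (t == "cartilage")
        mu[markerGenes[[st]]] <- mu[markerGenes[[st]]] * 2^config@markerLog2fc
      sel <- planted$subtype == st
      if (any(sel)) {
        ligHere <- planted$ligand[sel & planted$source == t]
        recHere <- planted$receptor[sel & planted$target == t]
        if (length(ligHere)) mu[ligHere] <- mu[ligHere] * ctBoost
        if (length(recHere)) mu[recHere] <- mu[recHere] * ctBoost
      }
      counts[, j] <- drawSample(mu, libs[j], dispOA)
    }
    metaRows[[t]] <- data.frame(
      sample_id = sampleIds, patient_id = keep, tissue = t,
      status = "OA", center = center[match(keep, patients)],
      age = age[match(keep, patients)], sex = sex[match(keep, patients)],
      kl = kl[match(keep, patients)],
      osteophyte = osteophyte[match(keep, patients)],
      jsn = jsn[match(keep, patients)], stringsAsFactors = FALSE)
    tissueSEs[[t]] <- counts
  }

  ## control cartilage samples: baseline means, reduced dispersion
  if (config@nControls > 0) {
    ctrlIds <- sprintf("CTRL%02d_cart", seq_len(config@nControls))
    libs <- round(runif(config@nControls, config@librarySizeRange[1],
                        config@librarySizeRange[2]))
    ctrl <- matrix(0L, nG, config@nControls,
                   dimnames = list(genes, ctrlIds))
    for (j in seq_len(config@nControls))
      ctrl[, j] <- drawSample(baseMean, libs[j], dispOA / 5)
    tissueSEs[["cartilage"]] <- cbind(tissueSEs[["cartilage"]], ctrl)
    metaRows[["control"]] <- data.frame(
      sample_id = ctrlIds,
      patient_id = sprintf("CTRL%02d", seq_len(config@nControls)),
      tissue = "cartilage", status = "control", center = "center1",
      age = NA_integer_, sex = NA_character_, kl = NA_integer_,
      osteophyte = NA_integer_, jsn = NA_integer_, stringsAsFactors = FALSE)
  }

  meta <- do.call(rbind, metaRows)
  rownames(meta) <- NULL

  ses <- lapply(names(tissueSEs), function(t) {
    m <- tissueSEs[[t]]
    cd <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
    rownames(cd) <- cd$sample_id
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = m),
      colData = S4Vectors::DataFrame(cd))
  })
  names(ses) <- names(tissueSEs)

  truth <- list(
    patient_subtype = patientSubtype,
    marker_genes = markerGenes,
    planted_crosstalk = planted,
    clinical_effects = eff
  )
  new("OACohort", tissues = ses, sampleTable = meta, truth = truth,
      config = config)
}

#' Generate a ligand-receptor pair database for a synthetic cohort
#'
#' Emits `nLrPairs` distinct ordered gene pairs from the cohort's gene
#' universe. All planted crosstalk pairs are included; the remainder are
#' random pairs with ligand and receptor distinct within each row.
#'
#' @param config the [CohortConfig-class] used for [generateCohort()] (same
#'   seed gives the same table and guarantees the planted pairs exist).
#' @return `data.frame` with columns `ligand` and `receptor`.
#' @export
generateLRDatabase <- function(config) {
  stopifnot(is(config, "CohortConfig"))
  validObject(config)
  if (config@nLrPairs > config@nGenes / 2)
    stop("nLrPairs must not exceed nGenes/2")
  coh <- .cohortDesign(config)
  planted <- coh$planted[, c("ligand", "receptor")]
  planted <- planted[!duplicated(planted), , drop = FALSE]
  nExtra <- config@nLrPairs - nrow(planted)
  if (nExtra < 0)
    stop("nLrPairs smaller than the number of planted crosstalk pairs")
  set.seed(.deriveSeed(config@seed, 17L))
  used <- unique(c(planted$ligand, planted$receptor))
  pool <- setdiff(coh$genes, used)
  extra <- matrix(sample(pool, 2L * nExtra), ncol = 2)
  db <- rbind(planted,
              data.frame(ligand = extra[, 1], receptor = extra[, 2],
                         stringsAsFactors = FALSE))
  rownames(db) <- NULL
  db
}

# Recreates the deterministic design portion (gene ids, blocks, planted
# crosstalk) of generateCohort without drawing counts. Must replay the same
# RNG stream prefix as generateCohort.
.cohortDesign <- function(config) {
  set.seed(config@seed)
  subtypes <- c("C1", "C2", "C3", "C4")
  tissues <- c("cartilage", "synovium", "subchondral_bone")
  nG <- config@nGenes
  genes <- sprintf("g%05d", seq_len(nG))
  nM <- config@nMarkersPerSubtype
  nCT <- config@nPlantedCrosstalkPerSubtype
  blockGenes <- sample(genes, 4L * nM + 8L * nCT)
  markerGenes <- lapply(seq_along(subtypes), function(i)
    sort(blockGenes[((i - 1L) * nM + 1L):(i * nM)]))
  names(markerGenes) <- subtypes
  ctPool <- if (nCT > 0) blockGenes[(4L * nM + 1L):length(blockGenes)]
            else character(0)
  planted <- if (nCT > 0) {
    dirGrid <- expand.grid(source = tissues, target = tissues,
                           stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_along(subtypes), function(i) {
      lig <- ctPool[((i - 1L) * 2L * nCT + 1L):((i - 1L) * 2L * nCT + nCT)]
      rec <- ctPool[((i - 1L) * 2L * nCT + nCT + 1L):(i * 2L * nCT)]
      dirs <- dirGrid[sample.int(nrow(dirGrid), nCT, replace = TRUE), ]
      data.frame(ligand = lig, receptor = rec,
                 source = dirs$source, target = dirs$target,
                 subtype = subtypes[i], stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  } else {
    data.frame(ligand = character(), receptor = character(),
               source = character(), target = character(),
               subtype = character(), stringsAsFactors = FALSE)
  }
  list(genes = genes, markerGenes = markerGenes, planted = planted)
}

#' Generate GMT-style gene sets for a synthetic cohort
#'
#' Emits random gene sets plus one positive-control set per subtype that
#' contains exactly that subtype's planted crosstalk ligands and receptors,
#' so over-representation of crosstalk genes is testable against ground
#' truth.
#'
#' @param config the [CohortConfig-class].
#' @param nRandomSets number of additional random sets.
#' @param setSizeRange size range of the random sets.
#' @return named list of gene-id character vectors; positive-control sets
#'   are named `crosstalk_C1` .. `crosstalk_C4`.
#' @export
generateGeneSets <- function(config, nRandomSets = 8L,
                             setSizeRange = c(15L, 60L)) {
  stopifnot(is(config, "CohortConfig"))
  design <- .cohortDesign(config)
  set.seed(.deriveSeed(config@seed, 29L))
  sets <- list()
  for (st in names(design$markerGenes)) {
    pl <- design$planted[design$planted$subtype == st, ]
    ctGenes <- unique(c(pl$ligand, pl$receptor))
    if (length(ctGenes))
      sets[[paste0("crosstalk_", st)]] <- sort(ctGenes)
  }
  for (i in seq_len(nRandomSets)) {
    sz <- sample(setSizeRange[1]:setSizeRange[2], 1)
    sets[[sprintf("random_set_%02d", i)]] <- sort(sample(design$genes, sz))
  }
  sets
}

#' Cohort, table and gene-set writers/readers
#'
#' Plain-text round-trippable serialization: per-tissue counts as TSV
#' (genes as rows) or MatrixMarket triplets with sidecar name files, pooled
#' metadata as TSV, ligand-receptor pairs as TSV with `ligand`/`receptor`
#' headers, gene sets as GMT, and ground truth as JSON.
#'
#' @param cohort an [OACohort-class].
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"mtx"` for the count matrices.
#' @return `writeCohort` invisibly returns the vector of files written;
#'   `readCohort` returns an [OACohort-class] (truth restored when the JSON
#'   file is present).
#' @export
writeCohort <- function(cohort, dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(is(cohort, "OACohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (t in names(cohort@tissues)) {
    f <- file.path(dir, paste0("counts_", t,
                               if (format == "tsv") ".tsv" else ".mtx"))
    writeCountMatrix(tissueCounts(cohort, t), f, format = format)
    files <- c(files, f)
  }
  metaFile <- file.path(dir, "samples.tsv")
  write.table(cohort@sampleTable, metaFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  files <- c(files, metaFile)
  if (length(cohort@truth)) {
    truthFile <- file.path(dir, "truth.json")
    tr <- cohort@truth
    ## named vectors as explicit tables so names survive JSON round trips
    tr$patient_subtype <- data.frame(
      patient_id = names(cohort@truth$patient_subtype),
      subtype = unname(cohort@truth$patient_subtype),
      stringsAsFactors = FALSE)
    jsonlite::write_json(tr, truthFile, digits = NA, dataframe = "columns")
    files <- c(files, truthFile)
  }
  invisible(files)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  meta <- readSampleTable(file.path(dir, "samples.tsv"))
  ext <- if (format == "tsv") ".tsv" else ".mtx"
  ses <- list()
  for (t in c("cartilage", "synovium", "subchondral_bone")) {
    f <- file.path(dir, paste0("counts_", t, ext))
    if (!file.exists(f)) next
    m <- readCountMatrix(f, format = format)
    cd <- meta[match(colnames(m), meta$sample_id), , drop = FALSE]
    rownames(cd) <- cd$sample_id
    ses[[t]] <- SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = m), colData = S4Vectors::DataFrame(cd))
  }
  truth <- list()
  truthFile <- file.path(dir, "truth.json")
  if (file.exists(truthFile)) {
    tr <- jsonlite::read_json(truthFile, simplifyVector = TRUE)
    tr$patient_subtype <- setNames(tr$patient_subtype$subtype,
                                   tr$patient_subtype$patient_id)
    tr$planted_crosstalk <- as.data.frame(tr$planted_crosstalk,
                                          stringsAsFactors = FALSE)
    truth <- tr
  }
  new("OACohort", tissues = ses, sampleTable = meta, truth = truth,
      config = NULL)
}

#' Read and write ligand-receptor pair tables and GMT gene sets
#'
#' @param db `data.frame` with `ligand` and `receptor` columns.
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @param descriptions optional per-set description column for the GMT.
#' @return readers return the parsed object.
#' @export
writeLRPairs <- function(db, path) {
  stopifnot(all(c("ligand", "receptor") %in% colnames(db)))
  write.table(db[, c("ligand", "receptor")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLRPairs
#' @export
readLRPairs <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("ligand", "receptor") %in% colnames(db)))
    stop("ligand-receptor table must have 'ligand' and 'receptor' columns")
  if (anyDuplicated(db[, c("ligand", "receptor")]))
    stop("duplicated ligand-receptor pair rows")
  db
}

#' @rdname writeLRPairs
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeLRPairs
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, character(1), 1)
  sets
}
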