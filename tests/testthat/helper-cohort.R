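# Shared fixtures, generated in code and memoised per test run.

.fixtureCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, config) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, generateCohort(config), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

# Small four-subtype cohort with planted structure, used across modules.
smallConfig <- function(seed = 3, nPatients = 40, nGenes = 800,
                        nMarkersPerSubtype = 25, markerLog2fc = 2,
                        nLrPairs = 100, nPlantedCrosstalkPerSubtype = 10,
                        tissueMissingRate = 0.3, ...) {
  CohortConfig(nPatients = nPatients, nGenes = nGenes,
               nMarkersPerSubtype = nMarkersPerSubtype,
               markerLog2fc = markerLog2fc, nLrPairs = nLrPairs,
               nPlantedCrosstalkPerSubtype = nPlantedCrosstalkPerSubtype,
               tissueMissingRate = tissueMissingRate, seed = seed, ...)
}

smallCohort <- function() cachedCohort("small", smallConfig())

# External validation cohort: same design (seed 11 biology), fresh
# patient-level sampling.
externalCohort <- function() {
  if (!exists("clfext", envir = .fixtureCache))
    assign("clfext",
           generateCohort(smallConfig(seed = 11, nPatients = 60),
                          samplingSeed = 77),
           envir = .fixtureCache)
  get("clfext", envir = .fixtureCache)
}

# Truth subtype label per cartilage OA sample of a cohort.
truthSampleLabels <- function(cohort) {
  tr <- cohortTruth(cohort)
  meta <- sampleTable(cohort)
  oa <- meta[meta$tissue == "cartilage" & meta$status == "OA", ]
  setNames(unname(tr$patient_subtype[oa$patient_id]), oa$sample_id)
}

# Random count matrix with dimnames, for filter oracles.
randomCounts <- function(nGenes, nSamples, seed, lambda = 50) {
  set.seed(seed)
  m <- matrix(rpois(nGenes * nSamples, lambda), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              sprintf("s%02d", seq_len(nSamples))))
  m
}

# Exhaustive AUROC oracle: enumerate all (in, out) pairs.
aurocByEnumeration <- function(values, inGroup) {
  ins <- values[inGroup]
  outs <- values[!inGroup]
  tot <- 0
  for (a in ins) for (b in outs)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(ins) * length(outs))
}
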