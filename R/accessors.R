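#' Accessors for cohort and model objects
#'
#' `tissueCounts()` extracts the raw count matrix of one tissue;
#' `sampleTable()` the pooled metadata; `cohortTruth()` the simulator ground
#' truth; `clusterLabels()` the final consensus labels; `consensusMatrix()`
#' the co-clustering frequency matrix.
#'
#' @param x an [OACohort-class] or [ConsensusModel-class].
#' @param tissue one of `"cartilage"`, `"synovium"`, `"subchondral_bone"`.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
tissueCounts <- function(x, tissue = "cartilage") {
  stopifnot(is(x, "OACohort"))
  if (!tissue %in% names(x@tissues))
    stop(sprintf("tissue '%s' not present in cohort", tissue))
  SummarizedExperiment::assay(x@tissues[[tissue]], "counts")
}

#' @rdname accessors
#' @export
sampleTable <- function(x) {
  stopifnot(is(x, "OACohort"))
  x@sampleTable
}

#' @rdname accessors
#' @export
cohortTruth <- function(x) {
  stopifnot(is(x, "OACohort"))
  x@truth
}

#' @rdname accessors
#' @export
tissueNames <- function(x) {
  stopifnot(is(x, "OACohort"))
  names(x@tissues)
}

#' @rdname accessors
#' @export
clusterLabels <- function(x) {
  stopifnot(is(x, "ConsensusModel"))
  x@labels
}

#' @rdname accessors
#' @export
consensusMatrix <- function(x) {
  stopifnot(is(x, "ConsensusModel"))
  x@consensus
}

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nPatients, "patients,",
      object@nGenes, "genes,", object@nControls, "controls\n")
  cat("  subtype proportions:",
      paste(sprintf("%.3f", object@subtypeProportions), collapse = " "), "\n")
  cat("  marker block:", object@nMarkersPerSubtype, "genes/subtype at log2FC",
      object@markerLog2fc, "| NB dispersion", object@nbDispersion, "\n")
  cat("  library sizes:",
      paste(format(object@librarySizeRange, big.mark = ","), collapse = " - "),
      "| seed", object@seed, "\n")
})

setMethod("show", "OACohort", function(object) {
  cat("OACohort with", length(object@tissues), "tissue(s):\n")
  for (tn in names(object@tissues)) {
    se <- object@tissues[[tn]]
    cat(sprintf("  %-16s %d genes x %d samples\n", tn, nrow(se), ncol(se)))
  }
  cat(" ", nrow(object@sampleTable), "samples,",
      length(unique(object@sampleTable$patient_id)), "patients\n")
  if (length(object@truth))
    cat("  synthetic ground truth attached\n")
})

setMethod("show", "ConsensusModel", function(object) {
  cat(sprintf(
    "ConsensusModel: k = %d, n HVG = %d, %d base solutions\n",
    object@k, object@nHVG, object@nSolutions))
  cat(sprintf("  mean silhouette %.3f; cluster sizes: %s\n",
    object@silhouette,
    paste(table(object@labels), collapse = ", ")))
})

setMethod("show", "CrosstalkResult", function(object) {
  cat(sprintf("CrosstalkResult %s: %s -> %s\n",
              object@subtype, object@source, object@target))
  if (object@empty) {
    cat("  no evaluable patients (flagged empty)\n")
  } else {
    cat(sprintf("  %d evaluable patients; %d/%d pairs expressed, %d high\n",
                object@nEvaluable, object@expressedPairs,
                nrow(object@pairs), object@highPairs))
  }
})

setMethod("show", "SubtypeModel", function(object) {
  cat(sprintf("SubtypeModel: %d marker-gene features, classes %s\n",
              length(object@featureGenes),
              paste(object@classes, collapse = ", ")))
  cat(sprintf("  out-of-bag accuracy %.3f (seed %d)\n",
              object@oobAccuracy, object@seed))
})
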