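#' @import methods
#' @importFrom stats cor dist prcomp kmeans hclust cutree as.dist sd var
#'   rnbinom rlnorm rnorm rbinom runif quantile pnorm pt phyper p.adjust
#'   wilcox.test fisher.test predict setNames aggregate
#' @importFrom utils read.delim write.table head combn
NULL

setClassUnion("integerOrNULL", c("integer", "NULL"))

#' Configuration of a synthetic multi-tissue osteoarthritis cohort
#'
#' Parameters of the negative-binomial cohort simulator: number of patients,
#' planted subtype proportions, gene universe size, marker-block geometry,
#' dispersion, library-size window, control samples, per-tissue missingness,
#' and the planted ligand-receptor crosstalk design.
#'
#' @slot nPatients number of OA patients (cartilage always sampled).
#' @slot subtypeProportions length-4 non-negative vector summing to 1;
#'   patients are assigned to subtypes C1..C4 by largest-remainder rounding.
#' @slot nGenes size of the gene universe shared by all tissues.
#' @slot nMarkersPerSubtype number of marker genes planted per subtype.
#' @slot markerLog2fc log2 fold elevation of a subtype's markers in that
#'   subtype's cartilage samples.
#' @slot nbDispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @slot librarySizeRange integer pair; target library sizes are drawn
#'   uniformly in this window.
#' @slot nControls number of non-OA control cartilage samples.
#' @slot tissueMissingRate probability in [0, 1) that a patient lacks a
#'   given non-cartilage tissue.
#' @slot nLrPairs rows of the emitted ligand-receptor database.
#' @slot nPlantedCrosstalkPerSubtype directed ligand-receptor pairs planted
#'   per subtype.
#' @slot seed integer seed; equal seeds give bit-identical cohorts.
#' @export
setClass("CohortConfig",
  representation(
    nPatients = "integer",
    subtypeProportions = "numeric",
    nGenes = "integer",
    nMarkersPerSubtype = "integer",
    markerLog2fc = "numeric",
    nbDispersion = "numeric",
    librarySizeRange = "integer",
    nControls = "integer",
    tissueMissingRate = "numeric",
    nLrPairs = "integer",
    nPlantedCrosstalkPerSubtype = "integer",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msgs <- character()
  chkPos <- function(x, nm, allowZero = FALSE) {
    if (length(x) != 1L || is.na(x) || (if (allowZero) x < 0 else x <= 0))
      sprintf("'%s' must be a single %s value", nm,
              if (allowZero) "non-negative" else "positive")
    else character()
  }
  msgs <- c(msgs,
    chkPos(object@nPatients, "nPatients"),
    chkPos(object@nGenes, "nGenes"),
    chkPos(object@nMarkersPerSubtype, "nMarkersPerSubtype"),
    chkPos(object@markerLog2fc, "markerLog2fc", allowZero = TRUE),
    chkPos(object@nbDispersion, "nbDispersion"),
    chkPos(object@nControls, "nControls", allowZero = TRUE),
    chkPos(object@nLrPairs, "nLrPairs"),
    chkPos(object@nPlantedCrosstalkPerSubtype,
           "nPlantedCrosstalkPerSubtype", allowZero = TRUE))
  if (length(object@subtypeProportions) != 4L ||
      any(object@subtypeProportions < 0))
    msgs <- c(msgs, "'subtypeProportions' must be 4 non-negative values")
  else if (abs(sum(object@subtypeProportions) - 1) > 1e-9)
    msgs <- c(msgs, "'subtypeProportions' must sum to 1 (tolerance 1e-9)")
  if (length(object@librarySizeRange) != 2L ||
      any(object@librarySizeRange <= 0) ||
      object@librarySizeRange[1] > object@librarySizeRange[2])
    msgs <- c(msgs,
      "'librarySizeRange' must be an increasing pair of positive integers")
  if (length(object@tissueMissingRate) != 1L ||
      object@tissueMissingRate < 0 || object@tissueMissingRate >= 1)
    msgs <- c(msgs, "'tissueMissingRate' must lie in [0, 1)")
  if (length(object@seed) != 1L || is.na(object@seed))
    msgs <- c(msgs, "'seed' must be a single integer")
  if (object@nLrPairs > object@nGenes / 2)
    msgs <- c(msgs, "'nLrPairs' must not exceed nGenes/2")
  if (4L * object@nMarkersPerSubtype +
      8L * object@nPlantedCrosstalkPerSubtype > object@nGenes)
    msgs <- c(msgs, "'nGenes' too small for the requested marker and crosstalk blocks")
  if (length(msgs)) msgs else TRUE
})

#' Construct a [CohortConfig-class]
#'
#' Default proportions are the exact cohort fractions 81/131, 24/131,
#' 10/131 and 16/131 (i.e. 61.8% of patients in subtype C1, 18.3% in C2,
#' 7.6% in C3 and 12.2% in C4 after rounding); default
#' library sizes span the usual shallow 3'-counting QC window.
#'
#' @param nPatients number of OA patients.
#' @param subtypeProportions length-4 proportions summing to 1.
#' @param nGenes gene universe size.
#' @param nMarkersPerSubtype planted markers per subtype.
#' @param markerLog2fc marker elevation (log2).
#' @param nbDispersion NB dispersion.
#' @param librarySizeRange target library-size window (pair).
#' @param nControls control cartilage samples.
#' @param tissueMissingRate per-patient probability of a missing
#'   non-cartilage tissue.
#' @param nLrPairs ligand-receptor database size.
#' @param nPlantedCrosstalkPerSubtype planted directed pairs per subtype.
#' @param seed integer seed.
#' @return a validated `CohortConfig`.
#' @examples
#' cfg <- CohortConfig(nPatients = 40, nGenes = 800, seed = 1)
#' @export
CohortConfig <- function(nPatients,
                         subtypeProportions = c(81, 24, 10, 16) / 131,
                         nGenes = 6000L,
                         nMarkersPerSubtype = 60L,
                         markerLog2fc = 2.0,
                         nbDispersion = 0.2,
                         librarySizeRange = c(600000L, 1800000L),
                         nControls = 4L,
                         tissueMissingRate = 0.5,
                         nLrPairs = 300L,
                         nPlantedCrosstalkPerSubtype = 20L,
                         seed = 1L) {
  asInt <- function(x, nm) {
    if (any(!is.finite(x)) || any(abs(x - round(x)) > 1e-8))
      stop(sprintf("'%s' must be integral", nm), call. = FALSE)
    as.integer(round(x))
  }
  new("CohortConfig",
    nPatients = asInt(nPatients, "nPatients"),
    subtypeProportions = as.numeric(subtypeProportions),
    nGenes = asInt(nGenes, "nGenes"),
    nMarkersPerSubtype = asInt(nMarkersPerSubtype, "nMarkersPerSubtype"),
    markerLog2fc = as.numeric(markerLog2fc),
    nbDispersion = as.numeric(nbDispersion),
    librarySizeRange = asInt(librarySizeRange, "librarySizeRange"),
    nControls = asInt(nControls, "nControls"),
    tissueMissingRate = as.numeric(tissueMissingRate),
    nLrPairs = asInt(nLrPairs, "nLrPairs"),
    nPlantedCrosstalkPerSubtype = asInt(nPlantedCrosstalkPerSubtype,
                                        "nPlantedCrosstalkPerSubtype"),
    seed = asInt(seed, "seed"))
}

#' Multi-tissue cohort container
#'
#' Holds one [SummarizedExperiment::SummarizedExperiment-class] of raw counts
#' per tissue (cartilage, synovium, subchondral_bone), the pooled sample
#' metadata table, the generating configuration and — for synthetic cohorts —
#' the ground truth (patient subtypes, planted markers, planted crosstalk,
#' clinical effect parameters).
#'
#' @slot tissues named list of `SummarizedExperiment`s with a `counts` assay.
#' @slot sampleTable `data.frame` of per-sample metadata.
#' @slot truth list of ground-truth elements (empty for real cohorts).
#' @slot config the `CohortConfig` used (may be `NULL`-like placeholder).
#' @export
setClass("OACohort",
  representation(
    tissues = "list",
    sampleTable = "data.frame",
    truth = "list",
    config = "ANY"
  )
)

setValidity("OACohort", function(object) {
  msgs <- character()
  if (!all(vapply(object@tissues, inherits, TRUE,
                  "SummarizedExperiment")))
    msgs <- c(msgs, "all tissues must be SummarizedExperiment objects")
  req <- c("sample_id", "patient_id", "tissue", "status")
  if (!all(req %in% colnames(object@sampleTable)))
    msgs <- c(msgs, sprintf("sampleTable must contain columns: %s",
                            paste(req, collapse = ", ")))
  else if (anyDuplicated(object@sampleTable$sample_id))
    msgs <- c(msgs, "duplicate sample_id in sampleTable")
  if (length(msgs)) msgs else TRUE
})

#' Consensus clustering result for one (n HVG, k) setting
#'
#' @slot consensus samples-by-samples co-clustering frequency matrix
#'   (symmetric, entries in \[0, 1\], unit diagonal).
#' @slot labels named integer cluster labels in 1..k, renumbered by
#'   decreasing cluster size.
#' @slot k number of clusters requested.
#' @slot nHVG number of highly variable genes used.
#' @slot silhouette mean silhouette width of the final labels under the
#'   distance 1 - consensus.
#' @slot nSolutions number of base clustering solutions combined.
#' @export
setClass("ConsensusModel",
  representation(
    consensus = "matrix",
    labels = "integer",
    k = "integer",
    nHVG = "integer",
    silhouette = "numeric",
    nSolutions = "integer"
  )
)

setValidity("ConsensusModel", function(object) {
  msgs <- character()
  cm <- object@consensus
  if (nrow(cm) != ncol(cm) || max(abs(cm - t(cm))) > 1e-12)
    msgs <- c(msgs, "consensus matrix must be symmetric")
  if (any(cm < -1e-12) || any(cm > 1 + 1e-12))
    msgs <- c(msgs, "consensus entries must lie in [0, 1]")
  if (any(abs(diag(cm) - 1) > 1e-12))
    msgs <- c(msgs, "consensus diagonal must be exactly 1")
  if (length(object@labels) != nrow(cm))
    msgs <- c(msgs, "one label per sample required")
  if (length(msgs)) msgs else TRUE
})

#' Directed ligand-receptor crosstalk result for one subtype and tissue pair
#'
#' @slot subtype subtype label.
#' @slot source source tissue (ligand side).
#' @slot target target tissue (receptor side).
#' @slot pairs per-pair `data.frame` with columns `ligand`, `receptor`,
#'   `n_evaluable`, `n_expressed`, `occurrence_ratio`, `expressed`, `high`.
#' @slot nEvaluable number of patients sampled in both tissues.
#' @slot expressedPairs pairs with occurrence ratio at or above the
#'   expression threshold.
#' @slot highPairs expressed pairs at or above the high-OR threshold.
#' @slot empty TRUE when no patient was evaluable (counts undefined, not 0).
#' @export
setClass("CrosstalkResult",
  representation(
    subtype = "character",
    source = "character",
    target = "character",
    pairs = "data.frame",
    nEvaluable = "integer",
    expressedPairs = "integer",
    highPairs = "integer",
    empty = "logical"
  )
)

#' Random-forest subtype classifier over marker-gene rank features
#'
#' @slot forest fitted `randomForest` object.
#' @slot featureGenes ordered marker genes used as features.
#' @slot markerSubtype named character: provenance subtype of each feature.
#' @slot classes subtype labels the model can emit.
#' @slot seed training seed.
#' @slot oobAccuracy out-of-bag accuracy on the training cohort.
#' @export
setClass("SubtypeModel",
  representation(
    forest = "ANY",
    featureGenes = "character",
    markerSubtype = "character",
    classes = "character",
    seed = "integer",
    oobAccuracy = "numeric"
  )
)
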