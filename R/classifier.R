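#' Within-sample quantile-rank normalization
#'
#' Replaces each sample's values on the given genes by fractional ranks in
#' (0, 1] (ties averaged), making downstream classification invariant to
#' any within-sample monotone transform — the cross-platform harmonization
#' used before subtype transfer. Requested genes absent from the matrix are
#' imputed at rank 0 and reported via the `"missing_genes"` attribute.
#'
#' @param expr expression matrix (genes x samples), any monotone scale.
#' @param genes gene ids to use, in the desired feature order.
#' @return genes x samples matrix of ranks with attribute `missing_genes`.
#' @export
rankNormalize <- function(expr, genes) {
  present <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, present)
  out <- matrix(0, length(genes), ncol(expr),
                dimnames = list(genes, colnames(expr)))
  if (length(present)) {
    sub <- expr[present, , drop = FALSE]
    out[present, ] <- apply(sub, 2, function(v)
      rank(v, ties.method = "average") / length(v))
  }
  attr(out, "missing_genes") <- missing
  out
}

#' Train a random-forest subtype classifier on marker genes
#'
#' Features are the marker genes (rank-normalized within sample); the
#' forest uses 500 trees and sqrt(p) candidate features per split, seeded
#' for determinism. Out-of-bag accuracy on the training cohort is recorded.
#'
#' @param expr discovery-cohort expression matrix (genes x samples).
#' @param labels named subtype labels covering the samples.
#' @param markers marker table from [findMarkers()] (or any `data.frame`
#'   with `gene` and `subtype` columns).
#' @param seed training seed.
#' @param nTrees number of trees.
#' @return a [SubtypeModel-class].
#' @export
trainSubtypeModel <- function(expr, labels, markers, seed = 1L,
                              nTrees = 500L) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("labels must cover every training sample")
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) stop("at least 2 classes required")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  genes <- unique(markers$gene)
  genes <- genes[genes %in% rownames(expr)]
  if (!length(genes)) stop("no marker gene present in the training matrix")
  feats <- t(rankNormalize(expr, genes))
  set.seed(as.integer(seed))
  forest <- randomForest::randomForest(feats, labels, ntree = nTrees)
  oob <- mean(forest$predicted == labels)
  prov <- setNames(as.character(markers$subtype[match(genes, markers$gene)]),
                   genes)
  new("SubtypeModel", forest = forest, featureGenes = genes,
      markerSubtype = prov, classes = levels(labels),
      seed = as.integer(seed), oobAccuracy = oob)
}

#' Assign subtypes to an external expression cohort
#'
#' Rank-normalizes the external matrix on the model's feature genes
#' (missing genes at rank 0), predicts by majority vote of the trees, and
#' tabulates the cohort composition with percentages at one decimal;
#' classes never predicted are reported as explicit zero-count rows.
#'
#' @param model a [SubtypeModel-class].
#' @param externalExpr external expression matrix (genes x samples), any
#'   within-sample monotone scale.
#' @return list with `labels` (named character), `probabilities`
#'   (samples x classes, rows summing to 1) and `composition`
#'   (`data.frame`: subtype, count, percent).
#' @export
predictSubtypes <- function(model, externalExpr) {
  stopifnot(is(model, "SubtypeModel"))
  if (ncol(externalExpr) == 0) stop("external matrix has no samples")
  shared <- intersect(model@featureGenes, rownames(externalExpr))
  if (!length(shared))
    stop("no shared feature genes between model and external cohort")
  feats <- t(rankNormalize(externalExpr, model@featureGenes))
  labels <- as.character(predict(model@forest, feats, type = "response"))
  names(labels) <- colnames(externalExpr)
  probs <- predict(model@forest, feats, type = "prob")
  rownames(probs) <- colnames(externalExpr)
  list(labels = labels, probabilities = probs,
       composition = compositionTable(labels, classes = model@classes))
}
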