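#' Sample-sample distance matrices for consensus clustering
#'
#' Euclidean distance on sample columns plus the two correlation distances
#' `1 - r` (Pearson, Spearman), the base distances combined by the
#' SC3-style consensus scheme. All outputs are symmetric with a zero
#' diagonal.
#'
#' @param X log-expression matrix, genes x samples.
#' @param metrics subset of `c("euclidean", "pearson", "spearman")`.
#' @return named list of samples-by-samples distance matrices.
#' @export
computeDistances <- function(X,
    metrics = c("euclidean", "pearson", "spearman")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (ncol(X) < 2) stop("at least 2 samples required")
  out <- list()
  if (any(metrics %in% c("pearson", "spearman"))) {
    zv <- apply(X, 2, sd) == 0
    if (any(zv))
      stop(sprintf("zero-variance sample(s) under correlation distance: %s",
                   paste(colnames(X)[zv], collapse = ", ")))
  }
  for (m in metrics) {
    D <- switch(m,
      euclidean = as.matrix(dist(t(X))),
      pearson = 1 - cor(X, method = "pearson"),
      spearman = 1 - cor(X, method = "spearman"))
    diag(D) <- 0
    D <- (D + t(D)) / 2
    dimnames(D) <- list(colnames(X), colnames(X))
    out[[m]] <- D
  }
  out
}

#' Low-dimensional transformation of a distance matrix
#'
#' `pca`: the distance matrix is treated as a feature matrix (one row per
#' sample), columns are centered, and the first `d` principal-component
#' coordinates are returned. `laplacian`: eigenvectors of the symmetric
#' normalized graph Laplacian of the affinity `A = exp(-D / max(D))` for
#' the `d` smallest non-trivial eigenvalues (the constant leading
#' eigenvector is dropped). Column signs are fixed so that each
#' column's largest-magnitude entry is positive, making the embedding
#' reproducible.
#'
#' @param D samples-by-samples distance matrix.
#' @param method `"pca"` or `"laplacian"`.
#' @param d embedding dimension, `1 <= d < nrow(D)`.
#' @return samples-by-d embedding matrix.
#' @export
transformDistance <- function(D, method = c("pca", "laplacian"), d) {
  method <- match.arg(method)
  n <- nrow(D)
  if (d < 1 || d >= n)
    stop(sprintf("d = %d out of range [1, %d]", d, n - 1))
  emb <- if (method == "pca") {
    pc <- prcomp(D, center = TRUE, scale. = FALSE)
    pc$x[, seq_len(d), drop = FALSE]
  } else {
    mx <- max(D)
    A <- if (mx > 0) exp(-D / mx) else matrix(1, n, n)
    deg <- rowSums(A)
    isq <- 1 / sqrt(deg)
    L <- diag(n) - (isq %o% isq) * A
    eig <- eigen(L, symmetric = TRUE)
    ## d smallest non-trivial eigenvalues, ascending: the very smallest
    ## eigenvalue's eigenvector is the constant-degree direction and carries
    ## no partition information, so it is dropped (standard spectral
    ## clustering practice); this keeps low-dimensional embeddings useful
    ## on small cohorts
    idx <- seq(n - 1, by = -1, length.out = d)
    eig$vectors[, idx, drop = FALSE]
  }
  ## deterministic sign convention
  for (j in seq_len(ncol(emb))) {
    i <- which.max(abs(emb[, j]))
    if (emb[i, j] < 0) emb[, j] <- -emb[, j]
  }
  rownames(emb) <- rownames(D)
  colnames(emb) <- paste0("dim", seq_len(d))
  emb
}

# d-region: 4%..7% of the sample count as in the SC3 scheme, never empty
# and never reaching n.
.dRange <- function(n, dFracs = c(0.04, 0.07)) {
  lo <- ceiling(dFracs[1] * n)
  hi <- floor(dFracs[2] * n)
  lo <- max(1L, min(lo, n - 1L))
  hi <- max(lo, min(hi, n - 1L))
  seq.int(lo, hi)
}

# All (distance, transform, d) base solutions as k-independent embeddings.
.baseEmbeddings <- function(X, dFracs = c(0.04, 0.07)) {
  dists <- computeDistances(X)
  dr <- .dRange(ncol(X), dFracs)
  embs <- list()
  for (dn in names(dists))
    for (tf in c("pca", "laplacian"))
      for (d in dr)
        embs[[sprintf("%s_%s_d%d", dn, tf, d)]] <-
          transformDistance(dists[[dn]], tf, d)
  embs
}

.consensusFromEmbeddings <- function(embs, k, seed, nHVG = NA_integer_) {
  n <- nrow(embs[[1]])
  samples <- rownames(embs[[1]])
  co <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_along(embs)) {
    set.seed(.deriveSeed(seed, i * 131L + k))
    cl <- kmeans(embs[[i]], centers = k, nstart = 10, iter.max = 300)$cluster
    co <- co + outer(cl, cl, "==")
  }
  cons <- co / length(embs)
  diag(cons) <- 1
  hc <- hclust(as.dist(1 - cons), method = "complete")
  raw <- cutree(hc, k = k)
  labels <- .renumberClusters(raw, samples)
  sil <- .meanSilhouette(labels, 1 - cons)
  new("ConsensusModel", consensus = cons, labels = labels, k = as.integer(k),
      nHVG = as.integer(nHVG), silhouette = sil,
      nSolutions = length(embs))
}

# Renumber clusters by decreasing size; ties by the lexicographically
# smallest member sample id.
.renumberClusters <- function(raw, samples) {
  ids <- sort(unique(raw))
  sizes <- vapply(ids, function(i) sum(raw == i), integer(1))
  firstMember <- vapply(ids, function(i) min(samples[raw == i]), character(1))
  ord <- order(-sizes, firstMember, method = "radix")
  remap <- integer(max(ids))
  remap[ids[ord]] <- seq_along(ids)
  out <- remap[raw]
  names(out) <- samples
  out
}

.meanSilhouette <- function(labels, dmat) {
  if (length(unique(labels)) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels, dmatrix = dmat)
  mean(sil[, "sil_width"])
}

#' SC3-style consensus clustering at fixed k
#'
#' Runs k-means (10 restarts, seeded per combination) on every
#' (distance, transform, d) embedding with d spanning 4-7% of the sample
#' count, averages the co-clustering indicators into a consensus matrix,
#' cuts the complete-linkage dendrogram of `1 - consensus` into `k` groups,
#' and scores the cut by mean silhouette width under `1 - consensus`.
#'
#' @param X log-expression matrix (genes x samples), typically
#'   log2(CPM + 1) restricted to highly variable genes.
#' @param k number of clusters (`2 <= k <=` sample count).
#' @param dFracs lower/upper fraction of samples for the embedding
#'   dimension sweep.
#' @param seed integer seed; the run is deterministic given the seed.
#' @param nHVG recorded gene count (metadata only).
#' @return a [ConsensusModel-class].
#' @export
consensusCluster <- function(X, k, dFracs = c(0.04, 0.07), seed = 1L,
                             nHVG = nrow(X)) {
  if (k < 2) stop("k must be at least 2")
  if (k > ncol(X)) stop(sprintf("k = %d exceeds sample count %d", k, ncol(X)))
  embs <- .baseEmbeddings(X, dFracs)
  .consensusFromEmbeddings(embs, k, seed, nHVG = nHVG)
}

#' Grid search over highly-variable-gene counts and cluster numbers
#'
#' One consensus clustering per (n HVG, k) grid point; the chosen point
#' maximizes mean silhouette width. `forceK` restricts the choice to a
#' fixed k (choosing only n) for the case where cluster number is fixed on
#' external grounds, e.g. clinical interpretability of an extra split.
#'
#' @param cpmMat CPM matrix of the clustering tissue.
#' @param samples samples to cluster (e.g. OA cartilage samples).
#' @param nGrid vector of HVG counts to try.
#' @param kGrid vector of cluster numbers to try.
#' @param seed integer seed.
#' @param dFracs embedding-dimension sweep fractions.
#' @param forceK optional fixed k overriding the silhouette argmax.
#' @return list with `table` (`data.frame`: n_hvg, k, silhouette,
#'   cluster_sizes), `chosen` (row index), `models` (named list of
#'   [ConsensusModel-class]), and `best` (the chosen model).
#' @export
gridSearch <- function(cpmMat, samples = colnames(cpmMat),
                       nGrid = seq(2500, 5000, by = 500),
                       kGrid = 2:8, seed = 1L, dFracs = c(0.04, 0.07),
                       forceK = NULL) {
  stopifnot(length(nGrid) > 0, length(kGrid) > 0)
  if (max(nGrid) > nrow(cpmMat))
    stop("largest nGrid value exceeds the available gene count")
  rows <- list()
  models <- list()
  for (n in nGrid) {
    X <- log2(selectHVG(cpmMat, n = n, samples = samples)[, samples,
                                                          drop = FALSE] + 1)
    embs <- .baseEmbeddings(X, dFracs)
    for (k in kGrid) {
      model <- .consensusFromEmbeddings(embs, k,
                                        .deriveSeed(seed, n), nHVG = n)
      key <- sprintf("n%d_k%d", n, k)
      models[[key]] <- model
      rows[[key]] <- data.frame(
        n_hvg = n, k = k, silhouette = model@silhouette,
        cluster_sizes = paste(sort(table(model@labels),
                                   decreasing = TRUE), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cand <- if (is.null(forceK)) seq_len(nrow(tab)) else which(tab$k == forceK)
  if (!length(cand)) stop("forceK is not in the k grid")
  chosen <- cand[which.max(tab$silhouette[cand])]
  list(table = tab, chosen = chosen,
       models = models, best = models[[sprintf("n%d_k%d", tab$n_hvg[chosen],
                                               tab$k[chosen])]])
}
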