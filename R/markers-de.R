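#' Area under the ROC curve for one gene against a grouping
#'
#' Mann-Whitney formulation: the fraction of (in-group, out-group) value
#' pairs in which the in-group value is larger, counting ties as one half.
#'
#' @param values numeric vector (e.g. one gene's expression).
#' @param inGroup logical vector marking the positive group.
#' @return AUROC in \[0, 1\].
#' @examples
#' aurocScore(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))  # 1
#' @export
aurocScore <- function(values, inGroup) {
  stopifnot(length(values) == length(inGroup))
  nIn <- sum(inGroup)
  nOut <- sum(!inGroup)
  if (nIn == 0 || nOut == 0)
    stop("both groups must be non-empty for AUROC")
  r <- rank(values)
  u <- sum(r[inGroup]) - nIn * (nIn + 1) / 2
  u / (nIn * nOut)
}

# Vectorized cluster-vs-rest rank statistics over a genes x samples matrix:
# per gene, midranks, the tie term sum(t^3 - t), and for a given in-group
# the AUROC plus the tie-corrected normal-approximation two-sided
# Wilcoxon rank-sum p (continuity-corrected).
.rankStats <- function(X) {
  R <- t(apply(X, 1, rank))
  tie <- apply(X, 1, function(v) {
    t <- table(v)
    sum(t^3 - t)
  })
  list(R = R, tie = tie, n = ncol(X))
}

.clusterVsRest <- function(rs, inGroup) {
  n1 <- sum(inGroup)
  n2 <- rs$n - n1
  rsum <- rowSums(rs$R[, inGroup, drop = FALSE])
  U <- rsum - n1 * (n1 + 1) / 2
  auroc <- U / (n1 * n2)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 * ((rs$n + 1) - rs$tie / (rs$n * (rs$n - 1)))
  z <- pmax(abs(U - mu) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- pmin(1, 2 * pnorm(-z))
  p[sigma2 <= 0] <- 1
  list(auroc = auroc, p = p)
}

#' Detect subtype marker genes by AUROC and rank-sum test
#'
#' For every gene and cluster, scores cluster-vs-rest separation by AUROC
#' and a two-sided Wilcoxon rank-sum p (tie-corrected normal
#' approximation), adjusts p by Benjamini-Hochberg across genes within each
#' cluster, keeps rows with adjusted p below `pAdjMax` and AUROC above
#' `aurocMin`, and assigns each surviving gene to the cluster in which its
#' AUROC is maximal. Rows are ranked within cluster by AUROC, ties by gene
#' id.
#'
#' @param expr expression matrix (genes x samples); any monotone per-gene
#'   scale, typically log2(CPM + 1).
#' @param labels named cluster labels covering `colnames(expr)`.
#' @param pAdjMax adjusted-p ceiling.
#' @param aurocMin strict AUROC floor.
#' @return `data.frame` with columns `gene`, `subtype`, `auroc`, `p`,
#'   `p_adj`; each gene appears for at most one subtype.
#' @export
findMarkers <- function(expr, labels, pAdjMax = 0.05, aurocMin = 0.6) {
  labels <- labels[colnames(expr)]
  if (anyNA(labels)) stop("labels must cover every sample in 'expr'")
  cl <- sort(unique(as.character(labels)))
  if (length(cl) < 2) stop("at least 2 clusters required")
  if (any(table(labels) < 2)) stop("every cluster needs at least 2 samples")
  rs <- .rankStats(expr)
  perCluster <- lapply(cl, function(cc) {
    st <- .clusterVsRest(rs, as.character(labels) == cc)
    data.frame(gene = rownames(expr), subtype = cc, auroc = st$auroc,
               p = st$p, p_adj = p.adjust(st$p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, perCluster)
  ## argmax-AUROC subtype per gene
  best <- all[order(all$gene, -all$auroc, all$subtype, method = "radix"), ]
  best <- best[!duplicated(best$gene), ]
  keep <- best[best$p_adj < pAdjMax & best$auroc > aurocMin, , drop = FALSE]
  keep <- keep[order(keep$subtype, -keep$auroc, keep$gene,
                     method = "radix"), ]
  rownames(keep) <- NULL
  keep
}

#' Pairwise differential expression between two subtypes
#'
#' Welch t-test on log2(CPM + 1) per gene, with fold change defined on
#' pseudocount-shifted mean CPM, `(mean_A + 1) / (mean_B + 1)`, and
#' Benjamini-Hochberg FDR across all tested genes. Genes are retained at
#' `|fold change| > fcMin` (i.e. `|log2fc| > log2(fcMin)`) and
#' `fdr < fdrMax`.
#'
#' @param counts raw count matrix covering both groups.
#' @param samplesA,samplesB sample ids of the two groups (>= 2 each).
#' @param fcMin fold-change cutoff (linear scale).
#' @param fdrMax FDR cutoff.
#' @return list with `table` (all genes: gene, log2fc, p, fdr, direction)
#'   and `retained` (subset passing both cutoffs), plus the thresholds.
#' @export
differentialExpression <- function(counts, samplesA, samplesB,
                                   fcMin = 4, fdrMax = 0.05) {
  counts <- .asCountMatrix(counts)
  if (length(samplesA) < 2 || length(samplesB) < 2)
    stop("each group needs at least 2 samples")
  stopifnot(all(c(samplesA, samplesB) %in% colnames(counts)))
  cpmMat <- computeCPM(counts[, c(samplesA, samplesB), drop = FALSE])
  A <- log2(cpmMat[, samplesA, drop = FALSE] + 1)
  B <- log2(cpmMat[, samplesB, drop = FALSE] + 1)
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- rowSums((A - mA)^2) / (nA - 1)
  vB <- rowSums((B - mB)^2) / (nB - 1)
  se2 <- vA / nA + vB / nB
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / (vA^2 / (nA^2 * (nA - 1)) + vB^2 / (nB^2 * (nB - 1)))
  p <- 2 * pt(-abs(tstat), df)
  p[se2 == 0 & (mA == mB)] <- 1
  p[se2 == 0 & (mA != mB)] <- 0
  log2fc <- log2((rowMeans(cpmMat[, samplesA, drop = FALSE]) + 1) /
                 (rowMeans(cpmMat[, samplesB, drop = FALSE]) + 1))
  fdr <- p.adjust(p, method = "BH")
  tab <- data.frame(gene = rownames(counts), log2fc = log2fc, p = p,
                    fdr = fdr,
                    direction = ifelse(log2fc > 0, "up", "down"),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  retained <- tab[abs(tab$log2fc) > log2(fcMin) & tab$fdr < fdrMax, ,
                  drop = FALSE]
  list(table = tab, retained = retained, fc_min = fcMin, fdr_max = fdrMax)
}

#' Venn-region cardinalities of up to three gene sets
#'
#' Counts every region of the Venn partition: for each non-empty
#' combination of the input sets, the number of elements belonging to
#' exactly those sets.
#'
#' @param sets named list of 1-3 character vectors.
#' @return named integer vector; names are set names joined by `"&"`.
#' @examples
#' overlapSets(list(A = c("a", "b"), B = c("b", "c")))
#' @export
overlapSets <- function(sets) {
  if (length(sets) > 3) stop("more than 3 sets unsupported")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1)
  out <- integer()
  for (sz in seq_along(sets)) {
    for (combo in utils::combn(names(sets), sz, simplify = FALSE)) {
      inAll <- rowSums(member[, combo, drop = FALSE]) == length(combo)
      outAll <- rowSums(member[, setdiff(names(sets), combo),
                               drop = FALSE]) == 0
      out[paste(combo, collapse = "&")] <- sum(inAll & outAll)
    }
  }
  out
}
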