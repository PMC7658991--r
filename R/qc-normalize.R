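#' Read and write a gene-by-sample count matrix
#'
#' TSV layout: gene ids in the first column, sample ids in the header.
#' MatrixMarket layout: a coordinate `.mtx` file with 1-based indices plus
#' sidecar name files `<path>.genes.txt` and `<path>.samples.txt` (one id
#' per line). Validation rejects duplicate gene or sample ids and negative
#' or non-integral entries, naming the offending id.
#'
#' @param path file path (`.mtx` path for MatrixMarket).
#' @param format `"tsv"` or `"mtx"`.
#' @param x integer matrix with gene/sample dimnames (writer).
#' @return integer matrix, genes as rows, file order preserved.
#' @export
readCountMatrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- genes
  } else {
    sp <- Matrix::readMM(path)
    genes <- readLines(paste0(path, ".genes.txt"))
    samples <- readLines(paste0(path, ".samples.txt"))
    if (nrow(sp) != length(genes) || ncol(sp) != length(samples))
      stop("MTX dimensions do not match sidecar name files")
    m <- as.matrix(sp)
    dimnames(m) <- list(genes, samples)
  }
  .validateCounts(m)
  storage.mode(m) <- "integer"
  m
}

.validateCounts <- function(m) {
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate gene id(s): %s",
                 paste(unique(rownames(m)[duplicated(rownames(m))]),
                       collapse = ", ")))
  if (anyDuplicated(colnames(m)))
    stop(sprintf("duplicate sample id(s): %s",
                 paste(unique(colnames(m)[duplicated(colnames(m))]),
                       collapse = ", ")))
  bad <- which(!is.finite(m) | m < 0 | abs(m - round(m)) > 1e-8,
               arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("invalid count at gene '%s', sample '%s'",
                 rownames(m)[bad[1, 1]], colnames(m)[bad[1, 2]]))
  invisible(TRUE)
}

#' @rdname readCountMatrix
#' @export
writeCountMatrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  x <- .asCountMatrix(x)
  if (format == "tsv") {
    df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(x, sparse = TRUE), path)
    writeLines(rownames(x), paste0(path, ".genes.txt"))
    writeLines(colnames(x), paste0(path, ".samples.txt"))
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Requires `sample_id`, `patient_id`, `tissue` and `status` columns;
#' clinical columns (`center`, `age`, `sex`, `kl`, `osteophyte`, `jsn`) are
#' optional and may contain missing values.
#'
#' @param path TSV path.
#' @return `data.frame` of per-sample metadata.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  meta <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("sample_id", "patient_id", "tissue", "status")
  missing <- setdiff(req, colnames(meta))
  if (length(missing))
    stop(sprintf("metadata lacks required column(s): %s",
                 paste(missing, collapse = ", ")))
  if (anyDuplicated(meta$sample_id))
    stop("duplicate sample_id in metadata")
  meta
}

#' Filter samples by sequencing depth
#'
#' Removes samples whose total counts fall strictly below `low` or strictly
#' above `high` (i.e. the boundary values are kept). Defaults give the
#' 500,000-2,000,000 total-count window used for shallow 3'-counting
#' libraries.
#'
#' @param x count matrix or `SummarizedExperiment` with a `counts` assay.
#' @param low,high inclusive depth window.
#' @return object of the same type restricted to retained samples, order
#'   preserved.
#' @export
filterSamplesByDepth <- function(x, low = 5e5, high = 2e6) {
  stopifnot(low < high)
  m <- .asCountMatrix(x)
  totals <- colSums(m)
  keep <- totals >= low & totals <= high
  if (!any(keep))
    stop("all samples removed by the depth filter (empty cohort)")
  if (is(x, "SummarizedExperiment")) x[, keep] else m[, keep, drop = FALSE]
}

#' Counts-per-million normalization
#'
#' `cpm(g, s) = counts(g, s) / colsum(s) * 1e6`; each output column sums to
#' one million.
#'
#' @param x count matrix or `SummarizedExperiment`.
#' @return numeric CPM matrix (genes x samples).
#' @export
computeCPM <- function(x) {
  m <- .asCountMatrix(x)
  totals <- colSums(m)
  if (any(totals <= 0))
    stop(sprintf("zero-depth sample(s): %s",
                 paste(colnames(m)[totals <= 0], collapse = ", ")))
  sweep(m, 2, totals, "/") * 1e6
}

#' Discard genes that vary in non-OA control samples
#'
#' Removes genes whose sample variance (denominator n-1) of log2(CPM + 1)
#' across the control samples exceeds `maxVariance`; all other genes are
#' retained in order. Filtering noise on healthy tissue removes genes whose
#' variability is not disease-driven.
#'
#' @param cpmMat CPM matrix.
#' @param controlSamples control sample ids (at least 2).
#' @param maxVariance variance ceiling on the log2(CPM + 1) scale.
#' @return CPM matrix restricted to retained genes.
#' @export
filterGenesControlVariance <- function(cpmMat, controlSamples,
                                       maxVariance = 3) {
  controlSamples <- intersect(controlSamples, colnames(cpmMat))
  if (length(controlSamples) < 2)
    stop("at least 2 control samples required (variance undefined)")
  lg <- log2(cpmMat[, controlSamples, drop = FALSE] + 1)
  v <- rowSums((lg - rowMeans(lg))^2) / (ncol(lg) - 1)
  cpmMat[v <= maxVariance, , drop = FALSE]
}

#' Keep genes expressed above a CPM floor in enough OA samples
#'
#' Retains genes with CPM strictly greater than `minCPM` in at least
#' `minSamples` of the given OA samples.
#'
#' @param cpmMat CPM matrix.
#' @param oaSamples OA sample ids to count over.
#' @param minCPM strict CPM floor.
#' @param minSamples minimum number of qualifying OA samples.
#' @return CPM matrix restricted to retained genes.
#' @export
filterGenesMinExpression <- function(cpmMat, oaSamples, minCPM = 5,
                                     minSamples = 15) {
  oaSamples <- intersect(oaSamples, colnames(cpmMat))
  n <- rowSums(cpmMat[, oaSamples, drop = FALSE] > minCPM)
  cpmMat[n >= minSamples, , drop = FALSE]
}

#' Select highly variable genes
#'
#' The `n` genes with the largest standard deviation of log2(CPM + 1)
#' across the given samples; ties broken by gene id so the choice is
#' deterministic. Returned rows are ordered by decreasing standard
#' deviation.
#'
#' @param cpmMat CPM matrix.
#' @param n number of genes to keep.
#' @param samples sample ids over which variability is measured (default:
#'   all columns; pass the OA samples to exclude controls).
#' @return CPM matrix restricted to the selected genes.
#' @export
selectHVG <- function(cpmMat, n = 4000, samples = colnames(cpmMat)) {
  samples <- intersect(samples, colnames(cpmMat))
  if (n > nrow(cpmMat))
    stop(sprintf("n = %d exceeds the %d available genes", n, nrow(cpmMat)))
  lg <- log2(cpmMat[, samples, drop = FALSE] + 1)
  sds <- sqrt(rowSums((lg - rowMeans(lg))^2) / (ncol(lg) - 1))
  ord <- order(-sds, rownames(cpmMat), method = "radix")
  cpmMat[ord[seq_len(n)], , drop = FALSE]
}
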