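# Internal helpers shared across modules.

# Deterministic sub-seed derivation; keeps values inside 32-bit range.
.deriveSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %%
               2147483647)
}

.asCountMatrix <- function(x) {
  if (is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  if (!is.matrix(x)) x <- as.matrix(x)
  x
}

#' Largest-remainder apportionment of patients to subtypes
#'
#' Splits `n` patients over proportions so that every patient lands in
#' exactly one subtype: floors first, then the remaining seats go to the
#' largest fractional remainders (ties to the earlier subtype).
#'
#' @param n number of patients.
#' @param proportions non-negative vector summing to 1.
#' @return integer vector of subtype sizes summing to `n`.
#' @examples
#' subtypeSizes(131, c(0.618, 0.183, 0.076, 0.122))  # 81 24 10 16
#' @export
subtypeSizes <- function(n, proportions) {
  stopifnot(n >= 0, all(proportions >= 0),
            abs(sum(proportions) - 1) <= 1e-9)
  quota <- n * proportions
  sizes <- floor(quota)
  rem <- n - sum(sizes)
  if (rem > 0) {
    frac <- quota - sizes
    take <- order(frac, seq_along(frac), decreasing = c(TRUE, FALSE),
                  method = "radix")[seq_len(rem)]
    sizes[take] <- sizes[take] + 1
  }
  as.integer(sizes)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' from the pair-counting contingency-table form.
#'
#' @param a,b label vectors of equal length.
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0)
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(choose2(tab))
  sumA <- sum(choose2(rowSums(tab)))
  sumB <- sum(choose2(colSums(tab)))
  nPairs <- choose2(sum(tab))
  expected <- sumA * sumB / nPairs
  maxIdx <- (sumA + sumB) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}

#' Composition table of predicted class counts
#'
#' Counts and percentages (one decimal, percent = count/total*100) per class,
#' reporting classes with zero assignments as explicit 0-count rows.
#'
#' @param labels factor or character vector of assigned classes.
#' @param classes full ordered set of classes to report.
#' @return `data.frame` with columns `subtype`, `count`, `percent`.
#' @examples
#' compositionTable(rep(c("C1", "C2", "C4"), c(30, 8, 5)),
#'                  classes = c("C1", "C2", "C3", "C4"))
#' @export
compositionTable <- function(labels, classes = sort(unique(labels))) {
  counts <- table(factor(labels, levels = classes))
  total <- sum(counts)
  data.frame(
    subtype = classes,
    count = as.integer(counts),
    percent = round(as.integer(counts) / total * 100, 1),
    stringsAsFactors = FALSE
  )
}
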