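#' Cochran-Armitage trend test for a 2 x k table with ordered scores
#'
#' With column scores `t_i`, first-row counts `r_i`, column totals `n_i`,
#' `N = sum(n_i)` and pooled proportion `pbar = sum(r_i)/N`, the statistic
#' is `T = sum(t_i (r_i - n_i pbar))` with variance
#' `pbar (1 - pbar) (sum(t_i^2 n_i) - (sum(t_i n_i))^2 / N)`;
#' `Z = T / sqrt(Var)` is compared to the standard normal, two-sided.
#' `Z^2` equals the usual chi-squared trend statistic.
#'
#' @param counts 2 x k matrix of non-negative integers (rows = the two
#'   groups, columns = ordered score categories).
#' @param scores strictly increasing column scores (default: column index
#'   or numeric column names when present).
#' @return list with `T`, `Var`, `Z` and two-sided `p`.
#' @examples
#' tab <- rbind(c(1, 5, 9), c(9, 5, 1))
#' cochranArmitage(tab, scores = c(0, 1, 2))
#' @export
cochranArmitage <- function(counts, scores = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2 || ncol(counts) < 2)
    stop("a 2 x k table with k >= 2 is required")
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  if (any(rowSums(counts) == 0)) stop("both row sums must be positive")
  if (is.null(scores)) {
    scores <- suppressWarnings(as.numeric(colnames(counts)))
    if (anyNA(scores)) scores <- seq_len(ncol(counts))
  }
  if (length(scores) != ncol(counts) || any(diff(scores) <= 0))
    stop("scores must be strictly increasing, one per column")
  r <- counts[1, ]
  n <- colSums(counts)
  N <- sum(n)
  pbar <- sum(r) / N
  Tstat <- sum(scores * (r - n * pbar))
  Var <- pbar * (1 - pbar) * (sum(scores^2 * n) - sum(scores * n)^2 / N)
  if (Var <= 0)
    stop("degenerate table: zero trend variance (all mass in one column?)")
  Z <- Tstat / sqrt(Var)
  list(T = Tstat, Var = Var, Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when the pooled size is at most 12 and no ties are
#' present; otherwise the tie-corrected normal approximation with
#' continuity correction. Two-sided.
#'
#' @param x,y numeric vectors.
#' @return list with `U` (Mann-Whitney statistic for `x`) and `p`.
#' @export
wilcoxonRankSum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12) && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, conf.int = FALSE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher's exact test for contingency tables
#'
#' Exact two-sided p for 2 x 2 tables (summing hypergeometric point
#' probabilities not exceeding the observed one); larger tables are
#' handled by a seeded Monte Carlo estimate.
#'
#' @param counts contingency table of non-negative integers.
#' @param seed seed for the Monte Carlo branch (tables larger than 2 x 2).
#' @param B Monte Carlo replicates.
#' @return two-sided p-value.
#' @export
fisherExact <- function(counts, seed = 1L, B = 1e5) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  if (nrow(counts) == 2 && ncol(counts) == 2) {
    fisher.test(counts)$p.value
  } else {
    set.seed(as.integer(seed))
    fisher.test(counts, simulate.p.value = TRUE, B = B)$p.value
  }
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up procedure: ascending p-values get `q_(i) = min_{j >= i}
#' p_(j) m / j`, clipped at 1, returned in the input order.
#'
#' @param p p-values in \[0, 1\].
#' @return adjusted values, same length and order.
#' @export
bhFDR <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Clinical-score distributions and pairwise trend tests per subtype
#'
#' For each subtype: category percentages for binned age, KL grade,
#' osteophyte score (0-12) and JSN score (0-6). For each score: all
#' pairwise Cochran-Armitage trend tests between subtypes over the observed
#' ordered categories (native score values; age uses bin indices), with
#' Benjamini-Hochberg FDR within each score's family of pairwise tests.
#' Degenerate pairs (zero trend variance) are reported with NA.
#'
#' @param meta sample metadata with `patient_id` plus clinical columns
#'   (`age`, `kl`, `osteophyte`, `jsn`); one row per patient is used.
#' @param labels named subtype labels per patient.
#' @param ageBreaks cut points for age binning.
#' @return list with `distributions` (per score, `data.frame` of
#'   percentages per subtype; rows sum to 100) and `tests`
#'   (`data.frame`: score, group1, group2, Z, p, fdr).
#' @export
subtypeClinicalReport <- function(meta, labels,
                                  ageBreaks = c(-Inf, 60, 65, 70, 75, Inf)) {
  pats <- intersect(names(labels), meta$patient_id)
  if (!length(pats)) stop("labels do not cover any metadata patient")
  one <- meta[match(pats, meta$patient_id), , drop = FALSE]
  lab <- as.character(labels[pats])
  subtypes <- sort(unique(lab))
  scoreOf <- list(
    age = as.integer(cut(one$age, breaks = ageBreaks, right = FALSE)),
    kl = one$kl, osteophyte = one$osteophyte, jsn = one$jsn)
  distributions <- list()
  tests <- list()
  for (sc in names(scoreOf)) {
    v <- scoreOf[[sc]]
    ok <- !is.na(v)
    cats <- sort(unique(v[ok]))
    tab <- t(vapply(subtypes, function(s) {
      x <- v[ok & lab == s]
      cnt <- vapply(cats, function(cc) sum(x == cc), integer(1))
      if (sum(cnt) == 0) rep(NA_real_, length(cats))
      else cnt / sum(cnt) * 100
    }, numeric(length(cats))))
    colnames(tab) <- as.character(cats)
    distributions[[sc]] <- as.data.frame(tab)
    prs <- utils::combn(subtypes, 2, simplify = FALSE)
    fam <- do.call(rbind, lapply(prs, function(pr) {
      cmat <- rbind(
        vapply(cats, function(cc) sum(v[ok] == cc & lab[ok] == pr[1]),
               integer(1)),
        vapply(cats, function(cc) sum(v[ok] == cc & lab[ok] == pr[2]),
               integer(1)))
      res <- tryCatch(cochranArmitage(cmat, scores = as.numeric(cats)),
                      error = function(e) list(Z = NA_real_, p = NA_real_))
      data.frame(score = sc, group1 = pr[1], group2 = pr[2],
                 Z = res$Z, p = res$p, stringsAsFactors = FALSE)
    }))
    fam$fdr <- NA_real_
    okP <- !is.na(fam$p)
    fam$fdr[okP] <- p.adjust(fam$p[okP], method = "BH")
    tests[[sc]] <- fam
  }
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(distributions = distributions, tests = tests)
}
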