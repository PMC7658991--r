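#' Evaluate one ligand-receptor pair for a directed tissue pair
#'
#' A patient is evaluable when sampled in both tissues; the pair counts as
#' co-expressed in a patient when the ligand's CPM in the source tissue and
#' the receptor's CPM in the target tissue both reach `tauExpr`. The
#' occurrence ratio (OR) is the fraction of evaluable patients with
#' co-expression; it is flagged undefined (NA) when no patient is
#' evaluable, never treated as 0.
#'
#' @param cpmSource,cpmTarget CPM matrices of the source/target tissue with
#'   patient ids as column names.
#' @param ligand,receptor gene ids.
#' @param patients patient ids of the subtype under consideration.
#' @param tauExpr CPM threshold for "expressed" (default 1 CPM).
#' @return list with `indicator` (named logical over evaluable patients),
#'   `n_evaluable`, `n_expressed`, and `occurrence_ratio`.
#' @export
evaluatePair <- function(cpmSource, cpmTarget, ligand, receptor, patients,
                         tauExpr = 1.0) {
  if (!ligand %in% rownames(cpmSource))
    stop(sprintf("gene '%s' absent from the source tissue matrix", ligand))
  if (!receptor %in% rownames(cpmTarget))
    stop(sprintf("gene '%s' absent from the target tissue matrix", receptor))
  ev <- intersect(intersect(patients, colnames(cpmSource)),
                  colnames(cpmTarget))
  if (!length(ev))
    return(list(indicator = logical(0), n_evaluable = 0L,
                n_expressed = 0L, occurrence_ratio = NA_real_))
  ind <- (cpmSource[ligand, ev] >= tauExpr) &
         (cpmTarget[receptor, ev] >= tauExpr)
  names(ind) <- ev
  list(indicator = ind, n_evaluable = length(ev),
       n_expressed = sum(ind), occurrence_ratio = mean(ind))
}

#' Score every ligand-receptor pair for one subtype and tissue direction
#'
#' Computes the occurrence ratio of each database pair over the subtype's
#' evaluable patients (those sampled in both tissues) and marks a pair
#' "expressed" when its OR reaches `minORExpressed`. When no patient is
#' evaluable the result is returned flagged empty with undefined counts.
#'
#' @param cpmByTissue named list of CPM matrices with patient-id columns.
#' @param patients patient ids belonging to the subtype.
#' @param db ligand-receptor `data.frame` (`ligand`, `receptor`).
#' @param source,target tissue names (ligand and receptor side).
#' @param subtype label recorded in the result.
#' @param tauExpr per-patient CPM threshold.
#' @param minORExpressed OR threshold for an "expressed" pair.
#' @return a [CrosstalkResult-class].
#' @export
countExpressedPairs <- function(cpmByTissue, patients, db, source, target,
                                subtype = "all", tauExpr = 1.0,
                                minORExpressed = 0.5) {
  stopifnot(all(c("ligand", "receptor") %in% colnames(db)))
  if (!source %in% names(cpmByTissue) || !target %in% names(cpmByTissue))
    stop(sprintf("tissue matrices missing for direction %s -> %s",
                 source, target))
  S <- cpmByTissue[[source]]
  T_ <- cpmByTissue[[target]]
  missL <- setdiff(db$ligand, rownames(S))
  if (length(missL))
    stop(sprintf("gene '%s' absent from tissue '%s'", missL[1], source))
  missR <- setdiff(db$receptor, rownames(T_))
  if (length(missR))
    stop(sprintf("gene '%s' absent from tissue '%s'", missR[1], target))
  ev <- intersect(intersect(patients, colnames(S)), colnames(T_))
  if (!length(ev)) {
    pairs <- data.frame(ligand = db$ligand, receptor = db$receptor,
                        n_evaluable = 0L, n_expressed = NA_integer_,
                        occurrence_ratio = NA_real_, expressed = NA,
                        high = NA, stringsAsFactors = FALSE)
    return(new("CrosstalkResult", subtype = subtype, source = source,
               target = target, pairs = pairs, nEvaluable = 0L,
               expressedPairs = 0L, highPairs = 0L, empty = TRUE))
  }
  ind <- (S[db$ligand, ev, drop = FALSE] >= tauExpr) &
         (T_[db$receptor, ev, drop = FALSE] >= tauExpr)
  orv <- rowMeans(ind)
  expressed <- orv >= minORExpressed
  pairs <- data.frame(ligand = db$ligand, receptor = db$receptor,
                      n_evaluable = length(ev),
                      n_expressed = as.integer(rowSums(ind)),
                      occurrence_ratio = unname(orv),
                      expressed = unname(expressed), high = FALSE,
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("CrosstalkResult", subtype = subtype, source = source,
      target = target, pairs = pairs, nEvaluable = length(ev),
      expressedPairs = as.integer(sum(expressed)), highPairs = 0L,
      empty = FALSE)
}

#' Mark highly expressed ligand-receptor pairs
#'
#' A pair is "high" when it is expressed and its occurrence ratio reaches
#' `tauOR`; `highPairs` counts them. Lowering `tauOR` never decreases the
#' count.
#'
#' @param result a [CrosstalkResult-class] with computed ORs.
#' @param tauOR high-OR threshold.
#' @return the result with the `high` flags and `highPairs` updated.
#' @export
selectHighPairs <- function(result, tauOR = 0.9) {
  stopifnot(is(result, "CrosstalkResult"))
  if (result@empty) return(result)
  high <- result@pairs$expressed & result@pairs$occurrence_ratio >= tauOR
  result@pairs$high <- high
  result@highPairs <- as.integer(sum(high))
  result
}

#' Tissue-crosstalk network for one subtype
#'
#' Directed weighted graph over the three joint tissues: one edge per
#' directed tissue pair (self-loops included), weighted by the number of
#' highly expressed ligand-receptor pairs in that direction. Directions
#' with no evaluable patients get an NA weight rather than 0.
#'
#' @param results list of [CrosstalkResult-class] for one subtype (up to
#'   nine directions).
#' @return edge-list `data.frame` with columns `source`, `target`,
#'   `weight`, `evaluable`.
#' @export
buildNetwork <- function(results) {
  stopifnot(length(results) > 0,
            all(vapply(results, is, TRUE, "CrosstalkResult")))
  edges <- do.call(rbind, lapply(results, function(r)
    data.frame(source = r@source, target = r@target,
               weight = if (r@empty) NA_integer_ else r@highPairs,
               evaluable = r@nEvaluable, stringsAsFactors = FALSE)))
  rownames(edges) <- NULL
  edges
}

#' Over-representation of crosstalk genes in gene sets
#'
#' The query is the union of ligand and receptor genes of the highly
#' expressed pairs; each set is scored by the one-sided hypergeometric
#' tail probability P(X >= overlap) against the background universe, with
#' Benjamini-Hochberg FDR across sets.
#'
#' @param highPairs `data.frame` of high pairs (columns `ligand`,
#'   `receptor`) or a [CrosstalkResult-class].
#' @param genesets named list of gene-id vectors.
#' @param background gene universe (must contain the query genes).
#' @return `data.frame` (set, set_size, overlap, p, fdr) sorted by p.
#' @export
enrichCrosstalkGenes <- function(highPairs, genesets, background) {
  if (is(highPairs, "CrosstalkResult"))
    highPairs <- highPairs@pairs[which(highPairs@pairs$high), , drop = FALSE]
  query <- unique(c(highPairs$ligand, highPairs$receptor))
  if (!length(query)) stop("empty query: no highly expressed pairs")
  background <- unique(background)
  if (!all(query %in% background))
    stop("background must contain every query gene")
  N <- length(background)
  q <- length(query)
  res <- do.call(rbind, lapply(names(genesets), function(nm) {
    s <- intersect(unique(genesets[[nm]]), background)
    k <- length(intersect(s, query))
    p <- phyper(k - 1, length(s), N - length(s), q, lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  res$fdr <- p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set, method = "radix"), ]
  rownames(res) <- NULL
  res
}
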