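## Evaluation: counting significant LEDs per correction method, matching a
## ranked LED list against a clinical-association knowledge base, ROC/PR
## summaries and top-k Fisher enrichment.

#' Count significant LEDs under each correction method
#'
#' Applies, to one test result table, the pooled Storey-Tibshirani
#' q-values, Benjamini-Hochberg, Bonferroni and Holm corrections and the
#' covariate-weighted BH at level `alpha`, plus the grouped local-FDR
#' calling at the conventional ranking gates (p < `maxP`, local FDR <=
#' `maxLfdr`, |delta| > `minAbsDelta`), and reports the number of
#' significant pairs for each. Deterministic given the table.
#'
#' @param testTable data.frame from [moderatedTTest()] or [anovaTest()].
#' @param alpha FDR level for the q-value/BH-family methods (default 0.20,
#'   the customary screen-wide reporting level).
#' @param maxP,maxLfdr,minAbsDelta gates for the grouped local-FDR calling
#'   (defaults 0.05, 0.6, 2).
#' @param minGroupTests passed to [groupedLocalFdr()] and [covariateBH()].
#' @return data.frame with columns `method` and `n_significant`.
#' @export
compareMethods <- function(testTable, alpha = 0.20,
                           maxP = 0.05, maxLfdr = 0.6, minAbsDelta = 2,
                           minGroupTests = 50L) {
  usable <- !is.na(testTable$p_value) &
    !(if ("skipped" %in% names(testTable)) testTable$skipped else FALSE)
  p <- testTable$p_value[usable]
  q <- storeyQvalues(p)
  counts <- c(
    storey_q = sum(q <= alpha),
    bh = unname(classicalCorrections(p, "bh", alpha)$n_significant_at),
    bonferroni = unname(classicalCorrections(p, "bonferroni",
                                             alpha)$n_significant_at),
    holm = unname(classicalCorrections(p, "holm", alpha)$n_significant_at),
    covariate_bh = unname(covariateBH(testTable, alpha = alpha,
                                      minGroupTests = minGroupTests
                                      )$n_significant_at))
  withLfdr <- groupedLocalFdr(testTable, minGroupTests = minGroupTests)
  counts <- c(counts,
              grouped_lfdr = nrow(callLeds(withLfdr, maxP = maxP,
                                           maxLfdr = maxLfdr,
                                           minAbsDelta = minAbsDelta)))
  data.frame(method = names(counts), n_significant = as.integer(counts),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Label ranked LEDs against a clinical-association knowledge base
#'
#' An LED is a true positive when some knowledge-base row for the disease
#' has the LED's biomarker gene as its biomarker and the LED's essential
#' gene as its target -- or, when an edge list is supplied, a target that
#' is a direct neighbour of the essential gene at the configured score
#' (pathway expansion).
#'
#' @param leds data.frame with columns `biomarker`, `knockout` (ranked or
#'   not).
#' @param kb data.frame from [readKnowledgeBase()], already filtered by the
#'   caller to the disease and its synonyms via the `disease` column match
#'   below.
#' @param disease disease label to select from `kb$disease` (exact match);
#'   synonym expansion is the caller's responsibility.
#' @param edges optional edge list for pathway expansion (see
#'   [readEdgeList()]).
#' @param evidenceLevels optional subset of evidence levels to use (e.g.
#'   `c("A", "B")`).
#' @param minScore edge score threshold for expansion (default 400).
#' @return logical vector of labels, one per LED row.
#' @export
matchKnowledgeBase <- function(leds, kb, disease, edges = NULL,
                               evidenceLevels = NULL, minScore = 400) {
  sel <- kb$disease == disease
  if (!is.null(evidenceLevels)) sel <- sel & kb$evidence_level %in% evidenceLevels
  if ("complete" %in% names(kb)) sel <- sel & kb$complete
  kb <- kb[sel, , drop = FALSE]
  if (!nrow(kb)) {
    warning("knowledge base empty after filtering: all labels negative")
    return(rep(FALSE, nrow(leds)))
  }
  direct <- paste(leds$biomarker, leds$knockout, sep = "\r") %in%
    paste(kb$biomarker_gene, kb$target_gene, sep = "\r")
  if (is.null(edges)) return(direct)
  ed <- edges[edges$combined_score >= minScore, , drop = FALSE]
  adj <- unique(rbind(data.frame(a = ed$gene_a, b = ed$gene_b),
                      data.frame(a = ed$gene_b, b = ed$gene_a)))
  out <- direct
  for (i in which(!direct)) {
    nbr <- adj$b[adj$a == leds$knockout[i]]
    out[i] <- any(kb$biomarker_gene == leds$biomarker[i] &
                    kb$target_gene %in% nbr)
  }
  out
}

#' ROC and precision-recall summaries for a ranked labelling
#'
#' AUROC is computed by the rank (Wilcoxon) statistic with ties averaged
#' -- equal to the probability that a random positive outscores a random
#' negative, counting ties as 1/2 -- and AUPR by step interpolation
#' (average precision), walking distinct score levels from best to worst.
#' Higher scores must rank first; pass e.g. `-p_value` for p-value
#' rankings.
#'
#' @param labels logical (or 0/1) vector; needs at least one positive and
#'   one negative.
#' @param scoresVec numeric ranking scores, larger = more confident.
#' @return list with `auroc`, `aupr`, `roc` (data.frame fpr/tpr) and `pr`
#'   (data.frame recall/precision) curve points.
#' @export
rocPr <- function(labels, scoresVec) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(scoresVec), !anyNA(labels),
            !anyNA(scoresVec))
  nPos <- sum(labels); nNeg <- sum(!labels)
  if (nPos == 0L || nNeg == 0L)
    stop("need at least one positive and one negative label", call. = FALSE)
  r <- rank(scoresVec)
  auroc <- (sum(r[labels]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
  o <- order(scoresVec, decreasing = TRUE)
  lab <- labels[o]; sc <- scoresVec[o]
  last <- cumsum(rle(sc)$lengths)      # indices ending each score level
  tp <- cumsum(lab)[last]; fp <- cumsum(!lab)[last]
  roc <- data.frame(fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos))
  rec <- tp / nPos
  prec <- tp / (tp + fp)
  aupr <- sum(diff(c(0, rec)) * prec)
  list(auroc = auroc, aupr = aupr, roc = roc,
       pr = data.frame(recall = rec, precision = prec))
}

#' Fisher exact enrichment of a 2x2 contingency table
#'
#' Exact hypergeometric tail probability (and conditional odds ratio) for
#' a table of counts, typically top-k-in-knowledge-base vs rest, as used
#' to compare two method rankings of equal length.
#'
#' @param a,b,c,d non-negative integer cells: top-k in KB, top-k not in KB,
#'   rest in KB, rest not in KB.
#' @param alternative `"greater"` (default; enrichment) or `"two_sided"`.
#' @return list with `odds_ratio` and `p_value`.
#' @examples
#' fisherEnrichment(17, 483, 1, 499)  # p ~ 6.4e-5
#' @export
fisherEnrichment <- function(a, b, c, d,
                             alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("cells must be non-negative integers", call. = FALSE)
  ft <- stats::fisher.test(matrix(cells, 2L, 2L, byrow = TRUE),
                           alternative = sub("_", ".", alternative))
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value)
}

#' Top-k enrichment of one ranking against a knowledge base
#'
#' Convenience wrapper building the 2x2 table for the top `k` of a ranked,
#' labelled LED list against the remainder of the ranking universe and
#' testing enrichment with [fisherEnrichment()]. The default universe is
#' `2 * k` (two method rankings of length `k` compared head-to-head);
#' override with `universe`.
#'
#' @param labels logical labels in ranking order (best first).
#' @param k size of the top list.
#' @param universe total number of ranked hypotheses considered (default
#'   `2 * k`); `labels` beyond `universe` are ignored, and missing tail
#'   labels are treated as negative.
#' @return list with the table cells `a`, `b`, `c`, `d`, `odds_ratio` and
#'   `p_value` (alternative `"greater"`).
#' @export
topkEnrichment <- function(labels, k, universe = 2L * k) {
  labels <- as.logical(labels)
  if (k < 1L || universe < k) stop("need 1 <= k <= universe", call. = FALSE)
  lab <- rep(FALSE, universe)
  lab[seq_len(min(length(labels), universe))] <-
    labels[seq_len(min(length(labels), universe))]
  a <- sum(lab[seq_len(k)]); b <- k - a
  c <- sum(lab[-seq_len(k)]); d <- (universe - k) - c
  c(list(a = a, b = b, c = c, d = d), fisherEnrichment(a, b, c, d))
}
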