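## LED calling: threshold gates on the corrected test table, sign-based
## classification into positive/negative/dual dependencies, and the
## optional relation filter against a scored gene-gene edge list.

.ledOrder <- function(p, delta, biomarker, knockout)
  order(p, -abs(delta), biomarker, knockout)

#' Call lethal dependencies from a corrected test table
#'
#' Keeps pairs with `p_value < maxP`, `lfdr <= maxLfdr` and
#' `|delta| > minAbsDelta` (all three gates strict or inclusive exactly as
#' written), then ranks by p ascending with ties broken by `|delta|`
#' descending, then biomarker and knockout ids. The default gates
#' (p < 0.05, local FDR <= 0.6, |delta| > 2) are the conventional ranking
#' thresholds for DEMETER-scale screens.
#'
#' @param testTable data.frame with columns `knockout`, `biomarker`,
#'   `delta`, `t_stat`, `p_value` and `lfdr` (see [groupedLocalFdr()]).
#' @param maxP keep rows with p-value strictly below this (default 0.05).
#' @param maxLfdr keep rows with local FDR at or below this (default 0.6).
#' @param minAbsDelta keep rows with `|delta|` strictly above this
#'   (default 2).
#' @return data.frame of called LEDs with the input columns plus `rank`;
#'   zero rows when nothing passes.
#' @seealso [classifyLeds()], [relationFilter()]
#' @export
callLeds <- function(testTable, maxP = 0.05, maxLfdr = 0.6, minAbsDelta = 2) {
  for (th in c(maxP, maxLfdr, minAbsDelta))
    if (length(th) != 1L || is.na(th) || th <= 0)
      stop("thresholds must be positive", call. = FALSE)
  stopifnot(all(c("knockout", "biomarker", "delta", "p_value", "lfdr")
                %in% names(testTable)))
  keep <- !is.na(testTable$p_value) & !is.na(testTable$lfdr) &
    testTable$p_value < maxP & testTable$lfdr <= maxLfdr &
    abs(testTable$delta) > minAbsDelta
  out <- testTable[keep, , drop = FALSE]
  out <- out[.ledOrder(out$p_value, out$delta, out$biomarker, out$knockout), ,
             drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify called LEDs as positive, negative or dual dependencies
#'
#' A record with `delta < 0` (mutants more sensitive to the knockout) is a
#' positive lethal dependency (pLED); `delta > 0` (mutants protected) a
#' negative one (nLED). A biomarker whose called records span both signs
#' forms a dual lethal dependency (dLED): its alteration marks sensitivity
#' to one knockout and resistance to another, and all its records are
#' promoted to `led_type = "dLED"` while keeping their sign class in
#' `sign_class`.
#'
#' @param leds data.frame from [callLeds()]; all `delta` must be non-zero.
#' @return `leds` with columns `sign_class` (`"pLED"`/`"nLED"`), `led_type`
#'   (`"pLED"`, `"nLED"` or `"dLED"`) and `dual` (logical), plus an
#'   attribute `"dualBiomarkers"` naming the dual biomarkers.
#' @export
classifyLeds <- function(leds) {
  if (!nrow(leds)) {
    leds$sign_class <- character(0); leds$led_type <- character(0)
    leds$dual <- logical(0)
    attr(leds, "dualBiomarkers") <- character(0)
    return(leds)
  }
  if (any(leds$delta == 0))
    stop("delta = 0 record cannot be classified; apply the |delta| gate first",
         call. = FALSE)
  leds$sign_class <- ifelse(leds$delta < 0, "pLED", "nLED")
  bySign <- table(leds$biomarker, leds$sign_class)
  duals <- rownames(bySign)[apply(bySign > 0, 1L, all)]
  if (ncol(bySign) < 2L) duals <- character(0)
  leds$dual <- leds$biomarker %in% duals
  leds$led_type <- ifelse(leds$dual, "dLED", leds$sign_class)
  attr(leds, "dualBiomarkers") <- duals
  leds
}

.edgeKeys <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

#' Filter LEDs by annotated gene-gene relations
#'
#' Retains LEDs whose biomarker and essential (knockout) gene are related
#' in a scored edge list: in `"direct"` mode the pair itself must have an
#' edge with `combined_score >= minScore` (inclusive); in
#' `"shared_neighbor"` mode a pair also passes when both genes have an
#' edge at that score to a common third gene. Self-pairs (biomarker equal
#' to the essential gene) always pass. Every record gets a
#' `relation_supported` flag; only supported records are returned.
#'
#' @param leds data.frame of called LEDs (columns `biomarker`, `knockout`).
#' @param edges data.frame with columns `gene_a`, `gene_b`,
#'   `combined_score` (see [readEdgeList()]); undirected.
#' @param minScore minimum combined score (default 400, the conventional
#'   medium-confidence cutoff on the 0-1000 scale).
#' @param mode `"direct"` (default) or `"shared_neighbor"`.
#' @return The supported subset of `leds`, with `relation_supported` set;
#'   the full flagged table is attached as attribute `"flagged"`.
#' @export
relationFilter <- function(leds, edges, minScore = 400,
                           mode = c("direct", "shared_neighbor")) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_a", "gene_b", "combined_score") %in% names(edges)))
  ed <- edges[edges$combined_score >= minScore, , drop = FALSE]
  if (!nrow(ed) && nrow(leds))
    warning("no edges at or above the score threshold: only self-pairs pass")
  keys <- unique(.edgeKeys(ed$gene_a, ed$gene_b))
  selfPair <- leds$biomarker == leds$knockout
  supported <- selfPair |
    .edgeKeys(leds$biomarker, leds$knockout) %in% keys
  if (mode == "shared_neighbor" && nrow(ed)) {
    nbrs <- function(g) {
      out <- c(ed$gene_b[ed$gene_a == g], ed$gene_a[ed$gene_b == g])
      setdiff(unique(out), g)
    }
    todo <- which(!supported)
    for (i in todo)
      if (length(intersect(nbrs(leds$biomarker[i]), nbrs(leds$knockout[i]))))
        supported[i] <- TRUE
  }
  leds$relation_supported <- supported
  out <- leds[supported, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flagged") <- leds
  out
}

#' Write a called-LED table to TSV
#'
#' Column layout mirrors the conventional ranking table: biomarker,
#' essential gene, increment of essentiality, t-score, p-value, local FDR,
#' LED type and (when present) relation support.
#'
#' @param leds data.frame from [classifyLeds()] (optionally after
#'   [relationFilter()]).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeLedTable <- function(leds, path) {
  cols <- c(biomarker = "biomarker", essential_gene = "knockout",
            increment_of_essentiality = "delta", t_score = "t_stat",
            p_value = "p_value", local_fdr = "lfdr", led_type = "led_type",
            rank = "rank")
  out <- data.frame(lapply(cols[cols %in% names(leds)],
                           function(cc) leds[[cc]]),
                    stringsAsFactors = FALSE)
  names(out) <- names(cols)[cols %in% names(leds)]
  if ("relation_supported" %in% names(leds))
    out$relation_supported <- leds$relation_supported
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export called LEDs as a bipartite variant-knockout graph (JSON)
#'
#' Nodes are gene variants (biomarkers) and knockouts; an edge links a
#' variant to a knockout whose essentiality it marks, signed by the
#' direction of the dependency. The JSON layout (`nodes` with `id` and
#' `kind`, `edges` with `source`, `target`, `delta`, `led_type`) is meant
#' for external network-visualisation tools.
#'
#' @param leds data.frame from [classifyLeds()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
exportBipartiteGraph <- function(leds, path) {
  bm <- unique(leds$biomarker)
  kn <- unique(leds$knockout)
  nodes <- data.frame(id = c(bm, kn),
                      kind = rep(c("variant", "knockout"),
                                 c(length(bm), length(kn))),
                      stringsAsFactors = FALSE)
  edges <- data.frame(source = leds$biomarker, target = leds$knockout,
                      delta = leds$delta,
                      led_type = if ("led_type" %in% names(leds))
                        leds$led_type else NA_character_,
                      stringsAsFactors = FALSE)
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}
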