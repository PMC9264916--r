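## Preprocessing: nearest-neighbour imputation of essentiality scores,
## variant dichotomization, and sample alignment across data types.

#' Impute missing essentiality scores by nearest-neighbour averaging
#'
#' Fills each missing entry with the mean, over the `k` nearest knockout
#' rows, of their observed values in that column. Row-row distance is the
#' root mean squared difference over columns observed in both rows (i.e.
#' squared Euclidean distance rescaled by the fraction of co-observed
#' columns), so rows with few shared measurements are not unfairly
#' favoured. Rows sharing no observed column with the target row are
#' excluded as neighbours. If none of the `k` neighbours is observed in the
#' target column, the row mean of the target row is used instead.
#'
#' @param M an [EssentialityMatrix-class]; every row must have at least one
#'   observed entry.
#' @param k number of neighbour rows to average (default 10); values larger
#'   than `nrow(M) - 1` are clamped with a warning.
#' @return An [EssentialityMatrix-class] with no missing entries; observed
#'   entries are unchanged.
#' @examples
#' m <- matrix(c(1, 2, NA, 1.1, 2.1, 3, 5, 6, 7), 3, byrow = TRUE,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
#' scores(knnImpute(EssentialityMatrix(m), k = 1))
#' @export
knnImpute <- function(M, k = 10L) {
  stopifnot(is(M, "EssentialityMatrix"))
  v <- scores(M)
  if (!anyNA(v)) return(M)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer", call. = FALSE)
  obs <- !is.na(v)
  allMissing <- rowSums(obs) == 0L
  if (any(allMissing))
    stop("row(s) with all entries missing: ",
         paste(utils::head(rownames(v)[allMissing], 5L), collapse = ", "),
         call. = FALSE)
  if (k > nrow(v) - 1L) {
    warning(sprintf("k = %d exceeds available neighbours; clamped to %d",
                    k, nrow(v) - 1L))
    k <- nrow(v) - 1L
  }
  rowMean <- rowMeans(v, na.rm = TRUE)
  out <- v
  for (i in which(rowSums(!obs) > 0L)) {
    d <- .rowDistances(v, obs, i)
    ord <- order(d, seq_along(d))          # deterministic tie-break by index
    nbr <- ord[is.finite(d[ord])]
    nbr <- utils::head(nbr, k)
    for (j in which(!obs[i, ])) {
      vals <- v[nbr, j]
      vals <- vals[!is.na(vals)]
      out[i, j] <- if (length(vals)) mean(vals) else rowMean[i]
    }
  }
  initialize(M, values = out)
}

# distances from row i to all rows: RMS difference over co-observed columns;
# Inf for self and for rows with no co-observed column
.rowDistances <- function(v, obs, i) {
  co <- obs %*% obs[i, ]                       # co-observed column counts
  diffs <- sweep(v, 2L, v[i, ])
  diffs[!obs | !matrix(obs[i, ], nrow(v), ncol(v), byrow = TRUE)] <- 0
  d <- sqrt(rowSums(diffs^2) / pmax(co, 1L))
  d[co == 0L] <- Inf
  d[i] <- Inf
  as.vector(d)
}

.variantClasses <- c("missense", "nonsense", "frameshift", "splice",
                     "silent", "noncoding", "other")

#' Dichotomize a variant table into a binary mutation matrix
#'
#' A sample is called mutant (1) for a gene if at least one of its variant
#' rows for that gene survives the filters; repeated qualifying variants
#' still give 1. The filters mirror common cell-line panel curation:
#' minimum allelic fraction, and exclusion of silent, non-coding, common
#' polymorphism and putative-neutral variants.
#'
#' @param variants data.frame as returned by [readVariantTable()].
#' @param genes,samples the gene and sample universes; the output matrix is
#'   dense over `genes x samples`.
#' @param minAllelicFraction drop variants with allelic fraction strictly
#'   below this (default 0.1); variants with missing fraction are kept.
#' @param excludeSilent,excludeNoncoding,excludeCommon,excludeNeutral
#'   logical filter switches, all TRUE by default.
#' @return A [MutationMatrix-class] of dimension
#'   `length(genes) x length(samples)`.
#' @export
dichotomizeVariants <- function(variants, genes, samples,
                                minAllelicFraction = 0.1,
                                excludeSilent = TRUE,
                                excludeNoncoding = TRUE,
                                excludeCommon = TRUE,
                                excludeNeutral = TRUE) {
  genes <- as.character(genes)
  samples <- as.character(samples)
  ind <- matrix(0, length(genes), length(samples),
                dimnames = list(genes, samples))
  if (nrow(variants)) {
    vc <- as.character(variants$variant_class)
    unknown <- !(vc %in% .variantClasses)
    if (any(unknown)) {
      warning(sprintf("%d variant(s) with unknown class (%s) treated as 'other'",
                      sum(unknown),
                      paste(utils::head(unique(vc[unknown]), 3L),
                            collapse = ", ")))
      vc[unknown] <- "other"
    }
    keep <- rep(TRUE, nrow(variants))
    af <- variants$allelic_fraction
    keep <- keep & (is.na(af) | af >= minAllelicFraction)
    if (excludeSilent) keep <- keep & vc != "silent"
    if (excludeNoncoding) keep <- keep & vc != "noncoding"
    if (excludeCommon) keep <- keep & !variants$common
    if (excludeNeutral) keep <- keep & !variants$neutral
    keep <- keep & variants$gene %in% genes & variants$sample_id %in% samples
    if (any(keep))
      ind[cbind(match(variants$gene[keep], genes),
                match(variants$sample_id[keep], samples))] <- 1
  }
  MutationMatrix(ind)
}

#' Align essentiality, mutation and expression data on shared cell lines
#'
#' Restricts all matrices to the intersection of their sample ids (in the
#' essentiality matrix's column order) and prunes cohort memberships to the
#' surviving samples. Sample ids are matched case-sensitively after
#' whitespace trimming. Dropped samples are reported via `message()` and in
#' the returned `dropped` element.
#'
#' @param D an [EssentialityMatrix-class].
#' @param M a [MutationMatrix-class].
#' @param X an [ExpressionMatrix-class], or NULL to skip.
#' @param cohorts a [CohortSpec-class] or list of them, or NULL.
#' @return list with elements `D`, `M`, `X`, `cohorts` (same shapes as the
#'   inputs, restricted to shared samples) and `dropped` (named list of
#'   sample ids removed from each input).
#' @export
alignSamples <- function(D, M, X = NULL, cohorts = NULL) {
  stopifnot(is(D, "EssentialityMatrix"), is(M, "MutationMatrix"))
  trimIds <- function(x) {
    colnames(x@values) <- trimws(colnames(x@values))
    x
  }
  D <- trimIds(D); M <- trimIds(M)
  if (!is.null(X)) X <- trimIds(X)
  shared <- intersect(sampleIds(D), sampleIds(M))
  if (!is.null(X)) shared <- intersect(shared, sampleIds(X))
  if (!length(shared))
    stop("no shared sample ids across the inputs", call. = FALSE)
  shared <- sampleIds(D)[sampleIds(D) %in% shared]  # keep D's column order
  dropped <- list(D = setdiff(sampleIds(D), shared),
                  M = setdiff(sampleIds(M), shared),
                  X = if (is.null(X)) character() else
                    setdiff(sampleIds(X), shared))
  for (nm in names(dropped))
    if (length(dropped[[nm]]))
      message(sprintf("alignSamples: dropped from %s: %s", nm,
                      paste(dropped[[nm]], collapse = ", ")))
  single <- !is.null(cohorts) && is(cohorts, "CohortSpec")
  if (single) cohorts <- list(cohorts)
  if (!is.null(cohorts)) {
    cohorts <- lapply(cohorts, function(cs) {
      lost <- setdiff(c(cs@memberSamples, cs@otherSamples), shared)
      if (length(lost))
        warning(sprintf("cohort '%s': pruned sample(s) not in aligned data: %s",
                        cs@tumorLabel, paste(lost, collapse = ", ")))
      mem <- intersect(cs@memberSamples, shared)
      if (!length(mem))
        stop(sprintf("cohort '%s' has no samples left after alignment",
                     cs@tumorLabel), call. = FALSE)
      CohortSpec(cs@tumorLabel, mem, intersect(cs@otherSamples, shared))
    })
    if (single) cohorts <- cohorts[[1L]]
  }
  list(D = D[, shared], M = M[, shared],
       X = if (is.null(X)) NULL else X[, shared],
       cohorts = cohorts, dropped = dropped)
}
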