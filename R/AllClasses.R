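#' @import methods
NULL

.checkIds <- function(ids, what) {
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    return(sprintf("duplicated %s id(s): %s", what,
                   paste(utils::head(dup, 5L), collapse = ", ")))
  }
  if (any(is.na(ids)) || any(!nzchar(ids)))
    return(sprintf("empty or NA %s id(s)", what))
  NULL
}

#' ScreenMatrix: shared representation of gene-by-sample matrices
#'
#' Virtual parent of [EssentialityMatrix-class], [MutationMatrix-class] and
#' [ExpressionMatrix-class]. Row and column identities live in the dimnames
#' of the `values` slot; subclasses add constraints on the entries.
#'
#' @slot values numeric matrix with unique, non-empty dimnames.
#' @name ScreenMatrix-class
#' @aliases ScreenMatrix
#' @exportClass ScreenMatrix
setClass("ScreenMatrix", representation("VIRTUAL", values = "matrix"),
         validity = function(object) {
  v <- object@values
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("matrix must carry row (gene) and column (sample) names")
  msg <- c(.checkIds(rownames(v), "gene"), .checkIds(colnames(v), "sample"))
  if (length(msg)) return(msg)
  if (nrow(v) < 1L || ncol(v) < 1L)
    return("matrix must have at least one row and one column")
  if (!is.numeric(v)) return("matrix entries must be numeric")
  TRUE
})

#' EssentialityMatrix: knockout-by-cell-line essentiality scores
#'
#' Holds a real-valued matrix of gene-essentiality scores (DEMETER- or
#' CERES-like): rows are knocked-out (or knocked-down) genes, columns are
#' cell lines, and more negative values mean the cell line depends more on
#' the gene. Missing measurements are stored as `NA` and can be filled in
#' with [knnImpute()].
#'
#' @slot values numeric matrix; `NA` marks missing entries, all other
#'   entries must be finite.
#' @seealso [EssentialityMatrix()], [knnImpute()], [moderatedTTest()]
#' @name EssentialityMatrix-class
#' @aliases EssentialityMatrix-class
#' @exportClass EssentialityMatrix
setClass("EssentialityMatrix", contains = "ScreenMatrix",
         validity = function(object) {
  v <- object@values
  if (any(!is.finite(v) & !is.na(v)))
    return("non-missing essentiality scores must be finite")
  TRUE
})

#' MutationMatrix: binary biomarker-by-cell-line alteration indicator
#'
#' Entry `(g, j)` is 1 when sample `j` carries a qualifying alteration of
#' biomarker gene `g` (mutant, MUT) and 0 otherwise (wild-type, WT).
#' Usually built from a variant table with [dichotomizeVariants()].
#'
#' @slot values numeric matrix with entries exactly 0 or 1.
#' @seealso [MutationMatrix()], [dichotomizeVariants()]
#' @name MutationMatrix-class
#' @exportClass MutationMatrix
setClass("MutationMatrix", contains = "ScreenMatrix",
         validity = function(object) {
  v <- object@values
  if (any(is.na(v)) || !all(v %in% c(0, 1)))
    return("mutation indicator entries must be exactly 0 or 1")
  TRUE
})

#' ExpressionMatrix: gene-by-cell-line expression in TPM
#'
#' @slot values non-negative finite numeric matrix (transcripts per million).
#' @seealso [ExpressionMatrix()], [selectEssentialGenes()]
#' @name ExpressionMatrix-class
#' @exportClass ExpressionMatrix
setClass("ExpressionMatrix", contains = "ScreenMatrix",
         validity = function(object) {
  v <- object@values
  if (any(is.na(v)) || any(!is.finite(v)) || any(v < 0))
    return("TPM values must be finite and non-negative")
  TRUE
})

#' CohortSpec: a tumor-type cohort of cell lines and its complement
#'
#' Names the cell lines belonging to the tumor type under study and the
#' remaining screened lines used for specificity checks.
#'
#' @slot tumorLabel single string naming the cohort (e.g. `"AML"`).
#' @slot memberSamples character vector of cohort cell-line ids (non-empty).
#' @slot otherSamples character vector of non-cohort cell-line ids,
#'   disjoint from `memberSamples`.
#' @seealso [CohortSpec()], [selectEssentialGenes()]
#' @name CohortSpec-class
#' @exportClass CohortSpec
setClass("CohortSpec",
         representation(tumorLabel = "character",
                        memberSamples = "character",
                        otherSamples = "character"),
         validity = function(object) {
  if (length(object@tumorLabel) != 1L || !nzchar(object@tumorLabel))
    return("tumorLabel must be a single non-empty string")
  if (length(object@memberSamples) < 1L)
    return("cohort must contain at least one sample")
  if (anyDuplicated(object@memberSamples) || anyDuplicated(object@otherSamples))
    return("duplicated sample ids in cohort specification")
  if (length(intersect(object@memberSamples, object@otherSamples)))
    return("member and other sample sets must be disjoint")
  TRUE
})

#' ShrinkageModel: empirical-Bayes variance moderation hyper-parameters
#'
#' The scaled-F prior fitted to per-knockout sample variances and the
#' resulting posterior (shrunk) variances; see [fitVariancePrior()].
#'
#' @slot priorDf prior degrees of freedom `d0 >= 0`; may be `Inf` when all
#'   variances are compatible with a single common value.
#' @slot priorVar prior variance `s0^2 > 0`.
#' @slot posteriorVar numeric vector of shrunk variances, one per knockout:
#'   `(d0*s0^2 + d_i*s_i^2) / (d0 + d_i)`.
#' @slot residDf residual degrees of freedom per knockout.
#' @slot fallback TRUE when too few usable variances forced the ordinary-t
#'   fallback (`priorDf = 0`).
#' @name ShrinkageModel-class
#' @exportClass ShrinkageModel
setClass("ShrinkageModel",
         representation(priorDf = "numeric", priorVar = "numeric",
                        posteriorVar = "numeric", residDf = "numeric",
                        fallback = "logical"),
         validity = function(object) {
  if (length(object@priorDf) != 1L || is.na(object@priorDf) ||
      object@priorDf < 0)
    return("priorDf must be a single value >= 0 (possibly Inf)")
  if (length(object@priorVar) != 1L ||
      (!is.na(object@priorVar) && object@priorVar <= 0))
    return("priorVar must be a single positive value")
  if (length(object@posteriorVar) != length(object@residDf))
    return("posteriorVar and residDf lengths differ")
  TRUE
})

#' LocalFDRModel: per-group local false discovery rate fit
#'
#' Stores, for one group of tests, the estimated proportion of true nulls
#' `pi0`, the monotone (Grenander-type) estimate of the p-value mixture
#' density `f`, and the per-test local FDR `pi0 * f0(p) / f(p)` with
#' `f0 = U(0,1)`. Built by [localFdr()].
#'
#' @slot groupId single string; `""` for a pooled fit.
#' @slot pi0 estimated null proportion in `(0, 1]`.
#' @slot densityX,densityF step-density representation: `densityF[i]` is the
#'   estimated mixture density on the interval `(densityX[i], densityX[i+1]]`.
#' @slot lfdr per-test local FDR in `[0, 1]`, in input order.
#' @slot nTests number of tests in the group.
#' @name LocalFDRModel-class
#' @exportClass LocalFDRModel
setClass("LocalFDRModel",
         representation(groupId = "character", pi0 = "numeric",
                        densityX = "numeric", densityF = "numeric",
                        lfdr = "numeric", nTests = "integer"),
         validity = function(object) {
  if (object@pi0 <= 0 || object@pi0 > 1) return("pi0 must lie in (0, 1]")
  if (any(object@lfdr < 0 | object@lfdr > 1, na.rm = TRUE))
    return("local FDR values must lie in [0, 1]")
  if (length(object@densityX) != length(object@densityF) + 1L)
    return("densityX must have one more element than densityF")
  if (any(object@densityF < 0)) return("density must be non-negative")
  TRUE
})

#' SyntheticScreen: a simulated loss-of-function screen with known truth
#'
#' Product of [simulateScreen()]: essentiality, mutation and expression
#' matrices over a common set of cell lines, plus the planted
#' (biomarker, knockout, sign) truth triples.
#'
#' @slot D [EssentialityMatrix-class] of simulated scores.
#' @slot M [MutationMatrix-class] of simulated alterations.
#' @slot X [ExpressionMatrix-class] (constant TPM by default).
#' @slot truth data.frame with columns `biomarker`, `knockout`, `sign`
#'   (-1 = mutants sensitised, +1 = mutants protected).
#' @slot config the [simulationConfig()] list that produced the screen.
#' @name SyntheticScreen-class
#' @exportClass SyntheticScreen
setClass("SyntheticScreen",
         representation(D = "EssentialityMatrix", M = "MutationMatrix",
                        X = "ExpressionMatrix", truth = "data.frame",
                        config = "list"),
         validity = function(object) {
  tr <- object@truth
  need <- c("biomarker", "knockout", "sign")
  if (!all(need %in% names(tr)))
    return("truth must have columns biomarker, knockout, sign")
  if (nrow(tr)) {
    if (!all(tr$biomarker %in% rownames(object@M@values)))
      return("truth references unknown biomarkers")
    if (!all(tr$knockout %in% rownames(object@D@values)))
      return("truth references unknown knockouts")
    if (!all(tr$sign %in% c(-1, 1)))
      return("truth signs must be -1 or +1")
  }
  TRUE
})

## ---- constructors -----------------------------------------------------

.namedMatrix <- function(values, rowIds = NULL, colIds = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(rowIds)) rownames(values) <- rowIds
  if (!is.null(colIds)) colnames(values) <- colIds
  values
}

#' Construct an EssentialityMatrix
#'
#' @param values numeric matrix of essentiality scores (knockouts in rows,
#'   cell lines in columns); `NA` marks missing measurements.
#' @param knockoutIds,sampleIds optional dimnames overriding those of
#'   `values`.
#' @return An [EssentialityMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'             dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' EssentialityMatrix(m)
#' @export
EssentialityMatrix <- function(values, knockoutIds = NULL, sampleIds = NULL)
  new("EssentialityMatrix",
      values = .namedMatrix(values, knockoutIds, sampleIds))

#' Construct a MutationMatrix
#'
#' @param values 0/1 matrix (biomarker genes in rows, cell lines in columns).
#' @param biomarkerIds,sampleIds optional dimnames overriding those of
#'   `values`.
#' @return A [MutationMatrix-class] object.
#' @export
MutationMatrix <- function(values, biomarkerIds = NULL, sampleIds = NULL)
  new("MutationMatrix",
      values = .namedMatrix(values, biomarkerIds, sampleIds))

#' Construct an ExpressionMatrix
#'
#' @param values non-negative TPM matrix (genes in rows, cell lines in
#'   columns).
#' @param geneIds,sampleIds optional dimnames overriding those of `values`.
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, geneIds = NULL, sampleIds = NULL)
  new("ExpressionMatrix", values = .namedMatrix(values, geneIds, sampleIds))

#' Construct a CohortSpec
#'
#' @param tumorLabel cohort name, e.g. `"AML"`.
#' @param memberSamples cell lines belonging to the cohort.
#' @param otherSamples non-cohort cell lines used for specificity checks.
#' @return A [CohortSpec-class] object.
#' @export
CohortSpec <- function(tumorLabel, memberSamples, otherSamples = character())
  new("CohortSpec", tumorLabel = as.character(tumorLabel),
      memberSamples = as.character(memberSamples),
      otherSamples = as.character(otherSamples))
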