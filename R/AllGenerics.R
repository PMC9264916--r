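#' Accessors for screen matrices and derived objects
#'
#' `scores()`, `indicator()` and `tpm()` return the underlying numeric
#' matrix of an [EssentialityMatrix-class], [MutationMatrix-class] or
#' [ExpressionMatrix-class]; `sampleIds()` the cell-line (column) ids;
#' `geneIds()` the row ids (knockouts, biomarkers or expressed genes
#' depending on the object); `knockoutIds()` and `biomarkerIds()` are
#' class-specific synonyms. `missingMask()` flags unmeasured entries of an
#' essentiality matrix. `lfdrValues()` extracts per-test local FDRs from a
#' [LocalFDRModel-class]. `screenTruth()` returns the planted truth of a
#' [SyntheticScreen-class].
#'
#' @param x an object of the matching class.
#' @return See the individual descriptions above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("indicator", function(x) standardGeneric("indicator"))
#' @rdname accessors
#' @export
setGeneric("tpm", function(x) standardGeneric("tpm"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("knockoutIds", function(x) standardGeneric("knockoutIds"))
#' @rdname accessors
#' @export
setGeneric("biomarkerIds", function(x) standardGeneric("biomarkerIds"))
#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname accessors
#' @export
setGeneric("lfdrValues", function(x) standardGeneric("lfdrValues"))
#' @rdname accessors
#' @export
setGeneric("screenTruth", function(x) standardGeneric("screenTruth"))

#' @rdname accessors
setMethod("scores", "EssentialityMatrix", function(x) x@values)
#' @rdname accessors
setMethod("indicator", "MutationMatrix", function(x) x@values)
#' @rdname accessors
setMethod("tpm", "ExpressionMatrix", function(x) x@values)
#' @rdname accessors
setMethod("sampleIds", "ScreenMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("geneIds", "ScreenMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("knockoutIds", "EssentialityMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("biomarkerIds", "MutationMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("missingMask", "EssentialityMatrix", function(x) is.na(x@values))
#' @rdname accessors
setMethod("lfdrValues", "LocalFDRModel", function(x) x@lfdr)
#' @rdname accessors
setMethod("screenTruth", "SyntheticScreen", function(x) x@truth)

#' @rdname accessors
#' @export
setMethod("dim", "ScreenMatrix", function(x) dim(x@values))

#' Subset a screen matrix by gene and/or sample ids (or indices)
#'
#' @param x a [ScreenMatrix-class] derivative.
#' @param i,j row (gene) and column (sample) subscripts.
#' @param ... ignored.
#' @param drop ignored; dimensions are always kept.
#' @return An object of the same class restricted to the selection.
#' @export
setMethod("[", "ScreenMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  initialize(x, values = v)
})

.showScreen <- function(object, what) {
  v <- object@values
  cat(sprintf("%s: %d %s x %d cell lines\n", class(object), nrow(v), what,
              ncol(v)))
  if (is(object, "EssentialityMatrix")) {
    nmiss <- sum(is.na(v))
    if (nmiss) cat(sprintf("  missing entries: %d (%.1f%%)\n", nmiss,
                           100 * nmiss / length(v)))
  }
  cat("  genes:  ", paste(utils::head(rownames(v), 4L), collapse = ", "),
      if (nrow(v) > 4L) ", ..." else "", "\n", sep = "")
  cat("  samples:", paste(utils::head(colnames(v), 4L), collapse = ", "),
      if (ncol(v) > 4L) ", ..." else "", "\n", sep = "")
  invisible(NULL)
}

#' @exportMethod show
setMethod("show", "EssentialityMatrix",
          function(object) .showScreen(object, "knockouts"))
setMethod("show", "MutationMatrix",
          function(object) .showScreen(object, "biomarkers"))
setMethod("show", "ExpressionMatrix",
          function(object) .showScreen(object, "genes"))

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec '%s': %d member / %d other cell lines\n",
              object@tumorLabel, length(object@memberSamples),
              length(object@otherSamples)))
})

setMethod("show", "ShrinkageModel", function(object) {
  cat(sprintf(
    "ShrinkageModel: prior df = %s, prior variance = %.4g (%d knockouts%s)\n",
    format(object@priorDf), object@priorVar, length(object@posteriorVar),
    if (object@fallback) "; ordinary-t fallback" else ""))
})

setMethod("show", "LocalFDRModel", function(object) {
  cat(sprintf(
    "LocalFDRModel%s: %d tests, pi0 = %.3f, lfdr range [%.3g, %.3g]\n",
    if (nzchar(object@groupId)) sprintf(" [group %s]", object@groupId) else "",
    object@nTests, object@pi0, min(object@lfdr), max(object@lfdr)))
})

setMethod("show", "SyntheticScreen", function(object) {
  cat(sprintf(
    "SyntheticScreen: %d knockouts x %d biomarkers x %d cell lines, %d true pairs\n",
    nrow(object@D@values), nrow(object@M@values), ncol(object@D@values),
    nrow(object@truth)))
})
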