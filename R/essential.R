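#' Select essential, cohort-specific, expressed knockout genes
#'
#' A knockout gene enters the downstream dependency tests when it is
#' (i) essential in at least `minFractionCohort` of the cohort cell lines
#' (score at or below `essentialScoreCutoff`), (ii) specific to the cohort,
#' i.e. essential in at most `maxFractionOther` of the remaining lines, and
#' (iii) expressed (TPM above `expressionTpmCutoff`) in at least
#' `minFractionExpressed` of the cohort lines before the knockout
#' experiment. All three fractions are reported for every gene, so the
#' selection can be audited or re-thresholded.
#'
#' @param D an [EssentialityMatrix-class] (complete; impute first).
#' @param X an [ExpressionMatrix-class]; knockout genes absent from its
#'   rows are treated as not expressed, with a warning.
#' @param cohort a [CohortSpec-class]; at least 2 member samples must be
#'   present in `D`. Specificity is computed over `otherSamples` (or over
#'   all non-member columns of `D` when `otherSamples` is empty).
#' @param essentialScoreCutoff a sample counts the gene as essential when
#'   its score is `<=` this cutoff (default -2, the conventional magnitude
#'   for a strong dependency on the DEMETER scale).
#' @param minFractionCohort minimum essential fraction in the cohort
#'   (default 0.20; disease presets may raise it, e.g. 0.25 for AML).
#' @param maxFractionOther maximum essential fraction outside the cohort
#'   (default 0.10).
#' @param expressionTpmCutoff TPM strictly above this counts as expressed
#'   (default 1).
#' @param minFractionExpressed minimum expressed fraction in the cohort
#'   (default 0.75).
#' @return data.frame (one row per knockout of `D`) with columns
#'   `knockout`, `frac_essential_cohort`, `frac_essential_other`,
#'   `frac_expressed`, `selected`.
#' @export
selectEssentialGenes <- function(D, X, cohort,
                                 essentialScoreCutoff = -2,
                                 minFractionCohort = 0.20,
                                 maxFractionOther = 0.10,
                                 expressionTpmCutoff = 1,
                                 minFractionExpressed = 0.75) {
  stopifnot(is(D, "EssentialityMatrix"), is(X, "ExpressionMatrix"),
            is(cohort, "CohortSpec"))
  v <- scores(D)
  member <- intersect(cohort@memberSamples, colnames(v))
  if (length(member) < 2L)
    stop("cohort must contain at least 2 cell lines present in the data",
         call. = FALSE)
  other <- if (length(cohort@otherSamples))
    intersect(cohort@otherSamples, colnames(v))
  else setdiff(colnames(v), member)

  ess <- !is.na(v) & v <= essentialScoreCutoff
  fracCohort <- rowMeans(ess[, member, drop = FALSE])
  fracOther <- if (length(other))
    rowMeans(ess[, other, drop = FALSE])
  else rep(0, nrow(v))

  xv <- tpm(X)
  xMember <- intersect(member, colnames(xv))
  kn <- rownames(v)
  fracExpr <- rep(0, length(kn))
  inX <- kn %in% rownames(xv)
  if (any(!inX))
    warning(sprintf("%d knockout gene(s) absent from the expression matrix treated as not expressed (e.g. %s)",
                    sum(!inX), paste(utils::head(kn[!inX], 3L), collapse = ", ")))
  if (length(xMember) && any(inX))
    fracExpr[inX] <- rowMeans(
      xv[kn[inX], xMember, drop = FALSE] > expressionTpmCutoff)

  res <- data.frame(
    knockout = kn,
    frac_essential_cohort = unname(fracCohort),
    frac_essential_other = unname(fracOther),
    frac_expressed = fracExpr,
    stringsAsFactors = FALSE)
  res$selected <- res$frac_essential_cohort >= minFractionCohort &
    res$frac_essential_other <= maxFractionOther &
    res$frac_expressed >= minFractionExpressed
  rownames(res) <- NULL
  res
}

#' Restrict an essentiality matrix to the selected essential genes
#'
#' @param D an [EssentialityMatrix-class].
#' @param geneSet data.frame from [selectEssentialGenes()].
#' @return `D` restricted to rows with `selected == TRUE`.
#' @export
filterEssential <- function(D, geneSet) {
  keep <- geneSet$knockout[geneSet$selected]
  if (!length(keep))
    stop("no knockout genes pass the essentiality criteria", call. = FALSE)
  D[keep, ]
}
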