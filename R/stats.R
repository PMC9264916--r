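## Two-group essentiality tests: empirical-Bayes moderated t-test and the
## one-way ANOVA baseline. For every (knockout, biomarker) pair the effect
## size is the increment of essentiality, delta = mean(score | mutant) -
## mean(score | wild-type); negative delta means mutant lines are more
## sensitive to the knockout.

#' Fit a scaled-F variance prior by moment matching (empirical Bayes)
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` of
#' the standard hierarchical model in which per-knockout sample variances
#' `s_i^2` (on `d_i` residual df) are distributed as `s0^2 * F(d_i, d0)`
#' around a common prior. The fit matches the mean and variance of
#' `log(s_i^2)` against the digamma/trigamma moments of the log-F
#' distribution; posterior variances shrink each `s_i^2` toward `s0^2`:
#' `(d0*s0^2 + d_i*s_i^2) / (d0 + d_i)`.
#'
#' @param sampleVars positive sample variances, one per knockout.
#' @param residDfs residual degrees of freedom, recycled to the length of
#'   `sampleVars`.
#' @return A [ShrinkageModel-class]. With fewer than 2 usable variances the
#'   ordinary-t fallback (`priorDf = 0`, posterior = sample variances) is
#'   returned with a warning; when the log-variances show no excess spread
#'   over pure sampling noise, `priorDf = Inf` and every posterior variance
#'   equals the common value.
#' @examples
#' set.seed(1)
#' d <- rep(10, 2000)
#' s2 <- 2 * rf(2000, d, 4)  # true prior: d0 = 4, s0^2 = 2
#' fitVariancePrior(s2, d)
#' @export
fitVariancePrior <- function(sampleVars, residDfs) {
  n <- length(sampleVars)
  residDfs <- rep_len(as.numeric(residDfs), n)
  usable <- is.finite(sampleVars) & sampleVars > 0 & residDfs >= 1
  mk <- function(d0, s0, fallback = FALSE) {
    post <- if (is.infinite(d0)) rep(s0, n)
      else (d0 * s0 + residDfs * sampleVars) / (d0 + residDfs)
    post[!usable] <- sampleVars[!usable]
    new("ShrinkageModel", priorDf = d0, priorVar = s0, posteriorVar = post,
        residDf = residDfs, fallback = fallback)
  }
  if (sum(usable) < 2L) {
    warning("fewer than 2 usable variances: ordinary-t fallback (priorDf = 0)")
    s0 <- if (any(usable)) sampleVars[usable][1L] else NA_real_
    m <- mk(0, s0, fallback = TRUE)
    m@posteriorVar <- sampleVars
    return(m)
  }
  s2 <- sampleVars[usable]
  df <- residDfs[usable]
  if (max(s2) - min(s2) < 1e-12 * max(s2, 1e-300))
    return(mk(Inf, s2[1L]))
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  evar <- stats::var(e)
  excess <- evar - mean(trigamma(df / 2))
  if (excess <= 0) return(mk(Inf, exp(mean(e))))
  d0 <- 2 * .trigammaInverse(excess)
  s0 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  mk(d0, s0)
}

# Newton solve of trigamma(x) = y for x > 0
.trigammaInverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) < 1e-10 * x) break
  }
  x
}

# per-knockout two-group summaries for one biomarker split
.groupStats <- function(v, mut, wt) {
  g <- function(cols) {
    a <- v[, cols, drop = FALSE]
    n <- rowSums(!is.na(a))
    m <- rowMeans(a, na.rm = TRUE)
    ss <- rowSums((a - m)^2, na.rm = TRUE)
    list(n = n, m = m, ss = ss)
  }
  gm <- g(mut); gw <- g(wt)
  df <- gm$n + gw$n - 2
  list(nMut = gm$n, nWt = gw$n, delta = gm$m - gw$m,
       s2 = ifelse(df > 0, (gm$ss + gw$ss) / df, NA_real_), df = df)
}

.pairTests <- function(D, M, minGroupSize, moderated, moderation, priorDf) {
  stopifnot(is(D, "EssentialityMatrix"), is(M, "MutationMatrix"))
  if (!identical(sampleIds(D), sampleIds(M)))
    stop("essentiality and mutation matrices are not sample-aligned; run alignSamples() first",
         call. = FALSE)
  minGroupSize <- as.integer(minGroupSize)
  if (is.na(minGroupSize) || minGroupSize < 2L)
    stop("minGroupSize must be an integer >= 2", call. = FALSE)
  v <- scores(D)
  ind <- indicator(M)
  bms <- rownames(ind)
  per <- vector("list", length(bms))
  names(per) <- bms
  for (b in bms) {
    mut <- which(ind[b, ] == 1)
    wt <- which(ind[b, ] == 0)
    st <- .groupStats(v, mut, wt)
    skipped <- st$nMut < minGroupSize | st$nWt < minGroupSize
    if (!all(skipped) && all(st$s2[!skipped] == 0, na.rm = TRUE) &&
        !anyNA(st$s2[!skipped]))
      stop("zero residual variance for every knockout of biomarker ", b,
           call. = FALSE)
    per[[b]] <- data.frame(
      knockout = rownames(v), biomarker = b,
      n_mut = st$nMut, n_wt = st$nWt, delta = st$delta,
      s2 = st$s2, resid_df = st$df, skipped = skipped,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, per)

  applyPrior <- function(rows) {
    ok <- !rows$skipped & is.finite(rows$s2) & rows$resid_df >= 1
    if (moderated && is.null(priorDf)) {
      sm <- if (sum(ok) >= 2L)
        fitVariancePrior(rows$s2[ok], rows$resid_df[ok])
      else {
        warning("too few testable knockouts for moderation; ordinary t used")
        new("ShrinkageModel", priorDf = 0, priorVar = NA_real_,
            posteriorVar = rows$s2[ok], residDf = rows$resid_df[ok],
            fallback = TRUE)
      }
      d0 <- sm@priorDf
      rows$post_var <- rows$s2
      rows$post_var[ok] <- sm@posteriorVar
    } else {
      d0 <- if (moderated) priorDf else 0
      if (is.infinite(d0))
        stop("an explicit priorDf must be finite", call. = FALSE)
      if (d0 > 0) {
        sm <- fitVariancePrior(rows$s2[ok], rows$resid_df[ok])
        s0 <- sm@priorVar
        rows$post_var <- (d0 * s0 + rows$resid_df * rows$s2) /
          (d0 + rows$resid_df)
      } else rows$post_var <- rows$s2
    }
    rows$df_total <- rows$resid_df + d0
    rows
  }

  if (moderation == "per_biomarker") {
    res <- do.call(rbind, lapply(split(res, res$biomarker), applyPrior))
  } else {
    res <- applyPrior(res)
  }
  se <- sqrt(res$post_var * (1 / res$n_mut + 1 / res$n_wt))
  res$t_stat <- res$delta / se
  res$p_value <- 2 * stats::pt(-abs(res$t_stat), df = res$df_total)
  res$t_stat[res$skipped] <- NA_real_
  res$p_value[res$skipped] <- NA_real_
  res$df_total[res$skipped] <- NA_real_
  res$group_id <- res$biomarker
  res <- res[order(res$knockout, res$biomarker), ]
  rownames(res) <- NULL
  res[c("knockout", "biomarker", "n_mut", "n_wt", "delta", "t_stat",
        "df_total", "p_value", "group_id", "skipped")]
}

#' Moderated t-tests of essentiality between mutant and wild-type lines
#'
#' For every (knockout, biomarker) pair with at least `minGroupSize` mutant
#' and wild-type cell lines, tests the null hypothesis that expected
#' essentiality is identical in mutant and wild-type lines. The pooled
#' within-pair variance is shrunk toward a prior fitted with
#' [fitVariancePrior()] across the knockouts of each biomarker's test
#' family (or globally, see `moderation`), and the t statistic
#' `delta / sqrt(postVar * (1/nMut + 1/nWt))` is referred to a t law on
#' `residDf + priorDf` degrees of freedom (two-sided). Pairs failing the
#' group-size gate are kept in the output with `skipped = TRUE` and `NA`
#' statistics rather than silently dropped.
#'
#' @param D an [EssentialityMatrix-class], typically already restricted to
#'   the selected essential genes and the cohort cell lines.
#' @param M a [MutationMatrix-class], sample-aligned with `D`.
#' @param minGroupSize minimum mutant and wild-type group size (default 2).
#' @param moderation `"per_biomarker"` (default): one variance prior per
#'   biomarker's family of knockout tests; `"global"`: a single prior over
#'   all pairs.
#' @param priorDf optional fixed prior degrees of freedom overriding the
#'   empirical-Bayes estimate; `priorDf = 0` gives the ordinary
#'   equal-variance t-test.
#' @return data.frame (the test result table) with one row per pair and
#'   columns `knockout`, `biomarker`, `n_mut`, `n_wt`, `delta`, `t_stat`,
#'   `df_total`, `p_value`, `group_id`, `skipped`, ordered by knockout then
#'   biomarker.
#' @seealso [anovaTest()] for the unmoderated baseline,
#'   [groupedLocalFdr()] for the grouped correction.
#' @export
moderatedTTest <- function(D, M, minGroupSize = 2L,
                           moderation = c("per_biomarker", "global"),
                           priorDf = NULL) {
  moderation <- match.arg(moderation)
  .pairTests(D, M, minGroupSize, moderated = TRUE, moderation = moderation,
             priorDf = priorDf)
}

#' One-way ANOVA baseline test of essentiality differences
#'
#' Two-level one-way ANOVA (mutant vs wild-type) for every pair; for two
#' groups the F statistic is exactly the square of the equal-variance
#' two-sample t and the p-value is identical, so this is the classical
#' unmoderated baseline used by standard screen pipelines.
#'
#' @inheritParams moderatedTTest
#' @return As [moderatedTTest()], with an additional `f_stat` column
#'   (`t_stat^2`); `t_stat` is the ordinary pooled-variance t.
#' @export
anovaTest <- function(D, M, minGroupSize = 2L) {
  res <- .pairTests(D, M, minGroupSize, moderated = FALSE,
                    moderation = "per_biomarker", priorDf = 0)
  res$f_stat <- res$t_stat^2
  res
}
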