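## Multiple-testing machinery: Storey-type pi0 estimation, q-values,
## monotone-density local FDR, the per-biomarker grouped correction that
## exploits hub-concentrated signal, a covariate-weighted BH procedure, and
## the classical corrections.

.checkP <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NA", call. = FALSE)
  p
}

#' Estimate the proportion of true null hypotheses (pi0)
#'
#' Storey-type estimation from the excess of p-values above a tuning point
#' lambda: `pi0(lambda) = #(p > lambda) / (n * (1 - lambda))`. The
#' `"bootstrap"` method (default) picks the lambda on `lambdaGrid` that
#' minimises a closed-form mean-squared-error estimate against the minimum
#' observed `pi0(lambda)`; `"smoother"` fits a cubic smoothing spline to
#' `pi0(lambda)` and reads it off at the largest lambda; `"fixed_lambda"`
#' uses the single given lambda. The estimate is clamped to
#' `[1/n, 1]`.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param method `"bootstrap"` (default), `"smoother"` or `"fixed_lambda"`.
#' @param lambdaGrid grid of lambda values (default `seq(0.05, 0.95, 0.05)`);
#'   for `"fixed_lambda"` only the first element is used.
#' @return Single pi0 estimate in `(0, 1]`. With fewer than 20 p-values the
#'   grid methods fall back to `fixed_lambda = 0.5` with a warning.
#' @export
estimatePi0 <- function(pvalues,
                        method = c("bootstrap", "smoother", "fixed_lambda"),
                        lambdaGrid = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  p <- .checkP(pvalues)
  n <- length(p)
  if (n < 20L && method != "fixed_lambda") {
    warning("fewer than 20 p-values: falling back to fixed_lambda = 0.5")
    method <- "fixed_lambda"
    lambdaGrid <- 0.5
  }
  lam <- sort(unique(lambdaGrid))
  if (any(lam <= 0 | lam >= 1))
    stop("lambdaGrid values must lie in (0, 1)", call. = FALSE)
  pi0l <- vapply(lam, function(l) mean(p > l) / (1 - l), numeric(1))
  pi0 <- switch(method,
    fixed_lambda = pi0l[1L],
    smoother = {
      if (length(lam) < 4L)
        stop("smoother needs at least 4 lambda grid points", call. = FALSE)
      fit <- stats::smooth.spline(lam, pi0l, df = 3)
      stats::predict(fit, x = max(lam))$y
    },
    bootstrap = {
      minpi0 <- stats::quantile(pi0l, 0.1, names = FALSE)
      W <- vapply(lam, function(l) sum(p >= l), numeric(1))
      mse <- W / (n^2 * (1 - lam)^2) * (1 - W / n) + (pi0l - minpi0)^2
      pi0l[which.min(mse)]
    })
  lower <- 1 / n
  if (pi0 < lower) {
    warning(sprintf("pi0 estimate %.3g clamped to lower bound 1/n = %.3g",
                    pi0, lower))
    pi0 <- lower
  }
  min(pi0, 1)
}

# Grenander decreasing-density estimate on [0, 1]: left slopes of the least
# concave majorant of the ECDF (with the (0,0) and (1,1) endpoints, so the
# step density integrates to exactly 1). Returns hull x and per-interval f.
.grenander <- function(p) {
  n <- length(p)
  sp <- sort(p)
  ux <- unique(sp)
  uy <- cumsum(tabulate(match(sp, ux), length(ux))) / n
  x <- c(0, ux); y <- c(0, uy)
  if (x[length(x)] < 1) { x <- c(x, 1); y <- c(y, 1) } else y[length(y)] <- 1
  # upper convex hull (least concave majorant) by monotone chain
  hx <- numeric(length(x)); hy <- numeric(length(x)); h <- 0L
  for (i in seq_along(x)) {
    while (h >= 2L &&
           (hy[h] - hy[h - 1L]) * (x[i] - hx[h]) <=
           (y[i] - hy[h]) * (hx[h] - hx[h - 1L])) h <- h - 1L
    h <- h + 1L
    hx[h] <- x[i]; hy[h] <- y[i]
  }
  hx <- hx[seq_len(h)]; hy <- hy[seq_len(h)]
  list(x = hx, f = diff(hy) / diff(hx))
}

#' Local false discovery rate from a monotone p-value density estimate
#'
#' Models the observed p-values as a two-group mixture
#' `f(p) = pi0 * f0(p) + (1 - pi0) * f1(p)` with a uniform null density
#' `f0 = 1` on `[0, 1]`, estimates the mixture density `f` by the Grenander
#' (monotone non-increasing) estimator -- the slopes of the least concave
#' majorant of the empirical CDF -- and returns the per-test local FDR
#' `min(1, pi0 / f(p))`, the posterior probability of the null given the
#' observed p-value. Monotonicity of `f` guarantees the local FDR is
#' non-decreasing in p without any ad-hoc clipping.
#'
#' @param pvalues p-values in `[0, 1]` (at least 20 recommended; group-wise
#'   routing of small groups is handled by [groupedLocalFdr()]).
#' @param pi0 null proportion; by default estimated with [estimatePi0()].
#' @param groupId optional label stored in the result.
#' @return A [LocalFDRModel-class]; `lfdrValues()` extracts the per-test
#'   local FDRs in input order.
#' @examples
#' set.seed(7)
#' p <- c(rbeta(300, 0.2, 1), runif(700))
#' m <- localFdr(p)
#' m
#' @export
localFdr <- function(pvalues, pi0 = estimatePi0(pvalues), groupId = "") {
  p <- .checkP(pvalues)
  if (pi0 <= 0 || pi0 > 1) stop("pi0 must lie in (0, 1]", call. = FALSE)
  if (length(unique(p)) == 1L) {
    warning("degenerate p-value distribution (all identical): lfdr = pi0 everywhere")
    return(new("LocalFDRModel", groupId = as.character(groupId), pi0 = pi0,
               densityX = c(0, 1), densityF = 1,
               lfdr = rep(pi0, length(p)), nTests = length(p)))
  }
  g <- .grenander(p)
  # left-continuous evaluation: p in (x[k], x[k+1]] gets slope f[k]
  idx <- findInterval(p, g$x, left.open = TRUE, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  f <- g$f[idx]
  lfdr <- pmin(1, pi0 / f)
  new("LocalFDRModel", groupId = as.character(groupId), pi0 = pi0,
      densityX = g$x, densityF = g$f, lfdr = lfdr, nTests = length(p))
}

#' Per-biomarker grouped local FDR correction
#'
#' The grouped correction at the heart of the pipeline: the full set of
#' (knockout, biomarker) p-values is split into one group per biomarker
#' (`group_id`), and pi0 and the local FDR are estimated independently
#' within each group. Hub biomarkers -- alterations associated with shifted
#' essentiality of many knockouts -- produce p-value histograms with a
#' spike near zero, hence low within-group pi0 and local FDR, while tests
#' under alteration-free groups are judged against their own flat
#' histogram. Groups smaller than `minGroupTests` fall back to a pooled
#' all-tests model and are flagged.
#'
#' @param testTable data.frame from [moderatedTTest()] or [anovaTest()]
#'   (columns `p_value`, `group_id`, `skipped`). Skipped rows get `NA`
#'   local FDR.
#' @param minGroupTests minimum group size for per-group estimation
#'   (default 50).
#' @param pi0Method passed to [estimatePi0()].
#' @return `testTable` with extra columns `lfdr`, `pi0_group`,
#'   `group_fallback`, plus an attribute `"groupDiagnostics"`: a data.frame
#'   of `group_id`, `n_tests`, `pi0`, `frac_p_below_0.05`, `fallback`.
#' @export
groupedLocalFdr <- function(testTable, minGroupTests = 50L,
                            pi0Method = "bootstrap") {
  stopifnot(all(c("p_value", "group_id") %in% names(testTable)))
  skipped <- if ("skipped" %in% names(testTable)) testTable$skipped
    else rep(FALSE, nrow(testTable))
  usable <- !skipped & !is.na(testTable$p_value)
  p <- testTable$p_value[usable]
  gid <- as.character(testTable$group_id[usable])
  lfdr <- rep(NA_real_, nrow(testTable))
  pi0g <- rep(NA_real_, nrow(testTable))
  fall <- rep(NA, nrow(testTable))

  pooledPi0 <- estimatePi0(p, method = pi0Method)
  pooled <- localFdr(p, pi0 = pooledPi0)
  pooledLfdr <- lfdrValues(pooled)

  groups <- split(seq_along(p), gid)
  diag <- data.frame(group_id = names(groups),
                     n_tests = lengths(groups),
                     pi0 = NA_real_, frac_p_below_0.05 = NA_real_,
                     fallback = FALSE, stringsAsFactors = FALSE)
  li <- rep(NA_real_, length(p)); gi <- li; fi <- logical(length(p))
  for (r in seq_len(nrow(diag))) {
    idx <- groups[[r]]
    diag$frac_p_below_0.05[r] <- mean(p[idx] < 0.05)
    if (length(idx) >= minGroupTests) {
      g0 <- estimatePi0(p[idx], method = pi0Method)
      m <- localFdr(p[idx], pi0 = g0, groupId = diag$group_id[r])
      li[idx] <- lfdrValues(m)
      gi[idx] <- g0
      diag$pi0[r] <- g0
    } else {
      li[idx] <- pooledLfdr[idx]
      gi[idx] <- pooledPi0
      fi[idx] <- TRUE
      diag$pi0[r] <- pooledPi0
      diag$fallback[r] <- TRUE
    }
  }
  lfdr[usable] <- li; pi0g[usable] <- gi; fall[usable] <- fi
  out <- testTable
  out$lfdr <- lfdr
  out$pi0_group <- pi0g
  out$group_fallback <- fall
  rownames(diag) <- NULL
  attr(out, "groupDiagnostics") <- diag
  out
}

#' Storey-Tibshirani q-values
#'
#' `q_i = pi0 * min over p_j >= p_i of (n * p_j / rank(p_j))`; with
#' `pi0 = 1` this is exactly the Benjamini-Hochberg adjusted p-value.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param pi0 null proportion; estimated with [estimatePi0()] by default.
#' @return q-values in input order, monotone non-decreasing in p.
#' @export
storeyQvalues <- function(pvalues, pi0 = estimatePi0(pvalues)) {
  p <- .checkP(pvalues)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * pmin(1, cummin(n / (n - seq_len(n) + 1L) * p[o]))[order(o)]
  q
}

#' Classical multiple-testing corrections
#'
#' Textbook Bonferroni, Holm and Benjamini-Hochberg adjusted p-values
#' (capped at 1), with rejection counts at the requested thresholds.
#'
#' @param pvalues p-values in `[0, 1]`.
#' @param method `"bh"`, `"bonferroni"` or `"holm"`.
#' @param thresholds levels at which to count rejections (default 0.05 and
#'   0.20).
#' @return list of class `"correction_result"` with elements `method`,
#'   `adjusted` (input order) and `n_significant_at` (named counts).
#' @export
classicalCorrections <- function(pvalues, method = c("bh", "bonferroni", "holm"),
                                 thresholds = c(0.05, 0.20)) {
  method <- match.arg(method)
  p <- .checkP(pvalues)
  adj <- stats::p.adjust(p, method = switch(method, bh = "BH",
                                            bonferroni = "bonferroni",
                                            holm = "holm"))
  structure(list(method = method, adjusted = adj,
                 n_significant_at = vapply(stats::setNames(thresholds,
                                                           thresholds),
                                           function(a) sum(adj <= a),
                                           numeric(1))),
            class = "correction_result")
}

#' Covariate-weighted Benjamini-Hochberg correction
#'
#' A single-split, group-weighted BH procedure in the spirit of independent
#' hypothesis weighting: each biomarker group `g` receives a weight
#' proportional to its estimated alternative fraction `1 - pi0_g`,
#' normalised so the average weight over tests is 1, and BH is applied to
#' `p_i / w_g(i)`. Because the weights are estimated on the same p-values
#' they are applied to (no cross-fitting), the raw alternative fraction
#' would be upwardly biased in groups whose pi0 estimate happens to be low
#' by chance, inflating the realised FDR; the estimate is therefore
#' debiased by subtracting `conservatism` standard errors of the
#' tail-count pi0 estimator and flooring at zero, so only groups with
#' demonstrable signal receive weight. Groups with no demonstrable signal
#' get weight 0 (their tests cannot be rejected); when no group shows any
#' signal all weights are 1 and the procedure reduces to plain BH.
#'
#' @param testTable data.frame with columns `p_value`, `group_id` and
#'   optionally `skipped`.
#' @param alpha nominal FDR level in (0, 1).
#' @param minGroupTests groups smaller than this share the pooled pi0
#'   (default 50).
#' @param pi0Method passed to [estimatePi0()].
#' @param conservatism number of standard errors subtracted from each
#'   group's estimated alternative fraction before weighting (default 2;
#'   0 recovers the naive plug-in weights).
#' @return list of class `"correction_result"` with elements `method`,
#'   `adjusted` (weighted-BH adjusted values, `NA` for skipped rows),
#'   `weights` (per test), `rejected` (logical at `alpha`) and
#'   `n_significant_at`.
#' @export
covariateBH <- function(testTable, alpha = 0.20, minGroupTests = 50L,
                        pi0Method = "bootstrap", conservatism = 2) {
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  stopifnot(all(c("p_value", "group_id") %in% names(testTable)))
  skipped <- if ("skipped" %in% names(testTable)) testTable$skipped
    else rep(FALSE, nrow(testTable))
  usable <- !skipped & !is.na(testTable$p_value)
  gidAll <- testTable$group_id
  gid <- if (is.factor(gidAll)) gidAll[usable]
    else factor(as.character(gidAll[usable]))
  p <- .checkP(testTable$p_value[usable])
  n <- length(p)
  groups <- split(seq_len(n), gid)
  empty <- lengths(groups) == 0L
  if (any(empty))
    warning(sprintf("empty group(s) assigned weight 1: %s",
                    paste(names(groups)[empty], collapse = ", ")))
  pooledPi0 <- estimatePi0(p, method = pi0Method)
  # group signal debiased by the binomial standard error of the lambda = 0.5
  # tail count, a computable proxy for the sampling error of the lambda-tail
  # pi0 estimators at typical group sizes
  signal <- vapply(groups, function(idx) {
    if (length(idx) >= minGroupTests) {
      raw <- 1 - estimatePi0(p[idx], method = pi0Method)
      tail <- mean(p[idx] > 0.5)
      se <- sqrt(tail * (1 - tail) / length(idx)) / 0.5
      max(0, raw - conservatism * max(se, 1 / length(idx)))
    } else max(0, 1 - pooledPi0)
  }, numeric(1))
  nPer <- lengths(groups)
  wbar <- sum(nPer * signal) / n
  wg <- if (wbar > 0) signal / wbar else rep(1, length(groups))
  wg[empty] <- 1
  w <- rep(NA_real_, n)
  for (r in seq_along(groups)) w[groups[[r]]] <- wg[r]
  pw <- ifelse(w > 0, p / w, Inf)
  o <- order(pw, decreasing = TRUE)
  adjU <- pmin(1, cummin(n / (n - seq_len(n) + 1L) * pw[o]))[order(o)]
  adjusted <- rep(NA_real_, nrow(testTable))
  weights <- rep(NA_real_, nrow(testTable))
  adjusted[usable] <- adjU
  weights[usable] <- w
  structure(list(method = "covariate_bh", adjusted = adjusted,
                 weights = weights,
                 rejected = !is.na(adjusted) & adjusted <= alpha,
                 n_significant_at = stats::setNames(
                   sum(adjU <= alpha), alpha)),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat(sprintf("correction_result [%s]: %d tests\n", x$method,
              length(x$adjusted)))
  for (nm in names(x$n_significant_at))
    cat(sprintf("  significant at %s: %d\n", nm,
                as.integer(x$n_significant_at[[nm]])))
  invisible(x)
}
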