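## Synthetic loss-of-function screens with hub-structured ground truth.
## The generator mirrors the alternative hypothesis of the two-group model:
## mutant cell lines of a "true" biomarker have the essentiality of its
## target knockouts shifted by a fixed effect, on top of homoscedastic
## noise around a common baseline. A few hub biomarkers shift many
## knockouts; the rest shift few or none.

#' Build a simulation configuration
#'
#' Defaults describe the reference hub-structured screen used throughout
#' the package's power and FDR studies: 60 cell lines, 100 knockouts, 100
#' biomarkers of which 5 are hubs with 40 true targets each (the other 95
#' carry no signal), mutation prevalence 0.3, effect size 3 essentiality
#' units and unit noise.
#'
#' @param nSamples number of cell lines (default 60).
#' @param nKnockouts number of knockout genes (default 100).
#' @param nBiomarkers number of biomarker genes (default 100).
#' @param nHubBiomarkers number of hub biomarkers (default 5).
#' @param targetsPerHub true target knockouts per hub (default 40).
#' @param targetsPerNonhub true targets per non-hub biomarker (default 0).
#' @param effectSize absolute mean shift added to mutant lines for each
#'   true (biomarker, knockout) pair (default 3); the sign of each pair is
#'   drawn 50/50 so positive, negative and dual dependencies all occur.
#' @param noiseSd score noise standard deviation (default 1).
#' @param mutationPrevalence Bernoulli mutation probability per biomarker
#'   and sample (default 0.3).
#' @param baselineEssentiality common baseline score (default 0).
#' @param noiseDist `"gaussian"` (default) or `"t5"` (Student t with 5 df,
#'   scaled to `noiseSd`) to stress heavy-tailed noise.
#' @param seed integer RNG seed (default 1).
#' @return list of class `"simulation_config"`.
#' @export
simulationConfig <- function(nSamples = 60L, nKnockouts = 100L,
                             nBiomarkers = 100L, nHubBiomarkers = 5L,
                             targetsPerHub = 40L, targetsPerNonhub = 0L,
                             effectSize = 3, noiseSd = 1,
                             mutationPrevalence = 0.3,
                             baselineEssentiality = 0,
                             noiseDist = c("gaussian", "t5"), seed = 1L) {
  noiseDist <- match.arg(noiseDist)
  cfg <- list(nSamples = as.integer(nSamples),
              nKnockouts = as.integer(nKnockouts),
              nBiomarkers = as.integer(nBiomarkers),
              nHubBiomarkers = as.integer(nHubBiomarkers),
              targetsPerHub = as.integer(targetsPerHub),
              targetsPerNonhub = as.integer(targetsPerNonhub),
              effectSize = effectSize, noiseSd = noiseSd,
              mutationPrevalence = mutationPrevalence,
              baselineEssentiality = baselineEssentiality,
              noiseDist = noiseDist, seed = as.integer(seed))
  stopifnot(cfg$nSamples >= 2L, cfg$nKnockouts >= 1L, cfg$nBiomarkers >= 1L,
            cfg$nHubBiomarkers <= cfg$nBiomarkers,
            cfg$targetsPerHub <= cfg$nKnockouts,
            cfg$targetsPerNonhub <= cfg$nKnockouts,
            cfg$noiseSd > 0,
            cfg$mutationPrevalence > 0, cfg$mutationPrevalence < 1)
  class(cfg) <- "simulation_config"
  cfg
}

#' Simulate a loss-of-function screen with known truth
#'
#' Draws mutation status Bernoulli(`mutationPrevalence`) per biomarker and
#' sample, essentiality scores as baseline plus homoscedastic noise, and
#' shifts mutant lines by `+/- effectSize` for each planted
#' (biomarker, knockout) truth pair. The expression matrix is constant 10
#' TPM so the expression filter is inert unless exercised on purpose.
#' Identical seeds give bit-identical screens. A truth-carrying biomarker
#' whose mutation column comes up with no mutants is redrawn up to 10
#' times, then an error is raised.
#'
#' @param config a [simulationConfig()] list.
#' @return A [SyntheticScreen-class].
#' @examples
#' scr <- simulateScreen(simulationConfig(nSamples = 20, nKnockouts = 10,
#'                                        nBiomarkers = 6, nHubBiomarkers = 1,
#'                                        targetsPerHub = 4, seed = 42))
#' scr
#' @export
simulateScreen <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  kn <- sprintf("KO%03d", seq_len(config$nKnockouts))
  bm <- sprintf("BM%03d", seq_len(config$nBiomarkers))
  sm <- sprintf("CL%03d", seq_len(config$nSamples))

  hubs <- bm[seq_len(config$nHubBiomarkers)]
  truth <- list()
  for (b in bm) {
    nt <- if (b %in% hubs) config$targetsPerHub else config$targetsPerNonhub
    if (nt > 0L) {
      tg <- sample(kn, nt)
      truth[[b]] <- data.frame(biomarker = b, knockout = tg,
                               sign = sample(c(-1, 1), nt, replace = TRUE),
                               stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth)
    else data.frame(biomarker = character(), knockout = character(),
                    sign = numeric(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  if (config$effectSize == 0)
    truth <- truth[0L, , drop = FALSE]

  ind <- matrix(stats::rbinom(config$nBiomarkers * config$nSamples, 1L,
                              config$mutationPrevalence),
                config$nBiomarkers, config$nSamples,
                dimnames = list(bm, sm))
  carriers <- unique(truth$biomarker)
  for (b in carriers) {
    tries <- 0L
    while (sum(ind[b, ]) == 0L) {
      tries <- tries + 1L
      if (tries > 10L)
        stop("no mutant lines drawn for truth biomarker ", b,
             " after 10 redraws; raise mutationPrevalence or nSamples",
             call. = FALSE)
      ind[b, ] <- stats::rbinom(config$nSamples, 1L,
                                config$mutationPrevalence)
    }
  }

  ncell <- config$nKnockouts * config$nSamples
  noise <- switch(config$noiseDist,
    gaussian = stats::rnorm(ncell, 0, config$noiseSd),
    t5 = stats::rt(ncell, df = 5) * config$noiseSd / sqrt(5 / 3))
  D <- matrix(config$baselineEssentiality + noise,
              config$nKnockouts, config$nSamples, dimnames = list(kn, sm))
  if (nrow(truth))
    for (r in seq_len(nrow(truth))) {
      mutCols <- ind[truth$biomarker[r], ] == 1L
      D[truth$knockout[r], mutCols] <-
        D[truth$knockout[r], mutCols] + truth$sign[r] * config$effectSize
    }

  X <- matrix(10, config$nKnockouts, config$nSamples,
              dimnames = list(kn, sm))
  new("SyntheticScreen", D = EssentialityMatrix(D),
      M = MutationMatrix(ind), X = ExpressionMatrix(X),
      truth = truth, config = unclass(config))
}

#' Empirical FDR and power of a call set against planted truth
#'
#' @param calls data.frame of called pairs with columns `biomarker` and
#'   `knockout` (e.g. from [callLeds()]), or NULL/zero rows for no calls.
#' @param truth data.frame of true pairs with columns `biomarker`,
#'   `knockout` (see [screenTruth()]).
#' @return list with `empirical_fdr` (false calls over `max(1, calls)`),
#'   `power` (true calls over `max(1, |truth|)`), `n_true`, `n_false`.
#' @export
evaluateFdrPower <- function(calls, truth) {
  key <- function(d) paste(d$biomarker, d$knockout, sep = "\r")
  nCalls <- if (is.null(calls)) 0L else nrow(calls)
  if (nCalls == 0L)
    return(list(empirical_fdr = 0, power = 0, n_true = 0L, n_false = 0L))
  isTrue <- key(calls) %in% key(truth)
  nTrue <- sum(isTrue)
  list(empirical_fdr = (nCalls - nTrue) / nCalls,
       power = nTrue / max(1L, nrow(truth)),
       n_true = nTrue, n_false = nCalls - nTrue)
}

#' Write a simulated screen to a fixture directory
#'
#' Emits `essentiality.tsv`, `mutations.tsv`, `expression.tsv`,
#' `truth.tsv` and `config.json` under `dir`, forming a self-contained
#' plain-text fixture for the command-line pipeline.
#'
#' @param screen a [SyntheticScreen-class].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
writeScreen <- function(screen, dir) {
  stopifnot(is(screen, "SyntheticScreen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeMatrix(screen@D, file.path(dir, "essentiality.tsv"))
  writeMatrix(screen@M, file.path(dir, "mutations.tsv"))
  writeMatrix(screen@X, file.path(dir, "expression.tsv"))
  utils::write.table(screen@truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(screen@config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
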