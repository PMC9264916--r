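## End-to-end orchestration: align -> impute -> essential-gene selection ->
## moderated tests -> grouped local FDR -> LED calling/classification ->
## optional relation filter -> method comparison, with a written run
## directory and an auditable manifest of every threshold applied.

.pipelineDefaults <- function(preset = "generic") {
  cfg <- list(
    essentialityPath = NA_character_, mutationPath = NA_character_,
    expressionPath = NA_character_, edgesPath = NA_character_,
    cohortLabel = "cohort", cohortSamples = character(),
    preset = preset,
    imputeK = 10L,
    essentialScoreCutoff = -2, minFractionCohort = 0.20,
    maxFractionOther = 0.10,
    expressionTpmCutoff = 1, minFractionExpressed = 0.75,
    minGroupSize = 2L, minGroupTests = 50L,
    maxP = 0.05, maxLfdr = 0.6, minAbsDelta = 2,
    fdrLevel = 0.20, relationMinScore = 400,
    useRelationFilter = FALSE, seed = 1L)
  if (preset == "aml") {
    cfg$minFractionCohort <- 0.25
    cfg$useRelationFilter <- TRUE
  }
  cfg
}

#' Build a pipeline run configuration
#'
#' Collects input paths, the cohort definition and every stage parameter
#' with its default. The `"aml"` preset raises the cohort essentiality
#' fraction to 0.25 and switches the relation filter on; everything is
#' overridable by name. Unknown parameter names are rejected.
#'
#' @param preset `"generic"` (default) or `"aml"`.
#' @param ... named overrides of any configuration field (see
#'   [runLedPipeline()] for their meaning): `essentialityPath`,
#'   `mutationPath`, `expressionPath`, `edgesPath`, `cohortLabel`,
#'   `cohortSamples`, `imputeK`, `essentialScoreCutoff`,
#'   `minFractionCohort`, `maxFractionOther`, `expressionTpmCutoff`,
#'   `minFractionExpressed`, `minGroupSize`, `minGroupTests`, `maxP`,
#'   `maxLfdr`, `minAbsDelta`, `fdrLevel`, `relationMinScore`,
#'   `useRelationFilter`, `seed`.
#' @return list of class `"led_pipeline_config"`.
#' @export
ledPipelineConfig <- function(preset = c("generic", "aml"), ...) {
  preset <- match.arg(preset)
  cfg <- .pipelineDefaults(preset)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) || (length(dots) && is.null(names(dots))))
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  class(cfg) <- "led_pipeline_config"
  cfg
}

#' Read / write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return `readRunConfig()` returns a validated
#'   `"led_pipeline_config"`; `writeRunConfig()` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- if (is.null(raw$preset)) "generic" else raw$preset
  defs <- .pipelineDefaults(preset)
  unknown <- setdiff(names(raw), c(names(defs), "preset"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg <- defs
  for (nm in setdiff(names(raw), "preset")) {
    v <- raw[[nm]]
    if (is.null(v)) v <- NA_character_            # JSON null: unset path
    if (is.list(v) && !length(v)) v <- character()  # empty JSON array
    cfg[[nm]] <- v
  }
  class(cfg) <- "led_pipeline_config"
  cfg
}

#' @rdname readRunConfig
#' @param config a `"led_pipeline_config"` list.
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "led_pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Run the full lethal-dependency discovery pipeline
#'
#' Executes, in order: sample alignment, nearest-neighbour imputation,
#' essential-gene selection for the cohort, moderated t-tests of every
#' (knockout, biomarker) pair on the cohort cell lines, per-biomarker
#' grouped local FDR, LED calling at the configured gates,
#' positive/negative/dual classification, the optional relation filter,
#' and the method-comparison count table. All stage parameters come from
#' the configuration and are recorded, together with per-stage row counts,
#' in `run_manifest.json`; outputs are deterministic given inputs and
#' configuration.
#'
#' Files written under `outputDir`: `essential_genes.tsv`,
#' `test_results.tsv`, `group_diagnostics.tsv`, `led_table.tsv`,
#' `bipartite_graph.json`, `method_comparison.tsv`, `run_manifest.json`.
#'
#' @param config a [ledPipelineConfig()] object with at least
#'   `essentialityPath` and `mutationPath` set.
#' @param outputDir run directory (created if absent).
#' @return Invisibly, a list with elements `essentialGenes`, `testTable`,
#'   `leds` (classified, post-filter when enabled), `comparison`,
#'   `manifest`.
#' @export
runLedPipeline <- function(config, outputDir) {
  stopifnot(inherits(config, "led_pipeline_config"))
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed)
  counts <- list()

  D <- readMatrix(config$essentialityPath, what = "essentiality")
  M <- readMatrix(config$mutationPath, what = "essentiality")
  M <- MutationMatrix(scores(M))
  X <- if (!is.na(config$expressionPath))
    readMatrix(config$expressionPath, what = "expression") else NULL

  cohortSamples <- if (length(config$cohortSamples))
    config$cohortSamples else sampleIds(D)
  cohort <- CohortSpec(config$cohortLabel, cohortSamples)
  al <- alignSamples(D, M, X, cohort)
  cohort <- al$cohorts
  counts$samples_aligned <- ncol(al$D)

  Dimp <- knnImpute(al$D, k = config$imputeK)

  # without expression data the expression criterion is made inert by a
  # saturating constant-TPM stand-in over the knockouts
  Xeff <- if (is.null(al$X))
    ExpressionMatrix(matrix(1e6, nrow(scores(Dimp)), ncol(scores(Dimp)),
                            dimnames = dimnames(scores(Dimp))))
  else al$X
  ess <- selectEssentialGenes(
    Dimp, Xeff, cohort,
    essentialScoreCutoff = config$essentialScoreCutoff,
    minFractionCohort = config$minFractionCohort,
    maxFractionOther = config$maxFractionOther,
    expressionTpmCutoff = config$expressionTpmCutoff,
    minFractionExpressed = config$minFractionExpressed)
  counts$essential_genes <- sum(ess$selected)
  Dsub <- filterEssential(Dimp, ess)[, cohort@memberSamples]
  Msub <- al$M[, cohort@memberSamples]

  testTable <- moderatedTTest(Dsub, Msub,
                              minGroupSize = config$minGroupSize)
  testTable <- groupedLocalFdr(testTable,
                               minGroupTests = config$minGroupTests)
  counts$tests <- sum(!testTable$skipped)
  counts$tests_skipped <- sum(testTable$skipped)

  leds <- callLeds(testTable, maxP = config$maxP, maxLfdr = config$maxLfdr,
                   minAbsDelta = config$minAbsDelta)
  leds <- classifyLeds(leds)
  counts$leds_called <- nrow(leds)
  if (config$useRelationFilter && !is.na(config$edgesPath)) {
    edges <- readEdgeList(config$edgesPath)
    leds <- relationFilter(leds, edges,
                           minScore = config$relationMinScore)
    counts$leds_relation_supported <- nrow(leds)
  }
  comparison <- compareMethods(testTable, alpha = config$fdrLevel,
                               maxP = config$maxP, maxLfdr = config$maxLfdr,
                               minAbsDelta = config$minAbsDelta,
                               minGroupTests = config$minGroupTests)

  wtsv <- function(d, f) utils::write.table(
    d, file.path(outputDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wtsv(ess, "essential_genes.tsv")
  wtsv(testTable, "test_results.tsv")
  wtsv(attr(testTable, "groupDiagnostics"), "group_diagnostics.tsv")
  writeLedTable(leds, file.path(outputDir, "led_table.tsv"))
  exportBipartiteGraph(leds, file.path(outputDir, "bipartite_graph.json"))
  wtsv(comparison, "method_comparison.tsv")

  manifest <- list(config = unclass(config), stage_counts = counts,
                   dual_biomarkers = as.list(attr(leds, "dualBiomarkers")))
  jsonlite::write_json(manifest, file.path(outputDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(list(essentialGenes = ess, testTable = testTable, leds = leds,
                 comparison = comparison, manifest = manifest))
}
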