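## File readers/writers for the minimal delimited dialects the pipeline
## consumes. All readers accept plain or gzip-compressed files; separator is
## inferred from the file name (.csv = comma, anything else = tab).

.openText <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.sepFor <- function(path) {
  if (grepl("\\.csv(\\.gz)?$", path, ignore.case = TRUE)) "," else "\t"
}

.missingSentinels <- c("", "NA", "NaN", "nan")

.readDelim <- function(path, header = TRUE) {
  con <- .openText(path)
  on.exit(close(con))
  utils::read.table(con, header = header, sep = .sepFor(path),
                    quote = "", comment.char = "", check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
}

#' Read a gene-by-sample matrix from delimited text
#'
#' Reads an essentiality-score or expression (TPM) matrix from a TSV/CSV
#' file (optionally gzip-compressed). The file has one header row of sample
#' ids and a first column of gene ids; `orientation = "genes_cols"` reads
#' the transposed layout. Empty cells, `"NA"` and `"NaN"` are treated as
#' missing (only legal for essentiality matrices).
#'
#' @param path path to a delimited text file; `.csv` means comma-separated,
#'   anything else tab-separated; a `.gz` suffix is decompressed on the fly.
#' @param what `"essentiality"` (default) or `"expression"`: which matrix
#'   class to build.
#' @param orientation `"genes_rows"` (default) or `"genes_cols"`.
#' @return An [EssentialityMatrix-class] or [ExpressionMatrix-class].
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\ts1\ts2", "A\t-1\t0.5", "B\tNA\t2"), tf)
#' readMatrix(tf)
#' @export
readMatrix <- function(path, what = c("essentiality", "expression"),
                       orientation = c("genes_rows", "genes_cols")) {
  what <- match.arg(what)
  orientation <- match.arg(orientation)
  df <- .readDelim(path, header = TRUE)
  if (ncol(df) < 2L)
    stop("malformed header in ", path,
         ": need one id column plus at least one data column", call. = FALSE)
  ids <- trimws(df[[1L]])
  colIds <- trimws(colnames(df)[-1L])
  body <- as.matrix(df[, -1L, drop = FALSE])
  body[trimws(body) %in% .missingSentinels] <- NA
  num <- suppressWarnings(matrix(as.numeric(body), nrow(body), ncol(body)))
  bad <- which(is.na(num) & !is.na(body), arr.ind = TRUE)
  if (nrow(bad)) {
    b <- bad[1L, ]
    stop(sprintf(
      "non-numeric cell '%s' at line %d, column '%s' of %s",
      body[b[1L], b[2L]], b[1L] + 1L, colIds[b[2L]], path), call. = FALSE)
  }
  for (side in list(list(ids, "row"), list(colIds, "column"))) {
    msg <- .checkIds(side[[1L]], side[[2L]])
    if (!is.null(msg)) stop(msg, " in ", path, call. = FALSE)
  }
  dimnames(num) <- list(ids, colIds)
  if (orientation == "genes_cols") num <- t(num)
  if (what == "expression") ExpressionMatrix(num) else EssentialityMatrix(num)
}

#' Write a gene-by-sample matrix to delimited text
#'
#' Inverse of [readMatrix()]; missing entries are always written as `"NA"`.
#'
#' @param x a [ScreenMatrix-class] derivative.
#' @param path output path; `.csv` selects comma separation, `.gz`
#'   compression.
#' @param idColumn header of the first (gene id) column.
#' @return `path`, invisibly.
#' @export
writeMatrix <- function(x, path, idColumn = "gene") {
  stopifnot(is(x, "ScreenMatrix"))
  v <- x@values
  sep <- .sepFor(path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(c(idColumn, colnames(v)), collapse = sep), con)
  body <- apply(v, 1L, function(r)
    paste(ifelse(is.na(r), "NA", formatC(r, format = "g", digits = 15L)),
          collapse = sep))
  writeLines(paste(rownames(v), body, sep = sep), con)
  invisible(path)
}

#' Read a minimal MAF-like variant table
#'
#' Expects a delimited file with named columns `sample_id`, `gene`,
#' `variant_class`, `allelic_fraction`, `common`, `neutral` (extra columns
#' are kept). `variant_class` values outside the recognised vocabulary
#' (`missense`, `nonsense`, `frameshift`, `splice`, `silent`, `noncoding`,
#' `other`) are recoded to `"other"` with a warning by
#' [dichotomizeVariants()], not here.
#'
#' @param path delimited text file (optionally `.gz`).
#' @return data.frame with the columns above; `allelic_fraction` numeric in
#'   `[0, 1]` (NA allowed), `common`/`neutral` logical.
#' @export
readVariantTable <- function(path) {
  df <- .readDelim(path, header = TRUE)
  need <- c("sample_id", "gene", "variant_class", "allelic_fraction",
            "common", "neutral")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("variant table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$sample_id <- trimws(df$sample_id)
  df$gene <- trimws(df$gene)
  df$allelic_fraction <- suppressWarnings(as.numeric(df$allelic_fraction))
  if (any(df$allelic_fraction < 0 | df$allelic_fraction > 1, na.rm = TRUE))
    stop("allelic_fraction outside [0, 1] in ", path, call. = FALSE)
  df$common <- tolower(trimws(df$common)) %in% c("true", "t", "1", "yes")
  df$neutral <- tolower(trimws(df$neutral)) %in% c("true", "t", "1", "yes")
  df
}

#' Read a scored gene-gene edge list (STRING-like)
#'
#' @param path delimited file with columns `gene_a`, `gene_b`,
#'   `combined_score` (integer 0-1000). Edges are undirected: `(a, b)` and
#'   `(b, a)` are equivalent.
#' @return data.frame with those three columns.
#' @export
readEdgeList <- function(path) {
  df <- .readDelim(path, header = TRUE)
  need <- c("gene_a", "gene_b", "combined_score")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("edge list ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$gene_a <- trimws(df$gene_a)
  df$gene_b <- trimws(df$gene_b)
  df$combined_score <- suppressWarnings(as.numeric(df$combined_score))
  if (any(is.na(df$combined_score)) ||
      any(df$combined_score < 0 | df$combined_score > 1000))
    stop("combined_score must be numeric in [0, 1000] in ", path,
         call. = FALSE)
  df[need]
}

#' Read a clinical-association knowledge base
#'
#' Minimal VICC-like dialect: columns `disease`, `biomarker_gene`,
#' `target_gene`, `evidence_level` (one of `A`, `B`, `C`, `lower`). Rows
#' with an empty biomarker or target are marked incomplete and dropped by
#' default, as are exact duplicates.
#'
#' @param path delimited file (optionally `.gz`).
#' @param dropIncomplete drop rows with missing biomarker/target
#'   (default TRUE).
#' @return data.frame with columns `disease`, `biomarker_gene`,
#'   `target_gene`, `evidence_level`, `complete`.
#' @export
readKnowledgeBase <- function(path, dropIncomplete = TRUE) {
  df <- .readDelim(path, header = TRUE)
  need <- c("disease", "biomarker_gene", "target_gene", "evidence_level")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("knowledge base ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[need]
  for (cc in need) df[[cc]] <- trimws(df[[cc]])
  df$complete <- nzchar(df$biomarker_gene) & !is.na(df$biomarker_gene) &
    nzchar(df$target_gene) & !is.na(df$target_gene)
  if (dropIncomplete) df <- df[df$complete, , drop = FALSE]
  df <- unique(df)
  rownames(df) <- NULL
  df
}
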