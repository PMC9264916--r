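# shared toy builders for the test suite; everything is generated in code

namedMat <- function(v, nr, nc, prefix = c("g", "s"), byrow = FALSE) {
  matrix(v, nr, nc, byrow = byrow,
         dimnames = list(sprintf("%s%d", prefix[1], seq_len(nr)),
                         sprintf("%s%d", prefix[2], seq_len(nc))))
}

toyEssentiality <- function(v, nr, nc) EssentialityMatrix(namedMat(v, nr, nc))

# one biomarker splitting columns into mut (first nMut) and wt (rest)
toyMutation <- function(nMut, n, name = "b1") {
  MutationMatrix(matrix(c(rep(1, nMut), rep(0, n - nMut)), 1, n,
                        dimnames = list(name, sprintf("s%d", seq_len(n)))))
}

writeTempTsv <- function(lines, ext = ".tsv") {
  tf <- tempfile(fileext = ext)
  writeLines(lines, tf)
  tf
}

# brute-force kNN imputation following the documented metric: RMS difference
# over co-observed columns, k nearest rows, mean of their observed values in
# the target column, row-mean fallback
bruteKnnImpute <- function(v, k) {
  out <- v
  for (i in seq_len(nrow(v))) for (j in seq_len(ncol(v))) {
    if (!is.na(v[i, j])) next
    d <- rep(Inf, nrow(v))
    for (r in seq_len(nrow(v))) {
      if (r == i) next
      co <- which(!is.na(v[i, ]) & !is.na(v[r, ]))
      if (length(co)) d[r] <- sqrt(mean((v[i, co] - v[r, co])^2))
    }
    ord <- order(d, seq_along(d))
    nbr <- head(ord[is.finite(d[ord])], k)
    vals <- v[nbr, j]
    vals <- vals[!is.na(vals)]
    out[i, j] <- if (length(vals)) mean(vals) else mean(v[i, ], na.rm = TRUE)
  }
  out
}

# small hub-structured test table straight from the simulator
simTestTable <- function(seed = 1, ...) {
  scr <- simulateScreen(simulationConfig(seed = seed, ...))
  list(screen = scr, tests = moderatedTTest(scr@D, scr@M))
}

pairKey <- function(d) paste(d$biomarker, d$knockout, sep = "\r")
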