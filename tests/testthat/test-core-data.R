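test_that("readMatrix parses ids, missing sentinels and both orientations", {
  tf <- writeTempTsv(c("gene\ts1\ts2", "A\t-1.5\t0.5", "B\tNA\t2", "C\t\t3"))
  m <- readMatrix(tf)
  expect_s4_class(m, "EssentialityMatrix")
  expect_identical(knockoutIds(m), c("A", "B", "C"))
  expect_identical(sampleIds(m), c("s1", "s2"))
  expect_identical(unname(missingMask(m)),
                   matrix(c(FALSE, TRUE, TRUE, FALSE, FALSE, FALSE), 3, 2))
  expect_equal(scores(m)["A", "s2"], 0.5)

  # transposed layout reads back as the transpose
  tt <- writeTempTsv(c("sample\tA\tB\tC", "s1\t-1.5\tNA\t",
                       "s2\t0.5\t2\t3"))
  m2 <- readMatrix(tt, orientation = "genes_cols")
  expect_equal(scores(m2), scores(m))
})

test_that("readMatrix round-trips through writeMatrix, including gzip", {
  v <- namedMat(c(1.25, -2, NA, 4e-3, 5, 6), 2, 3)
  m <- EssentialityMatrix(v)
  gz <- tempfile(fileext = ".tsv.gz")
  writeMatrix(m, gz)
  expect_equal(scores(readMatrix(gz)), v)
})

test_that("readMatrix rejects duplicate ids and non-numeric cells with context", {
  dup <- writeTempTsv(c("gene\ts1", "A\t1", "A\t2"))
  expect_error(readMatrix(dup), "A")
  bad <- writeTempTsv(c("gene\ts1\ts2", "A\t1\t2", "B\tx7\t3"))
  expect_error(readMatrix(bad), "line 3.*s1|s1.*line 3")
  expect_error(readMatrix(writeTempTsv("justoneheader")), "malformed|columns")
})

test_that("expression matrices must be non-negative and complete", {
  tf <- writeTempTsv(c("gene\ts1", "A\t-1"))
  expect_error(readMatrix(tf, what = "expression"), "non-negative")
  tf2 <- writeTempTsv(c("gene,s1,s2", "A,1.5,2"), ext = ".csv")
  x <- readMatrix(tf2, what = "expression")
  expect_s4_class(x, "ExpressionMatrix")
  expect_equal(unname(tpm(x)), matrix(c(1.5, 2), 1))
})

test_that("knnImpute returns complete matrices unchanged", {
  m <- toyEssentiality(rnorm(12), 3, 4)
  expect_identical(scores(knnImpute(m, k = 2)), scores(m))
})

test_that("knnImpute matches the brute-force nearest-neighbour oracle", {
  # k = 1: imputed value equals the single nearest row's value
  v <- namedMat(c(1, 2, NA, 1.1, 2.1, 3, 5, 6, 7), 3, 3, byrow = TRUE)
  got <- scores(knnImpute(EssentialityMatrix(v), k = 1))
  expect_equal(got, bruteKnnImpute(v, 1))
  expect_equal(got["g1", "s3"], 3)  # g2 is the nearest row

  # k = 2 on a 4-row toy: mean of the two nearest rows
  set.seed(41)
  v4 <- namedMat(rnorm(20), 4, 5)
  v4[2, 4] <- NA; v4[4, 1] <- NA
  expect_equal(scores(knnImpute(EssentialityMatrix(v4), k = 2)),
               bruteKnnImpute(v4, 2))

  # randomised cases, several k, preserving observed entries
  for (seed in 1:5) {
    set.seed(seed)
    v <- namedMat(rnorm(48), 6, 8)
    v[sample(length(v), 7)] <- NA
    if (any(rowSums(!is.na(v)) == 0)) next
    k <- sample(1:4, 1)
    got <- scores(knnImpute(EssentialityMatrix(v), k = k))
    expect_equal(got, bruteKnnImpute(v, k))
    expect_identical(got[!is.na(v)], v[!is.na(v)])
  }
})

test_that("knnImpute validates inputs and clamps oversized k", {
  v <- namedMat(c(NA, NA, 1, 2, 3, 4), 3, 2, byrow = TRUE)
  expect_error(knnImpute(EssentialityMatrix(v)), "all entries missing")
  v2 <- namedMat(c(1, 2, NA, 4, 5, 6), 3, 2, byrow = TRUE)
  expect_warning(out <- knnImpute(EssentialityMatrix(v2), k = 10), "clamped")
  expect_false(anyNA(scores(out)))
})

test_that("dichotomizeVariants applies the filters and is an idempotent OR", {
  genes <- c("KRAS", "TP53"); samples <- c("c1", "c2")
  emptyV <- data.frame(sample_id = character(), gene = character(),
                       variant_class = character(),
                       allelic_fraction = numeric(),
                       common = logical(), neutral = logical())
  expect_equal(unname(indicator(dichotomizeVariants(emptyV, genes, samples))),
               matrix(0, 2, 2))

  v <- data.frame(
    sample_id = c("c1", "c1", "c2", "c2", "c2"),
    gene = c("KRAS", "TP53", "KRAS", "KRAS", "TP53"),
    variant_class = c("silent", "missense", "missense", "missense",
                      "missense"),
    allelic_fraction = c(0.5, 0.5, 0.4, 0.6, 0.05),
    common = FALSE, neutral = FALSE)
  M <- dichotomizeVariants(v, genes, samples)
  # silent excluded; two qualifying KRAS/c2 variants still give 1; low
  # allelic fraction excluded
  expect_equal(indicator(M)["KRAS", "c1"], 0)
  expect_equal(indicator(M)["TP53", "c1"], 1)
  expect_equal(indicator(M)["KRAS", "c2"], 1)
  expect_equal(indicator(M)["TP53", "c2"], 0)

  # order invariance
  M2 <- dichotomizeVariants(v[sample(nrow(v)), ], genes, samples)
  expect_identical(indicator(M), indicator(M2))

  # unknown class is recoded with a warning, not an error
  v$variant_class[2] <- "weird_stuff"
  expect_warning(M3 <- dichotomizeVariants(v, genes, samples), "other")
  expect_equal(indicator(M3)["TP53", "c1"], 1)
})

test_that("alignSamples restricts to shared samples and prunes cohorts", {
  D <- toyEssentiality(rnorm(8), 2, 4)
  M <- toyMutation(2, 3)
  X <- ExpressionMatrix(namedMat(abs(rnorm(6)), 2, 3))
  co <- CohortSpec("toy", c("s1", "s4"))
  expect_message(expect_warning(al <- alignSamples(D, M, X, co), "s4"),
                 "dropped from D: s4")
  expect_identical(sampleIds(al$D), c("s1", "s2", "s3"))
  expect_identical(sampleIds(al$M), sampleIds(al$D))
  expect_identical(al$dropped$D, "s4")
  expect_identical(al$cohorts@memberSamples, "s1")

  # identical sample sets: nothing dropped, identical column order
  al2 <- alignSamples(al$D, al$M, al$X, al$cohorts)
  expect_true(all(lengths(al2$dropped) == 0))
  # idempotence
  expect_identical(scores(al2$D), scores(al$D))
  expect_identical(indicator(al2$M), indicator(al$M))

  Mfar <- MutationMatrix(matrix(1, 1, 1, dimnames = list("b", "zz")))
  expect_error(alignSamples(D, Mfar), "no shared sample")
})

test_that("class validity catches malformed objects", {
  expect_error(MutationMatrix(namedMat(c(0, 2), 1, 2)), "0 or 1")
  expect_error(ExpressionMatrix(namedMat(c(-1, 1), 1, 2)), "non-negative")
  expect_error(EssentialityMatrix(namedMat(c(Inf, 1), 1, 2)), "finite")
  expect_error(CohortSpec("x", c("a", "b"), c("b", "c")), "disjoint")
  expect_error(EssentialityMatrix(matrix(1)), "names")
})
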