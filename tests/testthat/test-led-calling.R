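# ten-pair toy modelled on the published AML ranking layout: a biomarker
# gene, an essential gene, the increment of essentiality, t, p and local FDR
amlToyTable <- function() {
  data.frame(
    biomarker = c("TGS1", "CLTCL1", "FLT3", "CDK14", "NPM1", "CDK14",
                  "NRAS", "NRAS", "EP300", "EP300"),
    knockout = c("SNRPF", "UBR5", "FLT3", "CDK2", "EEF2", "CCND2",
                 "NRAS", "PTPN11", "PLK1", "KLF2"),
    delta = c(-7.87, -6.66, -6.36, -3.95, 3.81, 2.97, -6.83, 4.17,
              -8.11, 3.69),
    t_stat = c(-4.05, -3.59, -4.53, -2.75, 3.34, 2.22, -8.71, 2.2,
               -4.04, 4.08),
    p_value = c(6.69e-4, 1.99e-3, 2.28e-4, 1.28e-2, 3.39e-3, 3.88e-2,
                4.67e-8, 4.05e-2, 7.01e-4, 6.38e-4),
    lfdr = c(0.336, 0.220, 0.200, 0.430, 0.596, 0.499, 1.38e-4, 0.589,
             0.217, 0.212),
    stringsAsFactors = FALSE)
}

test_that("calling keeps exactly the rows passing all three gates", {
  tab <- amlToyTable()
  called <- callLeds(tab)
  # brute-force filter oracle
  keep <- tab$p_value < 0.05 & tab$lfdr <= 0.6 & abs(tab$delta) > 2
  expect_setequal(pairKey(called), pairKey(tab[keep, ]))
  expect_equal(nrow(called), 10L)  # every published-style row passes
  # borderline nLED row with p ~ 0.039 and lfdr ~ 0.499 is retained
  expect_true("CCND2" %in% called$knockout)
  # ranked by p ascending; the strongest self-pair ranks first
  expect_equal(called$knockout[1], "NRAS")
  expect_equal(called$rank, seq_len(nrow(called)))
})

test_that("each gate excludes independently and order cannot matter", {
  tab <- amlToyTable()
  tab$p_value[6] <- 0.06            # p gate alone rejects
  tab$lfdr[5] <- 0.61               # lfdr gate alone rejects
  tab$delta[4] <- 1.9               # delta gate alone rejects
  called <- callLeds(tab)
  expect_false(any(called$knockout %in% c("CCND2", "EEF2", "CDK2")))
  expect_equal(nrow(called), 7L)
  # conjunction of gates: survivors equal intersection of single-gate runs
  s1 <- callLeds(tab, maxP = 0.05, maxLfdr = 1e6, minAbsDelta = 1e-9)
  s2 <- callLeds(tab, maxP = 1, maxLfdr = 0.6, minAbsDelta = 1e-9)
  s3 <- callLeds(tab, maxP = 1, maxLfdr = 1e6, minAbsDelta = 2)
  expect_setequal(pairKey(called),
                  intersect(intersect(pairKey(s1), pairKey(s2)), pairKey(s3)))
  expect_error(callLeds(tab, maxP = 0), "positive")
})

test_that("classification assigns pLED/nLED by sign and promotes duals", {
  leds <- classifyLeds(callLeds(amlToyTable()))
  expect_equal(leds$sign_class[leds$knockout == "FLT3"], "pLED")
  expect_equal(leds$led_type[leds$knockout == "FLT3"], "pLED")
  expect_equal(leds$sign_class[leds$knockout == "EEF2"], "nLED")
  # NRAS marks sensitivity to NRAS and resistance to PTPN11: dual; CDK14
  # also spans both signs (CDK2 sensitivity, CCND2 resistance) in this toy
  expect_setequal(attr(leds, "dualBiomarkers"),
                  c("NRAS", "EP300", "CDK14"))
  expect_true(all(leds$led_type[leds$biomarker == "NRAS"] == "dLED"))
  # promotion never changes the sign class
  expect_equal(leds$sign_class[leds$biomarker == "NRAS" &
                                 leds$knockout == "NRAS"], "pLED")
  # sign-class counts cover all records
  expect_equal(sum(leds$sign_class == "pLED") +
                 sum(leds$sign_class == "nLED"), nrow(leds))
})

test_that("single-signed biomarkers produce no dual dependencies", {
  tab <- amlToyTable()[1:3, ]
  leds <- classifyLeds(callLeds(tab))
  expect_length(attr(leds, "dualBiomarkers"), 0)
  expect_true(all(leds$led_type == "pLED"))
  bad <- tab; bad$delta[1] <- 0
  expect_error(classifyLeds(bad), "delta = 0")
})

test_that("relation filter honours the inclusive score threshold and modes", {
  leds <- data.frame(biomarker = c("A", "A", "FLT3"),
                     knockout = c("B", "D", "FLT3"),
                     delta = c(-3, -3, -6), p_value = 1e-3, lfdr = 0.1)
  edges <- data.frame(gene_a = c("A", "C", "A"),
                      gene_b = c("B", "B", "C"),
                      combined_score = c(400, 450, 450))
  direct <- relationFilter(leds, edges, minScore = 400, mode = "direct")
  # A-B at exactly 400 kept; A-D unsupported; self-pair always kept
  expect_setequal(pairKey(direct),
                  pairKey(leds[c(1, 3), ]))
  # D connects to nothing, but B and D share no neighbour; now test the
  # documented shared-neighbour case on a pair lacking a direct edge
  leds2 <- data.frame(biomarker = "A", knockout = "B",
                      delta = -3, p_value = 1e-3, lfdr = 0.1)
  edges2 <- data.frame(gene_a = c("A", "B"), gene_b = c("C", "C"),
                       combined_score = c(450, 450))
  expect_equal(nrow(relationFilter(leds2, edges2, mode = "direct")), 0L)
  shared <- relationFilter(leds2, edges2, mode = "shared_neighbor")
  expect_equal(nrow(shared), 1L)
  expect_true(shared$relation_supported)
})

test_that("empty edge lists keep only self-pairs, with a warning", {
  leds <- data.frame(biomarker = c("FLT3", "A"), knockout = c("FLT3", "B"),
                     delta = c(-6, -3), p_value = 1e-3, lfdr = 0.1)
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      combined_score = numeric())
  expect_warning(out <- relationFilter(leds, edges), "self-pairs")
  expect_equal(out$biomarker, "FLT3")
})

test_that("LED table and bipartite graph exports are well-formed", {
  leds <- classifyLeds(callLeds(amlToyTable()))
  tf <- tempfile(fileext = ".tsv")
  writeLedTable(leds, tf)
  back <- read.delim(tf)
  expect_equal(back$biomarker, leds$biomarker)
  expect_equal(back$increment_of_essentiality, leds$delta)
  jf <- tempfile(fileext = ".json")
  exportBipartiteGraph(leds, jf)
  g <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_setequal(unique(g$nodes$kind), c("variant", "knockout"))
  expect_equal(nrow(g$edges), nrow(leds))
})
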