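test_that("pi0 estimation is near 1 for uniform p-values and clamps extremes", {
  set.seed(31)
  pU <- runif(10000)
  expect_gte(estimatePi0(pU), 0.95)
  expect_lte(estimatePi0(pU), 1)
  grid <- (seq_len(10000) - 0.5) / 10000  # exact uniform grid
  expect_gte(estimatePi0(grid), 0.95)

  expect_warning(lo <- estimatePi0(rep(1e-4, 1000)), "clamped")
  expect_equal(lo, 1 / 1000)
  expect_error(estimatePi0(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_warning(estimatePi0(runif(10)), "fewer than 20")
})

test_that("pi0 recovery on a known 50/50 uniform-beta mixture", {
  set.seed(32)
  n <- 10000
  p <- c(runif(n / 2), rbeta(n / 2, 0.1, 1))
  for (m in c("bootstrap", "smoother")) {
    est <- estimatePi0(p, method = m)
    # lambda-tail estimators carry the Beta(0.1,1) tail mass, so the
    # analytic expectation is ~0.55; assert the 15% relative band
    expect_lt(abs(est - 0.5) / 0.5, 0.15)
  }
})

test_that("local FDR is ~1 under the null and capped at 1 everywhere", {
  set.seed(33)
  p <- runif(10000)
  l <- lfdrValues(localFdr(p))
  expect_lte(max(l), 1)
  expect_gte(median(l), 0.9)
  # boundary effect of the monotone density touches at most a handful
  expect_lt(mean(l < 0.9), 0.005)
  # monotone non-decreasing in p
  expect_true(all(diff(l[order(p)]) >= -1e-12))
})

test_that("local FDR matches the analytic mixture curve (MAE <= 0.05)", {
  set.seed(34)
  n <- 10000
  isAlt <- runif(n) < 0.2
  p <- ifelse(isAlt, rbeta(n, 0.2, 1), runif(n))
  m <- localFdr(p, pi0 = 0.8)
  truth <- 0.8 / (0.8 + 0.2 * 0.2 * p^(-0.8))
  qs <- quantile(p, c(0.05, 0.95))
  central <- p >= qs[1] & p <= qs[2]
  expect_lte(mean(abs(lfdrValues(m) - truth)[central]), 0.05)
  # density integrates to 1 by construction of the concave majorant
  expect_equal(sum(m@densityF * diff(m@densityX)), 1)
})

test_that("degenerate p-value sets fall back to lfdr = pi0", {
  expect_warning(m <- localFdr(rep(0.3, 30), pi0 = 0.7), "degenerate")
  expect_equal(lfdrValues(m), rep(0.7, 30))
})

test_that("grouped local FDR reduces to the pooled model for one group", {
  set.seed(35)
  tab <- data.frame(p_value = c(rbeta(100, 0.2, 1), runif(400)),
                    group_id = "only", skipped = FALSE)
  g <- groupedLocalFdr(tab)
  pooled <- localFdr(tab$p_value, pi0 = estimatePi0(tab$p_value))
  expect_equal(g$lfdr, lfdrValues(pooled))
  expect_false(any(g$group_fallback))
})

test_that("grouping sharpens lfdr for a signal-bearing group (hub mechanism)", {
  set.seed(36)
  nA <- 1000; nB <- 1000
  pA <- runif(nA)
  isAlt <- rep(c(TRUE, FALSE), each = nB / 2)
  pB <- ifelse(isAlt, rbeta(nB, 0.05, 1), runif(nB))
  tab <- data.frame(p_value = c(pA, pB),
                    group_id = rep(c("A", "B"), c(nA, nB)),
                    skipped = FALSE)
  g <- groupedLocalFdr(tab)
  pooled <- lfdrValues(localFdr(tab$p_value,
                                pi0 = estimatePi0(tab$p_value)))
  altIdx <- nA + which(isAlt)
  # grouped estimation gives the true alternatives a sharper (lower) lfdr
  expect_lt(median(g$lfdr[altIdx]), median(pooled[altIdx]))
  # the all-null group yields essentially no small-lfdr tests
  expect_lte(sum(g$lfdr[seq_len(nA)] <= 0.6), 5)
  # hub group shows the excess of small p-values that drives the mechanism
  di <- attr(g, "groupDiagnostics")
  expect_gt(di$frac_p_below_0.05[di$group_id == "B"], 0.3)
  expect_lt(di$frac_p_below_0.05[di$group_id == "A"], 0.1)
  expect_lt(di$pi0[di$group_id == "B"], di$pi0[di$group_id == "A"])
})

test_that("small groups fall back to the pooled model and are flagged", {
  set.seed(37)
  tab <- data.frame(p_value = runif(130),
                    group_id = rep(c("big", "small"), c(100, 30)),
                    skipped = FALSE)
  g <- groupedLocalFdr(tab, minGroupTests = 50)
  expect_true(all(g$group_fallback[tab$group_id == "small"]))
  expect_false(any(g$group_fallback[tab$group_id == "big"]))
})

test_that("Storey q-values follow the defining formula and reduce to BH", {
  # hand computation: p = {.01,.02,.03}, pi0 = 0.5 -> all q = 0.015
  expect_equal(storeyQvalues(c(0.01, 0.02, 0.03), pi0 = 0.5),
               rep(0.015, 3))
  set.seed(38)
  p <- runif(500)^1.5
  expect_equal(storeyQvalues(p, pi0 = 1), p.adjust(p, "BH"))
  # brute-force defining formula on a random instance
  pi0 <- 0.7
  q <- storeyQvalues(p, pi0 = pi0)
  n <- length(p)
  brute <- vapply(p, function(pi) {
    pi0 * min(1, min(n * p[p >= pi] / rank(p)[p >= pi]))
  }, numeric(1))
  expect_equal(q, brute)
  # ties: constant vector gives pi0 * p
  expect_equal(storeyQvalues(rep(0.2, 5), pi0 = 0.5), rep(0.1, 5))
  # monotone in p
  expect_true(all(diff(q[order(p)]) >= -1e-12))
})

test_that("classical corrections match brute-force textbook definitions", {
  bonfOracle <- function(p) pmin(1, p * length(p))
  holmOracle <- function(p) {
    n <- length(p); o <- order(p)
    adj <- cummax(pmin(1, (n - seq_len(n) + 1) * p[o]))
    adj[order(o)]
  }
  bhOracle <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    pmin(1, cummin(n / (n - seq_len(n) + 1) * p[o]))[order(o)]
  }
  toy <- c(0.01, 0.02, 0.03)
  expect_equal(classicalCorrections(toy, "bonferroni")$adjusted,
               c(0.03, 0.06, 0.09))
  expect_equal(classicalCorrections(toy, "holm")$adjusted,
               c(0.03, 0.04, 0.04))
  expect_equal(classicalCorrections(toy, "bh")$adjusted, rep(0.03, 3))
  for (seed in 1:5) {
    set.seed(seed)
    p <- runif(40)^2
    expect_equal(classicalCorrections(p, "bonferroni")$adjusted,
                 bonfOracle(p))
    expect_equal(classicalCorrections(p, "holm")$adjusted, holmOracle(p))
    expect_equal(classicalCorrections(p, "bh")$adjusted, bhOracle(p))
  }
  # single p-value unchanged; all-1 capped at 1
  expect_equal(classicalCorrections(0.2, "holm")$adjusted, 0.2)
  expect_equal(classicalCorrections(rep(1, 4), "bh")$adjusted, rep(1, 4))
})

test_that("covariate-weighted BH reduces to plain BH without group signal", {
  set.seed(39)
  # identical p-value multisets per group: equal estimated signal
  pg <- runif(100)
  tab <- data.frame(p_value = rep(pg, 3),
                    group_id = rep(c("a", "b", "c"), each = 100),
                    skipped = FALSE)
  cb <- covariateBH(tab, alpha = 0.2)
  expect_equal(unique(cb$weights), 1)
  expect_equal(cb$adjusted, p.adjust(tab$p_value, "BH"))
  # pure null: both procedures reject (essentially) nothing
  tabN <- data.frame(p_value = runif(300),
                     group_id = rep(c("a", "b", "c"), each = 100),
                     skipped = FALSE)
  cbN <- covariateBH(tabN, alpha = 0.2)
  expect_equal(sum(cbN$rejected), sum(p.adjust(tabN$p_value, "BH") <= 0.2))
})

test_that("covariate-weighted BH beats plain BH on hub-structured signal", {
  sim <- simTestTable(seed = 4)
  cb <- covariateBH(sim$tests, alpha = 0.2)
  plainBH <- sum(p.adjust(sim$tests$p_value, "BH") <= 0.2)
  expect_gte(sum(cb$rejected), plainBH)
  # hub groups carry large weights, pure-noise groups do not
  wHub <- mean(cb$weights[sim$tests$biomarker %in% sprintf("BM%03d", 1:5)])
  expect_gt(wHub, 1)
})

test_that("covariate-weighted BH validates alpha and warns on empty groups", {
  tab <- data.frame(p_value = runif(60),
                    group_id = factor(rep("a", 60), levels = c("a", "ghost")),
                    skipped = FALSE)
  expect_error(covariateBH(tab, alpha = 1.2), "alpha")
  expect_warning(cb <- covariateBH(tab, alpha = 0.2), "ghost")
  expect_equal(unique(cb$weights), 1)
})

test_that("lfdr and q-values are invariant to test-row permutation", {
  set.seed(40)
  tab <- data.frame(p_value = c(rbeta(150, 0.2, 1), runif(450)),
                    group_id = rep(c("g1", "g2", "g3"), each = 200),
                    skipped = FALSE)
  g1 <- groupedLocalFdr(tab)
  perm <- sample(nrow(tab))
  g2 <- groupedLocalFdr(tab[perm, ])
  expect_equal(g2$lfdr, g1$lfdr[perm])
  q1 <- storeyQvalues(tab$p_value, pi0 = 0.8)
  q2 <- storeyQvalues(tab$p_value[perm], pi0 = 0.8)
  expect_equal(q2, q1[perm])
})
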