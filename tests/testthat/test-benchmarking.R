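test_that("benchmarkLabels derives and checks the effective split", {
  lab <- benchmarkLabels(c("a", "b", "c"), ic50 = c(0.5, 10, 40))
  expect_equal(lab$effective, c(TRUE, FALSE, FALSE))  # 10 uM is ineffective
  expect_error(benchmarkLabels(c("a", "a"), ic50 = c(1, 2)), "duplicated")
  expect_error(benchmarkLabels("a", ic50 = 20, effective = TRUE),
               "contradict")
  expect_s3_class(agentSet("s", c("a", "b")), "AgentSet")
  expect_error(agentSet("s", character(0)), "non-empty")
})

test_that("drAuc reproduces hand-computed cases", {
  lab <- benchmarkLabels(c("e1", "e2", "i1", "i2"),
                         effective = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(drAuc(c(e1 = -3, e2 = -2, i1 = -1, i2 = 0), lab), 1.0)
  expect_equal(drAuc(c(e1 = -3, e2 = 0, i1 = -2, i2 = -1), lab), 0.5)
  lab3 <- benchmarkLabels(c("e1", "i1", "i2"),
                          effective = c(TRUE, FALSE, FALSE))
  expect_equal(drAuc(c(e1 = -1, i1 = -1, i2 = 0), lab3), 0.75)
  labBad <- benchmarkLabels(c("e1", "e2"), effective = c(TRUE, TRUE))
  expect_error(drAuc(c(e1 = 1, e2 = 2), labBad), "ineffective")
})

test_that("drAuc equals brute-force all-pairs concordance", {
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(4:30, 1)
    nE <- sample(seq_len(n - 1), 1)
    s <- round(rnorm(n), 1)  # rounding creates cross-class ties
    names(s) <- sprintf("c%02d", seq_len(n))
    eff <- c(rep(TRUE, nE), rep(FALSE, n - nE))[sample(n)]
    lab <- benchmarkLabels(names(s), effective = eff)
    expect_equal(drAuc(s, lab), bruteForceAuc(s, eff), tolerance = 1e-12)
  }
})

test_that("profiles collapse to the median compound score", {
  sc <- data.frame(profile_id = c("p1", "p2", "p3", "p4"),
                   compound_id = c("A", "A", "A", "B"),
                   xsum = c(-3, -1, 5, 0))
  lab <- benchmarkLabels(c("A", "B"), effective = c(TRUE, FALSE))
  expect_equal(drAuc(sc, lab, "xsum"), 1.0)  # median(A) = -1 < 0
  sc$xsum[4] <- NA
  expect_error(drAuc(sc, lab, "xsum"), "ineffective")  # B dropped as missing
})

test_that("permutation p for DR-AUC is seeded and calibrated to 1/6", {
  lab <- benchmarkLabels(c("e1", "e2", "i1", "i2"),
                         effective = c(TRUE, TRUE, FALSE, FALSE))
  s <- c(e1 = -3, e2 = -2, i1 = -1, i2 = 0)
  r1 <- drAucPermutation(s, lab, nPerm = 10000, seed = 3)
  r2 <- drAucPermutation(s, lab, nPerm = 10000, seed = 3)
  expect_identical(r1, r2)
  expect_equal(r1$dr_auc, 1.0)
  # exhaustive null over the 6 distinct labelings: P(AUC >= 1) = 1/6;
  # sampled estimate within the binomial 99% CI
  expect_lt(abs(r1$p_value - 1 / 6), 0.01)
  expect_gte(r1$p_value, 1 / 10001)
})

test_that("permuted-label AUC null is centred at 0.5", {
  set.seed(12)
  s <- setNames(rnorm(40), sprintf("c%02d", 1:40))
  eff <- rep(c(TRUE, FALSE), 20)
  lab <- benchmarkLabels(names(s), effective = eff)
  nPerm <- 2000
  nulls <- withr::with_seed(99, replicate(nPerm, {
    sigreverse:::.aucEffLow(s, sample(eff))
  }))
  se <- sd(nulls) / sqrt(nPerm)
  expect_lt(abs(mean(nulls) - 0.5), 3 * se + 1e-3)
})

test_that("drEs follows the GSEA sign convention on ranked compounds", {
  s <- setNames(seq(-5, 4), sprintf("c%02d", 1:10))  # c01 most reversing
  # agents = the 2 most-reversing compounds: bottom of the descending
  # ranking -> positions {9,10} -> strongly negative enrichment
  expect_equal(drEs(s, agentSet("a", c("c01", "c02"))),
               mdEnrichmentScore(c(9, 10), 10))
  expect_equal(drEs(s, agentSet("a", c("c01", "c02"))), -0.9)
  # mirror: least-reversing agents at the top -> +0.8
  expect_equal(drEs(s, agentSet("a", c("c09", "c10"))), 0.8)
  # uniformly interleaved agents -> near zero
  expect_lte(abs(drEs(s, agentSet("a", sprintf("c%02d", c(2, 4, 6, 8, 10))))),
             0.2)
  expect_error(drEs(s, agentSet("a", "zz")), "no agent")
})

test_that("moving an agent toward the reversal end never increases drEs", {
  set.seed(41)
  for (rep in 1:50) {
    n <- sample(10:25, 1)
    s <- setNames(sort(rnorm(n)), sprintf("c%02d", seq_len(n)))
    k <- sample(2:4, 1)
    agents <- sample(names(s), k)
    base <- drEs(s, agentSet("a", agents))
    # swap the least-reversing agent one rank toward the reversal end
    ord <- names(s)  # ascending score = reversal end first
    idx <- max(match(agents, ord))
    if (idx > 1 && !(ord[idx - 1] %in% agents)) {
      better <- c(setdiff(agents, ord[idx]), ord[idx - 1])
      expect_lte(drEs(s, agentSet("a", better)), base + 1e-12)
    }
  }
})

test_that("drEsPermutation is seeded, calibrated, and detects planted sets", {
  s <- setNames(seq(-10, 9), sprintf("c%02d", 1:20))
  agents <- agentSet("planted", sprintf("c%02d", 1:4))
  r1 <- drEsPermutation(s, agents, nPerm = 5000, seed = 5)
  r2 <- drEsPermutation(s, agents, nPerm = 5000, seed = 5)
  expect_identical(r1, r2)
  expect_lt(r1$p_value, 0.01)
  expect_equal(r1$agent_set_size, 4L)
  # the alternative null permutes scores instead of membership
  r3 <- drEsPermutation(s, agents, nPerm = 5000, seed = 5, null = "scores")
  expect_lt(r3$p_value, 0.01)
})

test_that("weighted DR-ES variant agrees in sign on a planted set", {
  s <- setNames(seq(-10, 9), sprintf("c%02d", 1:20))
  agents <- agentSet("planted", sprintf("c%02d", 1:4))
  expect_lt(drEs(s, agents, weighted = TRUE), 0)
  expect_gt(drEs(s, agentSet("a", sprintf("c%02d", 17:20)), weighted = TRUE),
            0)
})

test_that("topnSweep records each topN and holds KS/RGES constant", {
  fx <- smallSim()
  sw <- topnSweep(fx$hep, fx$sim$query, methods = c("xsum", "ks"),
                  topnRange = c(50, 52), labels = fx$bench$labels,
                  agents = fx$bench$agents)
  expect_equal(sum(sw$method == "xsum"), 3L)
  expect_equal(sum(sw$method == "ks"), 3L)
  ks <- sw[sw$method == "ks", ]
  expect_equal(length(unique(ks$dr_auc)), 1L)
  expect_equal(length(unique(ks$dr_es)), 1L)
  expect_error(topnSweep(fx$hep, fx$sim$query, topnRange = c(50, 1e5),
                         labels = fx$bench$labels,
                         agents = fx$bench$agents), "gene count")
})

test_that("topnSweep xsum rows match scoreProfiles at each topN", {
  fx <- smallSim()
  sw <- topnSweep(fx$hep, fx$sim$query, methods = "xsum",
                  topnRange = c(20, 22), labels = fx$bench$labels,
                  agents = fx$bench$agents)
  for (tN in 20:22) {
    sc <- scoreProfiles(fx$hep, fx$sim$query, methods = "xsum", topN = tN)
    expect_equal(sw$dr_auc[sw$topN == tN],
                 drAuc(sc, fx$bench$labels, "xsum"), tolerance = 1e-12)
    expect_equal(sw$dr_es[sw$topN == tN],
                 drEs(sc, fx$bench$agents, "xsum"), tolerance = 1e-12)
  }
})

test_that("binSummarize means equal an independent group-by average", {
  sweep <- data.frame(method = "xsum", topN = c(50, 60, 110, 120),
                      dr_auc = c(0.6, 0.7, 0.8, 0.9),
                      dr_es = c(-0.1, -0.2, -0.3, -0.4))
  class(sweep) <- c("SweepResult", "data.frame")
  bs <- binSummarize(sweep, binWidth = 50)
  expect_equal(bs$mean_dr_auc, c(0.65, 0.85))
  expect_equal(bs$mean_dr_es, c(-0.15, -0.35))
  expect_equal(bs$n, c(2L, 2L))

  # single-entry bin
  one <- sweep[1, ]; class(one) <- c("SweepResult", "data.frame")
  expect_equal(binSummarize(one, 50)$mean_dr_auc, 0.6)

  # random sweeps against independent tapply oracle
  set.seed(13)
  for (rep in 1:20) {
    sw <- data.frame(method = "xsum", topN = sample(50:489, 60),
                     dr_auc = runif(60), dr_es = runif(60, -1, 1))
    class(sw) <- c("SweepResult", "data.frame")
    bs <- binSummarize(sw, 50)
    lo <- min(sw$topN); hi <- max(sw$topN)
    grp <- pmin((sw$topN - lo) %/% 50, (hi - lo) %/% 50)
    oracleAuc <- as.numeric(tapply(sw$dr_auc, grp, mean))
    expect_equal(bs$mean_dr_auc, oracleAuc, tolerance = 1e-12)
  }
})

test_that("the last partial bin is flagged", {
  sw <- data.frame(method = "xsum", topN = c(450:489),
                   dr_auc = runif(40), dr_es = runif(40, -1, 0))
  class(sw) <- c("SweepResult", "data.frame")
  bs <- binSummarize(sw, 50)
  expect_true(all(bs$partial))
  expect_equal(bs$bin, "[450,489]")
})

test_that("sizeSweepRandom saturates at the full size and is seeded", {
  fx <- smallSim()
  q <- fx$sim$query
  full <- sigSize(q)
  sw <- sizeSweepRandom(q, sizes = c(5, full), reps = 8, refs = fx$hep,
                        labels = fx$bench$labels, agents = fx$bench$agents,
                        topN = 20, seed = 77)
  expect_equal(nrow(sw), 16L)
  fullRows <- sw[sw$size == full, ]
  expect_equal(length(unique(fullRows$dr_auc)), 1L)  # all reps identical
  expect_equal(length(unique(fullRows$dr_es)), 1L)
  sw2 <- sizeSweepRandom(q, sizes = c(5, full), reps = 8, refs = fx$hep,
                         labels = fx$bench$labels, agents = fx$bench$agents,
                         topN = 20, seed = 77)
  expect_identical(sw, sw2)
  expect_error(sizeSweepRandom(q, sizes = full + 1, reps = 2, refs = fx$hep,
                               labels = fx$bench$labels,
                               agents = fx$bench$agents, seed = 1),
               "exceeds")
})

test_that("sizeSweepFc thresholds, deduplicates and orders signatures", {
  de <- data.frame(gene = c("a", "b", "c", "d", "e"),
                   log2fc = c(1.2, 0.8, 0.4, -0.5, -1.1),
                   p_value = 0.001, adjusted_p = 0.005)
  sigs <- sizeSweepFc(de, start = 0.1, step = 0.05)
  # tau = 0.45 signature: up {a,b}, down {d,e}
  sizes <- vapply(sigs, sigSize, numeric(1))
  expect_equal(sizes, sort(sizes, decreasing = TRUE))
  tau45 <- Filter(function(s) isTRUE(all.equal(attr(s, "threshold"), 0.45)),
                  sigs)
  expect_length(tau45, 1L)
  expect_setequal(upGenes(tau45[[1]]), c("a", "b"))
  expect_setequal(downGenes(tau45[[1]]), c("d", "e"))
  # duplicates removed: distinct gene sets only
  fps <- vapply(sigs, function(s)
    paste(sort(sigGenes(s)), collapse = ";"), character(1))
  expect_false(any(duplicated(fps)))
  # thresholds beyond max |log2fc| contribute nothing / empty result
  expect_length(sizeSweepFc(de, start = 1.3), 0L)
  # p cut filters the candidate genes
  de$adjusted_p[1] <- 0.5
  sigs2 <- sizeSweepFc(de, start = 0.1, step = 0.05, pCut = 0.01)
  expect_false("a" %in% sigGenes(sigs2[[1]]))
})
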