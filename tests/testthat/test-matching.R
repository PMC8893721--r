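test_that("extremeTrim keeps the extreme tails and zeroes the rest", {
  p <- c(a = 3, b = 2, c = 1, d = -1, e = -2, f = -3)
  expect_equal(extremeTrim(p, 1),
               c(a = 3, b = 0, c = 0, d = 0, e = 0, f = -3))
  expect_equal(extremeTrim(p, 3), p)   # saturation: topN >= n/2
  expect_equal(extremeTrim(p, 10), p)
  expect_error(extremeTrim(p, 0), "topN")
  expect_error(extremeTrim(unname(p), 1), "named")
})

test_that("extremeTrim resolves ties by smaller gene identifier", {
  p <- c(b = 2, a = 2, c = 1, d = -1, e = -1.5, f = -1.5)
  tr <- extremeTrim(p, 1)
  expect_equal(tr[["a"]], 2)
  expect_equal(tr[["b"]], 0)
  expect_equal(tr[["e"]], -1.5)  # e < f lexicographically
  expect_equal(tr[["f"]], 0)
})

test_that("extremeTrim agrees with an exhaustive sort oracle", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(6:20, 1)
    topN <- sample(1:2, 1)
    vals <- round(rnorm(n), 1)  # rounding forces ties
    names(vals) <- sprintf("g%02d", sample(n))
    tr <- extremeTrim(vals, topN)
    if (2 * topN >= n) {
      expect_identical(tr, vals)
      next
    }
    # oracle: full sort on (value, gene id) keys
    keyUp <- order(-vals, names(vals))
    keyDn <- order(vals, names(vals))
    keep <- union(names(vals)[keyUp[1:topN]], names(vals)[keyDn[1:topN]])
    expect_setequal(names(tr)[tr != 0], intersect(keep, names(vals)[vals != 0]))
    expect_equal(tr[keep], vals[keep])
    expect_lte(sum(tr != 0), 2 * topN)
  }
})

test_that("scoreXsum is sum over up minus sum over down", {
  q <- querySignature("g1", "g2")
  tr <- c(g1 = 2.0, g2 = -1.5, g3 = 0)
  expect_equal(scoreXsum(tr, q), 3.5)
  expect_equal(scoreXsum(c(g1 = -2.0, g2 = 1.5, g3 = 0), q), -3.5)
  expect_equal(scoreXsum(c(g1 = 0, g2 = 0, g3 = 5), q), 0)
  expect_error(scoreXsum(c(x = 1), q), "aligned")
})

test_that("eXtreme correlations are reversal-oriented with missing cases", {
  q <- querySignature("g1", "g2")
  # mimicry: profile matches the query pattern -> +1 (worst for reversal)
  expect_equal(scoreExtremeCorrelation(c(g1 = 1, g2 = -1), q, "xcos"), 1)
  # perfect reversal: profile is the exact negation -> -1 (best)
  expect_equal(scoreExtremeCorrelation(c(g1 = -1, g2 = 1), q, "xcos"), -1)
  # hand-derived: cos = 3.5 / (sqrt(2) * 2.5)
  expect_equal(scoreExtremeCorrelation(c(g1 = 2, g2 = -1.5), q, "xcos"),
               3.5 / (sqrt(2) * 2.5), tolerance = 1e-12)
  expect_equal(scoreExtremeCorrelation(c(g1 = -2, g2 = 1.5), q, "xcos"),
               -3.5 / (sqrt(2) * 2.5), tolerance = 1e-12)
  # all query genes trimmed out -> zero norm -> NA
  expect_true(is.na(scoreExtremeCorrelation(c(g1 = 0, g2 = 0), q, "xcos")))
  expect_true(is.na(scoreExtremeCorrelation(c(g1 = 1, g2 = 1), q, "xcor")))
})

test_that("mdEnrichmentScore matches its defining examples", {
  expect_equal(mdEnrichmentScore(c(1, 2), 10), 0.8)
  expect_equal(mdEnrichmentScore(c(9, 10), 10), -0.9)
  expect_equal(mdEnrichmentScore(4, 4), -1)
  expect_error(mdEnrichmentScore(integer(0), 10), "empty")
  expect_error(mdEnrichmentScore(c(0, 2), 10), "within")
  expect_error(mdEnrichmentScore(c(2, 11), 10), "within")
})

test_that("mdEnrichmentScore equals brute-force enumeration on random lists", {
  set.seed(7)
  for (rep in 1:300) {
    n <- sample(5:50, 1)
    t <- sample(1:min(10, n), 1)
    pos <- sample(n, t)
    expect_equal(mdEnrichmentScore(pos, n), bruteForceMdEs(pos, n),
                 tolerance = 1e-12)
  }
})

test_that("KS and RGES follow the same-sign rule", {
  # toy list of 10 genes ranked g01 (top) .. g10 (bottom)
  prof <- setNames(seq(10, 1), sprintf("g%02d", 1:10))
  topQ <- querySignature(c("g01", "g02"), c("g09", "g10"))
  expect_equal(scoreKs(prof, topQ), 0.8 - (-0.9))   # 1.7, concordant
  expect_equal(scoreRges(prof, topQ), 1.7)

  revQ <- querySignature(c("g09", "g10"), c("g01", "g02"))
  expect_equal(scoreKs(prof, revQ), -0.9 - 0.8)     # -1.7, reversal
  expect_equal(scoreRges(prof, revQ), -1.7)

  # both sets in the top half: same sign -> KS 0, RGES keeps the difference
  sameQ <- querySignature(c("g01", "g02"), c("g03", "g04"))
  esUp <- mdEnrichmentScore(c(1, 2), 10)
  esDn <- mdEnrichmentScore(c(3, 4), 10)
  expect_gt(esUp * esDn, 0)
  expect_equal(scoreKs(prof, sameQ), 0)
  expect_equal(scoreRges(prof, sameQ), esUp - esDn)

  expect_error(scoreKs(prof, querySignature("g01", "zz")), "aligned")
})

test_that("KS/RGES law holds over randomized profile-query pairs", {
  set.seed(23)
  genes <- sprintf("g%02d", 1:30)
  for (rep in 1:300) {
    prof <- setNames(rnorm(30), genes)
    q <- randomSignatureFor(genes, sample(2:5, 1), sample(2:5, 1))
    esu <- mdEnrichmentScore(
      sigreverse:::.rankedPositions(prof, upGenes(q)), 30)
    esd <- mdEnrichmentScore(
      sigreverse:::.rankedPositions(prof, downGenes(q)), 30)
    ks <- scoreKs(prof, q); rges <- scoreRges(prof, q)
    if (sign(esu) != sign(esd)) expect_identical(ks, rges)
    else expect_identical(ks, 0)
    expect_equal(rges, esu - esd)
  }
})

test_that("XSum is positively homogeneous with trimming held fixed", {
  set.seed(5)
  genes <- sprintf("g%02d", 1:40)
  prof <- setNames(rnorm(40), genes)
  q <- randomSignatureFor(genes, 4, 4)
  tr <- extremeTrim(prof, 8)
  for (alpha in c(0.5, 2, 7.3)) {
    expect_equal(scoreXsum(alpha * tr, q), alpha * scoreXsum(tr, q),
                 tolerance = 1e-12)
  }
})

test_that("negating a profile negates XSum and flips enrichment signs", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:50)
  for (rep in 1:20) {
    prof <- setNames(rnorm(50), genes)  # continuous: tie-free
    q <- randomSignatureFor(genes, 5, 5)
    tr <- extremeTrim(prof, 10); trNeg <- extremeTrim(-prof, 10)
    expect_equal(scoreXsum(trNeg, q), -scoreXsum(tr, q), tolerance = 1e-12)
    # es_up and es_down each flip sign (the MD statistic is not
    # magnitude-antisymmetric, only sign-antisymmetric); under list
    # reversal the two running maxima swap up to +-1/n, so the flip is
    # guaranteed except when ES = -b with b - a <= 2/n (near-balanced walk)
    for (set in list(upGenes(q), downGenes(q))) {
      pos <- sort(sigreverse:::.rankedPositions(prof, set))
      t <- length(pos); j <- seq_len(t)
      a <- max(j / t - pos / 50); b <- max(pos / 50 - (j - 1) / t)
      es <- mdEnrichmentScore(pos, 50)
      esNeg <- mdEnrichmentScore(
        sigreverse:::.rankedPositions(-prof, set), 50)
      if (es > 0 || b - a > 2 / 50 + 1e-9) expect_lt(es * esNeg, 0)
    }
    # hence KS flips sign or collapses to 0 under the same-sign rule
    ks <- scoreKs(prof, q); ksNeg <- scoreKs(-prof, q)
    expect_lte(ks * ksNeg, 0)
  }
})

test_that("scoreProfiles has the right shape and is deterministic", {
  fx <- smallSim()
  q <- fx$sim$query
  sc <- scoreProfiles(fx$hep, q, methods = c("xsum", "xcos"), topN = 20)
  expect_equal(nrow(sc), ncol(fx$hep))
  expect_true(all(c("profile_id", "compound_id", "xsum", "xcos") %in%
                    colnames(sc)))
  expect_equal(attr(sc, "topN"), 20)
  expect_true(all(abs(sc$xcos) <= 1))
  sc2 <- scoreProfiles(fx$hep, q, methods = c("xsum", "xcos"), topN = 20)
  expect_identical(sc, sc2)
})

test_that("scoreProfiles batch path matches the per-profile primitives", {
  fx <- smallSim()
  q <- alignQuery(fx$sim$query, fx$hep)
  sc <- scoreProfiles(fx$hep, q, topN = 20)
  vals <- zscores(fx$hep)
  for (j in c(1, 7, 30)) {
    prof <- vals[, j]
    tr <- extremeTrim(prof, 20)
    expect_equal(sc$xsum[j], scoreXsum(tr, q), tolerance = 1e-12)
    expect_equal(sc$xcos[j], scoreExtremeCorrelation(tr, q, "xcos"),
                 tolerance = 1e-12)
    expect_equal(sc$xcor[j], scoreExtremeCorrelation(tr, q, "xcor"),
                 tolerance = 1e-12)
    expect_equal(sc$xspe[j], scoreExtremeCorrelation(tr, q, "xspe"),
                 tolerance = 1e-12)
    expect_equal(sc$ks[j], scoreKs(prof, q), tolerance = 1e-12)
    expect_equal(sc$rges[j], scoreRges(prof, q), tolerance = 1e-12)
  }
})

test_that("a planted perfect reverser ranks first under every method", {
  set.seed(9)
  genes <- sprintf("g%03d", 1:100)
  q <- querySignature(genes[1:10], genes[11:18])
  vals <- matrix(rnorm(100 * 20, sd = 0.3), 100, 20,
                 dimnames = list(genes, sprintf("p%02d", 1:20)))
  qv <- queryVector(q)
  vals[names(qv), 5] <- -5 * qv + rnorm(18, sd = 0.05)
  refs <- tinyRefs(values = vals)
  sc <- scoreProfiles(refs, q, topN = 15)
  for (m in c("xsum", "xcos", "xcor", "xspe", "ks", "rges")) {
    expect_equal(which.min(sc[[m]]), 5L, label = m)
  }
})

test_that("scores are invariant to gene-order permutation of the matrix", {
  fx <- smallSim()
  q <- fx$sim$query
  sc <- scoreProfiles(fx$hep, q, topN = 20)
  perm <- sample(nrow(fx$hep))
  shuffled <- referenceProfileSet(zscores(fx$hep)[perm, ],
                                 profileMeta(fx$hep))
  sc2 <- scoreProfiles(shuffled, q, topN = 20)
  for (m in c("xsum", "xcos", "xcor", "xspe", "ks", "rges"))
    expect_equal(sc[[m]], sc2[[m]], tolerance = 1e-12, label = m)
})
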