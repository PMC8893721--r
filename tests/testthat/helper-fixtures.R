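# Shared fixtures, all built in code. Expensive ones are memoised for the
# duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# Tiny hand-built reference set: 6 genes, explicit values.
tinyRefs <- function(values = NULL, cells = NULL, compounds = NULL) {
  if (is.null(values)) {
    values <- cbind(p1 = c(3, 2, 1, -1, -2, -3),
                    p2 = c(-3, -2, -1, 1, 2, 3))
    rownames(values) <- paste0("g", 1:6)
  }
  n <- ncol(values)
  meta <- data.frame(
    profile_id = colnames(values),
    compound_id = if (is.null(compounds)) paste0("c", seq_len(n)) else compounds,
    cell_line = if (is.null(cells)) rep("CL01", n) else cells,
    dose = 10, time = 6, is_gold = TRUE,
    stringsAsFactors = FALSE)
  referenceProfileSet(values, meta)
}

# Small but realistic simulated fixture (single cell line for scoring).
smallSim <- function() memoise_fixture("smallSim", function() {
  cfg <- simConfig(nGenes = 200, nCompounds = 60, nCellLines = 2,
                   nUp = 15, nDown = 10, agentSetSize = 8, seed = 42)
  sim <- simulateReference(cfg)
  bench <- simulateBenchmark(sim$truth, cfg)
  list(cfg = cfg, sim = sim, bench = bench,
       hep = filterProfiles(sim$refs, cellLine = "CL01", verbose = FALSE))
})

# The default study-condition fixture (978 genes, 500 compounds, 9 cell
# lines, 10% reversers), scored in one cell line.
defaultFixture <- function() memoise_fixture("defaultFixture", function() {
  cfg <- simConfig(seed = 2024)
  sim <- simulateReference(cfg)
  bench <- simulateBenchmark(sim$truth, cfg)
  hep <- filterProfiles(sim$refs, cellLine = "CL01", verbose = FALSE)
  list(cfg = cfg, sim = sim, bench = bench, hep = hep)
})

# Independent brute-force oracles ------------------------------------------

# Maximum-deviation ES by explicit enumeration over every list position.
bruteForceMdEs <- function(positions, n) {
  isHit <- seq_len(n) %in% positions
  t <- sum(isHit)
  a <- -Inf; b <- -Inf
  for (i in seq_len(n)) {
    if (isHit[i]) {
      j <- sum(isHit[seq_len(i)])
      a <- max(a, j / t - i / n)
      b <- max(b, i / n - (j - 1) / t)
    }
  }
  if (a > b) a else -b
}

# All-pairs concordance AUC with half-credit ties (effective scores lower).
bruteForceAuc <- function(scores, effective) {
  e <- scores[effective]; i <- scores[!effective]
  tot <- 0
  for (x in e) for (y in i)
    tot <- tot + if (x < y) 1 else if (x == y) 0.5 else 0
  tot / (length(e) * length(i))
}

randomSignatureFor <- function(genes, nUp, nDown, name = "q") {
  pick <- sample(genes, nUp + nDown)
  querySignature(pick[seq_len(nUp)], pick[nUp + seq_len(nDown)], name = name)
}
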