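#' Configuration for the synthetic LINCS-like generator
#'
#' Bundles every parameter of the simulation: reference-set shape, the
#' additive profile model (shared + cell-specific + noise components),
#' planted reversal signal, the disease signature shape, the pseudo-IC50
#' mapping, and the agent-set sampling. Defaults mirror the scale anchors
#' of the emulated platform: 978 landmark genes, 9 heavily profiled cell
#' lines, an IC50 threshold of 10 uM, and a 27-compound agent set. The
#' config is a plain serialisable list; the same config (including
#' \code{seed}) yields bit-identical outputs.
#'
#' @param nGenes gene-space size (default 978).
#' @param nCellLines number of cell lines (default 9).
#' @param nCompounds number of compounds (default 500).
#' @param noiseSd residual noise sd (z-score units, default 1).
#' @param sharing sharing coefficient s in [0, 1]: weight of the
#'   cross-cell-line shared response component. A scalar, a
#'   length-\code{nCompounds} vector, or a named per-MOA vector (names
#'   "MOA1".."MOAk"); default 0.1 (weak sharing).
#' @param nMoas number of mechanism-of-action groups compounds are
#'   round-robin assigned to (default 10).
#' @param reverserFraction fraction of compounds planted as reversers of
#'   the disease signature (default 0.1).
#' @param betaRange reversal-strength range, beta ~ Unif(range)
#'   (default c(0.5, 2)).
#' @param nUp,nDown disease-signature shape (default 48 up, 22 down).
#' @param effectRange |log2FC| magnitude range of the disease pattern,
#'   drawn Unif(range) per gene (default c(1, 3)).
#' @param ic50A,ic50B pseudo-IC50 mapping: log10(IC50/uM) =
#'   \code{ic50A - ic50B * beta} for reversers (beta = 0 otherwise), plus
#'   lognormal jitter. Defaults a = 1.5, b = 1.5 place non-reversers near
#'   32 uM (ineffective) and strong reversers well below 10 uM.
#' @param ic50JitterSd sd of the log10 jitter (default 0.25).
#' @param agentSetSize curated agent-set size (default 27).
#' @param agentWeight agent sampling exponent: compounds drawn with
#'   probability proportional to \code{beta^agentWeight}, so the default 1
#'   gives beta-proportional weights (non-reversers, beta = 0, are only
#'   used to fill up the set when fewer than \code{agentSetSize} compounds
#'   have positive weight) and 0 gives uniform sampling.
#' @param nPerGroup samples per group in the synthetic case/control
#'   expression matrix (default 10).
#' @param querySd per-gene expression sd in that matrix (default 0.5).
#' @param seed integer master seed; all sub-streams derive from it.
#' @return list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenes = 978, nCellLines = 9, nCompounds = 500,
                      noiseSd = 1, sharing = 0.1, nMoas = 10,
                      reverserFraction = 0.1, betaRange = c(0.5, 2),
                      nUp = 48, nDown = 22, effectRange = c(1, 3),
                      ic50A = 1.5, ic50B = 1.5, ic50JitterSd = 0.25,
                      agentSetSize = 27, agentWeight = 1,
                      nPerGroup = 10, querySd = 0.5, seed = 1) {
  cfg <- list(nGenes = nGenes, nCellLines = nCellLines,
              nCompounds = nCompounds, noiseSd = noiseSd, sharing = sharing,
              nMoas = nMoas, reverserFraction = reverserFraction,
              betaRange = betaRange, nUp = nUp, nDown = nDown,
              effectRange = effectRange, ic50A = ic50A, ic50B = ic50B,
              ic50JitterSd = ic50JitterSd, agentSetSize = agentSetSize,
              agentWeight = agentWeight, nPerGroup = nPerGroup,
              querySd = querySd, seed = seed)
  .validateSimConfig(cfg)
  class(cfg) <- c("SimConfig", "list")
  cfg
}

.validateSimConfig <- function(cfg) {
  with(cfg, {
    if (nGenes < 4 || nCompounds < 1 || nCellLines < 1)
      stopInput("nGenes >= 4, nCompounds >= 1, nCellLines >= 1 required")
    if (reverserFraction < 0 || reverserFraction > 1)
      stopInput("reverserFraction must be in [0, 1]")
    if (any(sharing < 0) || any(sharing > 1))
      stopInput("sharing coefficients must be in [0, 1]")
    if (betaRange[1] > betaRange[2] || betaRange[1] < 0)
      stopInput("betaRange must satisfy 0 <= min <= max")
    if (effectRange[1] > effectRange[2] || effectRange[1] < 0)
      stopInput("effectRange must satisfy 0 <= min <= max")
    if (noiseSd < 0 || querySd < 0 || ic50JitterSd < 0)
      stopInput("standard deviations must be non-negative")
    if (nUp + nDown > nGenes)
      stopInput("signature size nUp + nDown exceeds nGenes")
    if (nUp < 1 || nDown < 1)
      stopInput("nUp and nDown must be >= 1")
    if (length(seed) != 1L || is.na(seed))
      stopInput("seed must be a single integer")
  })
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(paste0(
    "SimConfig: %d genes x %d compounds x %d cell lines (seed %d)\n",
    "  noise sd %.2g, reversers %.0f%% with beta in [%.2g, %.2g]\n",
    "  signature %d up / %d down, |log2FC| in [%.2g, %.2g]\n"),
    x$nGenes, x$nCompounds, x$nCellLines, x$seed, x$noiseSd,
    100 * x$reverserFraction, x$betaRange[1], x$betaRange[2],
    x$nUp, x$nDown, x$effectRange[1], x$effectRange[2]))
  invisible(x)
}

# Independent sub-streams of the master seed (kept within 32-bit range).
.subSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 131 + k) %% 2147483647)
}

# The planted disease pattern is a deterministic function of the config, so
# simulateReference() and simulateQuery() agree without sharing state.
.diseasePattern <- function(cfg) {
  withSeed(.subSeed(cfg$seed, 1), {
    genes <- sprintf("G%04d", seq_len(cfg$nGenes))
    sigGenes <- sample(genes, cfg$nUp + cfg$nDown)
    up <- sigGenes[seq_len(cfg$nUp)]
    down <- sigGenes[cfg$nUp + seq_len(cfg$nDown)]
    mag <- c(stats::runif(cfg$nUp, cfg$effectRange[1], cfg$effectRange[2]),
             -stats::runif(cfg$nDown, cfg$effectRange[1], cfg$effectRange[2]))
    names(mag) <- c(up, down)
    list(genes = genes, up = up, down = down, magnitude = mag)
  })
}

.patternSignature <- function(pat, name = "planted_disease") {
  mag <- pat$magnitude
  if (any(mag == 0)) mag <- numeric(0)  # degenerate zero-effect config
  querySignature(pat$up, pat$down, mag, name)
}

#' Simulate a LINCS-like reference profile set
#'
#' Generates z-score profiles under an additive model: the profile of
#' compound k in cell line c is
#' \code{s_k * shared_k + (1 - s_k) * specific_kc + noise}, with shared and
#' cell-specific components standard normal and noise
#' \code{N(0, noiseSd^2)}. Compounds flagged as reversers additionally
#' receive \code{-beta_k * pattern} on the disease-signature genes in every
#' cell line, where the pattern carries the signed log2FC magnitudes. All
#' profiles sit in one perturbation stratum (10 uM, 6 h, is_gold).
#'
#' @param cfg a [simConfig()].
#' @return list with \code{refs} (a \linkS4class{ReferenceProfileSet}),
#'   \code{truth} (data.frame: \code{compound_id}, \code{moa},
#'   \code{sharing}, \code{is_reverser}, \code{beta}) and \code{query} (the
#'   ground-truth \linkS4class{QuerySignature}). The truth record is also
#'   stored in \code{metadata(refs)$truth}.
#' @examples
#' sim <- simulateReference(simConfig(nGenes = 60, nCompounds = 20,
#'                                    nCellLines = 2, nUp = 10, nDown = 5,
#'                                    seed = 1))
#' sim$refs
#' @export
simulateReference <- function(cfg) {
  .validateSimConfig(cfg)
  pat <- .diseasePattern(cfg)
  genes <- pat$genes
  compounds <- sprintf("CPD%04d", seq_len(cfg$nCompounds))
  cells <- sprintf("CL%02d", seq_len(cfg$nCellLines))
  moa <- sprintf("MOA%d", ((seq_len(cfg$nCompounds) - 1L) %% cfg$nMoas) + 1L)
  sharing <- cfg$sharing
  if (!is.null(names(sharing)) && length(sharing) > 1L) {
    sharing <- unname(sharing[moa])
    if (any(is.na(sharing)))
      stopInput("per-MOA sharing vector must name every MOA group")
  } else if (length(sharing) == 1L) {
    sharing <- rep(sharing, cfg$nCompounds)
  } else if (length(sharing) != cfg$nCompounds) {
    stopInput("sharing must be scalar, per-MOA named, or per-compound")
  }
  out <- withSeed(.subSeed(cfg$seed, 2), {
    nRev <- round(cfg$reverserFraction * cfg$nCompounds)
    isRev <- logical(cfg$nCompounds)
    if (nRev > 0) isRev[sample(cfg$nCompounds, nRev)] <- TRUE
    beta <- numeric(cfg$nCompounds)
    beta[isRev] <- stats::runif(nRev, cfg$betaRange[1], cfg$betaRange[2])
    G <- cfg$nGenes
    sigIdx <- match(names(pat$magnitude), genes)
    values <- matrix(0, G, cfg$nCompounds * cfg$nCellLines)
    col <- 0L
    for (k in seq_len(cfg$nCompounds)) {
      shared <- stats::rnorm(G)
      revTerm <- if (isRev[k]) -beta[k] * pat$magnitude else NULL
      for (c in seq_len(cfg$nCellLines)) {
        specific <- stats::rnorm(G)
        eps <- if (cfg$noiseSd > 0) stats::rnorm(G, sd = cfg$noiseSd) else 0
        v <- sharing[k] * shared + (1 - sharing[k]) * specific + eps
        if (!is.null(revTerm)) v[sigIdx] <- v[sigIdx] + revTerm
        col <- col + 1L
        values[, col] <- v
      }
    }
    list(values = values, isRev = isRev, beta = beta)
  })
  rownames(out$values) <- genes
  meta <- data.frame(
    profile_id = paste(rep(compounds, each = cfg$nCellLines),
                       rep(cells, cfg$nCompounds), sep = "_"),
    compound_id = rep(compounds, each = cfg$nCellLines),
    cell_line = rep(cells, cfg$nCompounds),
    dose = 10, time = 6, is_gold = TRUE,
    moa = rep(moa, each = cfg$nCellLines),
    clinical_phase = NA_character_,
    stringsAsFactors = FALSE)
  colnames(out$values) <- meta$profile_id
  refs <- referenceProfileSet(out$values, meta)
  truth <- data.frame(compound_id = compounds, moa = moa,
                      sharing = sharing, is_reverser = out$isRev,
                      beta = out$beta, stringsAsFactors = FALSE)
  S4Vectors::metadata(refs)$truth <- truth
  list(refs = refs, truth = truth, query = .patternSignature(pat))
}

#' Simulate benchmark labels and an agent set from a truth record
#'
#' Maps each compound's planted reversal strength to a pseudo-IC50,
#' \code{log10(IC50) = ic50A - ic50B * beta + N(0, ic50JitterSd^2)} (beta =
#' 0 for non-reversers), splits compounds at the 10 uM threshold, and
#' samples an agent set of \code{agentSetSize} compounds with probability
#' proportional to \code{beta^agentWeight} (beta-proportional by default,
#' emulating a curated set of genuinely active agents; uniform when
#' \code{agentWeight = 0}). When fewer than \code{agentSetSize} compounds
#' carry positive weight the remainder is drawn uniformly from the rest.
#'
#' @param truth truth data.frame from [simulateReference()].
#' @param cfg the same [simConfig()].
#' @return list with \code{labels} (a [benchmarkLabels()]) and
#'   \code{agents} (an [agentSet()]).
#' @export
simulateBenchmark <- function(truth, cfg) {
  .validateSimConfig(cfg)
  if (nrow(truth) < cfg$agentSetSize)
    stopInput("fewer compounds (%d) than agentSetSize (%d)",
              nrow(truth), cfg$agentSetSize)
  withSeed(.subSeed(cfg$seed, 3), {
    log10ic <- cfg$ic50A - cfg$ic50B * truth$beta +
      stats::rnorm(nrow(truth), sd = cfg$ic50JitterSd)
    labels <- benchmarkLabels(truth$compound_id, ic50 = 10^log10ic)
    w <- truth$beta^cfg$agentWeight  # 0^0 == 1: exponent 0 is uniform
    k <- cfg$agentSetSize
    pos <- which(w > 0)
    picked <- if (length(pos) >= k) {
      sample(truth$compound_id[pos], k, prob = w[pos])
    } else {
      c(truth$compound_id[pos],
        sample(truth$compound_id[-pos], k - length(pos)))
    }
    list(labels = labels,
         agents = agentSet("synthetic_agents", picked))
  })
}

#' Simulate a disease query signature with its expression realisation
#'
#' Emits the planted disease pattern three ways: the ground-truth
#' \linkS4class{QuerySignature}; a synthetic case/control log2-scale
#' expression matrix realising it (case mean minus control mean equals the
#' pattern's log2FC on signature genes, zero elsewhere; per-gene sd
#' \code{querySd}); and the DE table obtained by running [deSignature()]
#' on that matrix. This closes the loop for end-to-end tests of signature
#' extraction and size sweeps.
#'
#' @param cfg a [simConfig()].
#' @return list with \code{signature}, \code{expr} (genes x samples),
#'   \code{groups} (factor control/case), \code{de} (DE table).
#' @export
simulateQuery <- function(cfg) {
  .validateSimConfig(cfg)
  pat <- .diseasePattern(cfg)
  G <- cfg$nGenes; n <- cfg$nPerGroup
  expr <- withSeed(.subSeed(cfg$seed, 4), {
    m <- matrix(stats::rnorm(G * 2 * n, sd = cfg$querySd), G, 2 * n)
    rownames(m) <- pat$genes
    colnames(m) <- c(sprintf("ctrl%02d", seq_len(n)),
                     sprintf("case%02d", seq_len(n)))
    idx <- match(names(pat$magnitude), pat$genes)
    m[idx, n + seq_len(n)] <- m[idx, n + seq_len(n)] + pat$magnitude
    m
  })
  groups <- factor(rep(c("control", "case"), each = n),
                   levels = c("control", "case"))
  de <- deSignature(expr, groups)$de
  list(signature = .patternSignature(pat), expr = expr, groups = groups,
       de = de)
}
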