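#' Benchmark labels: per-compound potency
#'
#' Builds the effective/ineffective split used by the AUC-based
#' benchmarking standard: a compound is effective when its IC50 is below
#' the threshold (default 10 uM).
#'
#' @param compoundId character vector of compound identifiers (unique).
#' @param ic50 numeric IC50s in uM (optional if \code{effective} given).
#' @param effective logical; when omitted, derived as
#'   \code{ic50 < threshold}. When both are given they must agree.
#' @param threshold IC50 cutoff in uM.
#' @return data.frame of class \code{"BenchmarkLabels"} with columns
#'   \code{compound_id}, \code{ic50}, \code{effective}.
#' @export
benchmarkLabels <- function(compoundId, ic50 = NULL, effective = NULL,
                            threshold = 10) {
  compoundId <- as.character(compoundId)
  if (anyDuplicated(compoundId))
    stopInput("duplicated compound_id in benchmark labels")
  if (is.null(effective)) {
    if (is.null(ic50)) stopInput("need ic50 or effective")
    effective <- ic50 < threshold
  } else if (!is.null(ic50) && !identical(as.logical(effective),
                                          ic50 < threshold)) {
    stopInvariant("effective flags contradict ic50 < %g uM", threshold)
  }
  out <- data.frame(compound_id = compoundId,
                    ic50 = if (is.null(ic50)) NA_real_ else ic50,
                    effective = as.logical(effective),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("BenchmarkLabels", "data.frame")
  out
}

#' Agent set: a curated collection of compounds
#'
#' @param name set name.
#' @param compounds character vector of compound identifiers (non-empty).
#' @return list of class \code{"AgentSet"} with \code{name}, \code{compounds}.
#' @export
agentSet <- function(name, compounds) {
  compounds <- unique(as.character(compounds))
  if (length(compounds) == 0L) stopInput("agent set must be non-empty")
  structure(list(name = name, compounds = compounds), class = "AgentSet")
}

# Collapse a score table to one score per compound (median over profiles).
# Marked-missing (NA) scores are excluded with a logged count.
.compoundScores <- function(scores, method, verbose = FALSE) {
  if (is.data.frame(scores)) {
    if (!method %in% colnames(scores))
      stopInput("method '%s' not present in score table", method)
    s <- scores[[method]]
    cmpd <- scores$compound_id
  } else {
    s <- as.numeric(scores)
    cmpd <- names(scores)
    if (is.null(cmpd)) stopInput("scores vector must be named by compound")
  }
  drop <- is.na(s)
  if (any(drop)) {
    if (verbose)
      message(sprintf("excluding %d marked-missing scores", sum(drop)))
    s <- s[!drop]; cmpd <- cmpd[!drop]
  }
  if (length(s) == 0L) stopInput("no non-missing scores")
  out <- tapply(s, cmpd, stats::median)
  stats::setNames(as.numeric(out), names(out))
}

#' Drug-retrieval AUC (DR-AUC)
#'
#' Rank-based AUC of the classifier "more-negative score implies
#' effective": the probability that a random effective compound scores
#' below a random ineffective one, ties contributing 1/2
#' (Mann-Whitney). Profiles are collapsed to one score per compound by the
#' median before ranking. Higher DR-AUC = better retrieval.
#'
#' @param scores a score table from [scoreProfiles()] (with
#'   \code{method} naming the column) or a named numeric vector keyed by
#'   compound.
#' @param labels a [benchmarkLabels()] object.
#' @param method score column when \code{scores} is a data.frame.
#' @return single numeric in [0, 1].
#' @export
drAuc <- function(scores, labels, method = "xsum") {
  s <- .compoundScores(scores, method)
  lab <- labels[match(names(s), labels$compound_id), ]
  keep <- !is.na(lab$effective)
  s <- s[keep]; eff <- lab$effective[keep]
  nE <- sum(eff); nI <- sum(!eff)
  if (nE == 0L || nI == 0L)
    stopInput("need at least one effective and one ineffective compound")
  .aucEffLow(s, eff)
}

# AUC that effective scores are lower, half-credit ties, via midranks.
.aucEffLow <- function(s, eff) {
  nE <- sum(eff); nI <- sum(!eff)
  rk <- rank(s, ties.method = "average")
  uGreater <- sum(rk[eff]) - nE * (nE + 1) / 2   # pairs eff > ineff (+ ties/2)
  1 - uGreater / (nE * nI)
}

#' DR-AUC with permutation significance
#'
#' Permutes the effective/ineffective labels \code{nPerm} times and
#' reports the one-sided p-value for the observed DR-AUC being high:
#' with add-one smoothing \code{p = (1 + #[perm >= obs]) / (nPerm + 1)}
#' (the raw fraction is reported alongside as \code{p_raw}).
#'
#' @inheritParams drAuc
#' @param nPerm number of label permutations (default 10000).
#' @param seed integer seed; the result is deterministic given it.
#' @return list of class \code{"DrAucResult"}: \code{dr_auc},
#'   \code{p_value}, \code{p_raw}, \code{n_permutations},
#'   \code{n_effective}, \code{n_ineffective}.
#' @export
drAucPermutation <- function(scores, labels, method = "xsum",
                             nPerm = 10000, seed = NULL) {
  s <- .compoundScores(scores, method)
  lab <- labels[match(names(s), labels$compound_id), ]
  keep <- !is.na(lab$effective)
  s <- s[keep]; eff <- lab$effective[keep]
  nE <- sum(eff); nI <- sum(!eff)
  if (nE == 0L || nI == 0L)
    stopInput("need at least one effective and one ineffective compound")
  obs <- .aucEffLow(s, eff)
  null <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    .aucEffLow(s, sample(eff))
  }, numeric(1)))
  structure(list(
    dr_auc = obs,
    p_value = (1 + sum(null >= obs)) / (nPerm + 1),
    p_raw = mean(null >= obs),
    n_permutations = nPerm,
    n_effective = nE,
    n_ineffective = nI
  ), class = "DrAucResult")
}

#' @export
print.DrAucResult <- function(x, ...) {
  cat(sprintf("DR-AUC = %.4f (p = %.4g, %d permutations, %d eff / %d ineff)\n",
              x$dr_auc, x$p_value, x$n_permutations,
              x$n_effective, x$n_ineffective))
  invisible(x)
}

#' Drug-retrieval enrichment score (DR-ES)
#'
#' Unweighted maximum-deviation (GSEA-style, exponent 0) enrichment of an
#' agent set in the compound ranking by similarity score descending, so
#' that an agent set concentrated at the strong-reversal (most negative
#' score) end yields a negative DR-ES. Lower = better retrieval. No
#' normalised score (NES) is computed. A score-weighted variant (GSEA
#' exponent 1) is available via \code{weighted = TRUE}.
#'
#' @inheritParams drAuc
#' @param agents an [agentSet()].
#' @param weighted use |score|-weighted hit increments instead of the
#'   classic unweighted KS statistic.
#' @return single numeric in [-1, 1].
#' @export
drEs <- function(scores, agents, method = "xsum", weighted = FALSE) {
  s <- .compoundScores(scores, method)
  hits <- intersect(agents$compounds, names(s))
  if (length(hits) == 0L)
    stopInput("no agent overlaps the scored compounds")
  # descending: strongest reversal (most negative) at the bottom
  ord <- order(-s, names(s), method = "radix")
  ranked <- names(s)[ord]
  pos <- match(hits, ranked)
  if (weighted) {
    .weightedEs(pos, abs(s[ord]), length(s))
  } else {
    mdEnrichmentScore(pos, length(s))
  }
}

# GSEA exponent-1 running-sum ES: hit steps proportional to |score|.
.weightedEs <- function(positions, absWeights, n) {
  hit <- logical(n); hit[positions] <- TRUE
  wHit <- absWeights * hit
  denom <- sum(wHit)
  if (denom == 0) return(NA_real_)
  pHit <- cumsum(wHit) / denom
  pMiss <- cumsum(!hit) / (n - length(positions))
  dev <- pHit - pMiss
  dev[which.max(abs(dev))]
}

#' DR-ES with permutation significance
#'
#' Null built by re-sampling agent-set membership: \code{nPerm} random
#' compound sets of the same size drawn without replacement, each scored by
#' [drEs()]. One-sided toward reversal (negative enrichment):
#' \code{p = (1 + #[null <= obs]) / (nPerm + 1)}. Permuting the score
#' vector instead is available via \code{null = "scores"}.
#'
#' @inheritParams drEs
#' @param nPerm number of permutations (default 10000).
#' @param seed integer seed.
#' @param null \code{"membership"} (default) or \code{"scores"}.
#' @return list of class \code{"DrEsResult"}: \code{dr_es}, \code{p_value},
#'   \code{p_raw}, \code{n_permutations}, \code{agent_set_size}.
#' @export
drEsPermutation <- function(scores, agents, method = "xsum", nPerm = 10000,
                            seed = NULL, null = c("membership", "scores"),
                            weighted = FALSE) {
  null <- match.arg(null)
  s <- .compoundScores(scores, method)
  hits <- intersect(agents$compounds, names(s))
  if (length(hits) == 0L)
    stopInput("no agent overlaps the scored compounds")
  obs <- drEs(s, agents, weighted = weighted)
  k <- length(hits)
  cmpds <- names(s)
  nullEs <- withSeed(seed, vapply(seq_len(nPerm), function(i) {
    if (null == "membership") {
      fake <- agentSet("perm", sample(cmpds, k))
      drEs(s, fake, weighted = weighted)
    } else {
      sp <- stats::setNames(sample(s), cmpds)
      drEs(sp, agentSet("perm", hits), weighted = weighted)
    }
  }, numeric(1)))
  structure(list(
    dr_es = obs,
    p_value = (1 + sum(nullEs <= obs)) / (nPerm + 1),
    p_raw = mean(nullEs <= obs),
    n_permutations = nPerm,
    agent_set_size = k
  ), class = "DrEsResult")
}

#' @export
print.DrEsResult <- function(x, ...) {
  cat(sprintf("DR-ES = %.4f (p = %.4g, %d permutations, %d agents)\n",
              x$dr_es, x$p_value, x$n_permutations, x$agent_set_size))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Sweeps

#' Sweep the topN trimming parameter
#'
#' Recomputes scores and both benchmarking standards for every topN in the
#' range for each eXtreme method. KS and RGES ignore trimming, so their
#' values are computed once and replicated across topN.
#'
#' @param refs a \linkS4class{ReferenceProfileSet}.
#' @param query a \linkS4class{QuerySignature}.
#' @param methods methods to sweep.
#' @param topnRange integer range \code{c(lo, hi)} (default c(50, 489)).
#' @param labels a [benchmarkLabels()] object.
#' @param agents an [agentSet()].
#' @param by step between evaluated topN values (default 1).
#' @param useMagnitude passed to the correlation methods.
#' @return data.frame of class \code{"SweepResult"} with columns
#'   \code{method}, \code{topN}, \code{dr_auc}, \code{dr_es}.
#' @export
topnSweep <- function(refs, query, methods = c("xsum"), topnRange = c(50, 489),
                      labels, agents, by = 1, useMagnitude = TRUE) {
  methods <- match.arg(methods, .all_methods, several.ok = TRUE)
  if (topnRange[1] < 1 || topnRange[2] > nrow(refs))
    stopInput("topnRange must lie within [1, gene count]")
  topNs <- seq(topnRange[1], topnRange[2], by = by)
  query <- alignQuery(query, refs)
  values <- zscores(refs)
  cd <- profileMeta(refs)
  rankmat <- .rankMatrices(values)
  extreme <- intersect(methods, c("xsum", "xcos", "xcor", "xspe"))
  fullMethods <- intersect(methods, c("ks", "rges"))
  rows <- list()
  evalScores <- function(s, method, topN) {
    sv <- stats::setNames(s, cd$compound_id)
    sv <- .compoundScores(sv, method = NULL)
    data.frame(method = method, topN = topN,
               dr_auc = drAuc(sv, labels),
               dr_es = drEs(sv, agents),
               stringsAsFactors = FALSE)
  }
  for (tN in topNs) {
    if (length(extreme)) {
      ext <- .scoreExtremeBatch(values, rankmat, query, extreme, tN,
                                useMagnitude)
      for (m in extreme)
        rows[[length(rows) + 1L]] <- evalScores(ext[, m], m, tN)
    }
  }
  if (length(fullMethods)) {
    base <- scoreProfiles(refs, query, methods = fullMethods, topN = 200)
    for (m in fullMethods) {
      one <- evalScores(base[[m]], m, topNs[1])
      for (tN in topNs) {
        rec <- one; rec$topN <- tN
        rows[[length(rows) + 1L]] <- rec
      }
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$method, .all_methods), out$topN), ]
  rownames(out) <- NULL
  class(out) <- c("SweepResult", "data.frame")
  out
}

#' Bin-normalise a topN sweep
#'
#' Divides the topN axis into half-open bins of \code{binWidth} values
#' (the last bin absorbs any remainder up to the range maximum and is
#' flagged partial) and reports the mean DR-AUC / DR-ES per (method, bin),
#' damping single-topN outliers when choosing an operating window.
#'
#' @param sweep a \code{SweepResult} from [topnSweep()].
#' @param binWidth bin width in topN units (default 50).
#' @return data.frame with \code{method}, \code{bin} (label),
#'   \code{bin_start}, \code{bin_end}, \code{n}, \code{mean_dr_auc},
#'   \code{mean_dr_es}, \code{partial}.
#' @export
binSummarize <- function(sweep, binWidth = 50) {
  if (nrow(sweep) == 0L) stopInput("empty sweep")
  lo <- min(sweep$topN); hi <- max(sweep$topN)
  idx <- pmin((sweep$topN - lo) %/% binWidth,
              max((hi - lo) %/% binWidth, 0))
  key <- interaction(sweep$method, idx, drop = TRUE)
  recs <- lapply(split(sweep, key), function(d) {
    b <- (d$topN[1] - lo) %/% binWidth
    start <- lo + b * binWidth
    end <- min(start + binWidth - 1, hi)
    data.frame(method = d$method[1],
               bin = sprintf("[%d,%d]", start, end),
               bin_start = start, bin_end = end, n = nrow(d),
               mean_dr_auc = mean(d$dr_auc),
               mean_dr_es = mean(d$dr_es),
               partial = (end - start + 1) < binWidth,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out <- out[order(match(out$method, .all_methods), out$bin_start), ]
  rownames(out) <- NULL
  out
}

#' Random-subsampling signature-size sweep
#'
#' Draws, for each requested size, \code{reps} random sub-signatures from
#' the full query (simple random sampling without replacement, each gene
#' keeping its direction and magnitude) and evaluates both benchmarking
#' standards for each.
#'
#' @param fullQuery the complete \linkS4class{QuerySignature}.
#' @param sizes integer vector of signature sizes (e.g. 5 to full - 1).
#' @param reps sub-signatures per size (default 1000).
#' @param refs,labels,agents evaluation context.
#' @param method matching method used for scoring (default "xsum").
#' @param topN trimming parameter (default 200).
#' @param seed integer seed; draws are deterministic given it.
#' @return data.frame with \code{size}, \code{rep}, \code{dr_auc},
#'   \code{dr_es}.
#' @export
sizeSweepRandom <- function(fullQuery, sizes, reps = 1000, refs, labels,
                            agents, method = "xsum", topN = 200,
                            seed = NULL) {
  full <- alignQuery(fullQuery, refs)
  genes <- sigGenes(full)
  if (any(sizes > length(genes)))
    stopInput("requested size exceeds the full signature size")
  if (any(sizes < 1)) stopInput("sizes must be >= 1")
  pre <- .precomputeScoring(refs, topN)
  sigs <- withSeed(seed, {
    lapply(sizes, function(sz) lapply(seq_len(reps), function(r) {
      .subSignature(full, sz, sprintf("%s_s%d_r%d", full@name, sz, r))
    }))
  })
  rows <- list()
  for (i in seq_along(sizes)) {
    for (r in seq_len(reps)) {
      sv <- .scorePrecomputed(pre, sigs[[i]][[r]], method)
      rows[[length(rows) + 1L]] <- data.frame(
        size = sizes[i], rep = r,
        dr_auc = drAuc(sv, labels),
        dr_es = drEs(sv, agents))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# SRSWOR sub-signature preserving direction and magnitudes. A draw that
# would empty one direction is accepted: sub-signatures are scored as-is
# except for KS/RGES which require both sets (caller's concern).
.subSignature <- function(full, size, name) {
  genes <- sigGenes(full)
  if (size >= length(genes)) pick <- genes
  else pick <- sample(genes, size)
  up <- intersect(full@up, pick)
  down <- intersect(full@down, pick)
  mag <- full@magnitude
  if (length(mag)) mag <- mag[names(mag) %in% pick]
  querySignature(up, down, mag, name)
}

# Precompute per-profile structures shared by repeated scoring of many
# query signatures against a fixed reference and topN.
.precomputeScoring <- function(refs, topN) {
  values <- zscores(refs)
  rankmat <- .rankMatrices(values)
  n <- nrow(values)
  if (2 * topN >= n) trimmed <- values
  else trimmed <- values * (rankmat$desc <= topN | rankmat$asc <= topN)
  list(values = values, rankmat = rankmat, trimmed = trimmed,
       compound_id = profileMeta(refs)$compound_id, n = n)
}

# Score one signature using precomputed structures; returns a named
# compound-level (median-collapsed) score vector.
.scorePrecomputed <- function(pre, sig, method) {
  if (method == "xsum") {
    s <- colSums(pre$trimmed[sig@up, , drop = FALSE]) -
      colSums(pre$trimmed[sig@down, , drop = FALSE])
  } else if (method %in% c("xcos", "xcor", "xspe")) {
    q <- queryVector(sig)
    m <- pre$trimmed[names(q), , drop = FALSE]
    s <- switch(method,
      xcos = {
        np <- sqrt(colSums(m^2))
        raw <- as.numeric(crossprod(q, m)) / (sqrt(sum(q^2)) * np)
        raw[np == 0] <- NA_real_
        raw
      },
      xcor = .safeCor(q, m, "pearson"),
      xspe = .safeCor(q, m, "spearman"))
  } else if (method %in% c("ks", "rges")) {
    if (length(sig@up) == 0L || length(sig@down) == 0L)
      stopInput("KS/RGES scoring requires non-empty up and down sets")
    esu <- apply(pre$rankmat$desc[sig@up, , drop = FALSE], 2,
                 mdEnrichmentScore, n = pre$n)
    esd <- apply(pre$rankmat$desc[sig@down, , drop = FALSE], 2,
                 mdEnrichmentScore, n = pre$n)
    s <- if (method == "ks") ifelse(sign(esu) == sign(esd), 0, esu - esd)
    else esu - esd
  } else stopInput("unknown method '%s'", method)
  .compoundScores(stats::setNames(s, pre$compound_id), method = NULL)
}

#' Fold-change-threshold signature-size sweep
#'
#' Iterates the |log2FC| threshold from \code{start} in steps of
#' \code{step} up to the maximum |log2FC| in the table; each threshold
#' yields the signature of genes beyond it (optionally also passing a
#' p-value cut). Duplicate gene sets are removed and signatures returned by
#' decreasing size.
#'
#' @param de a DE table (data.frame with \code{gene}, \code{log2fc},
#'   \code{p_value}, \code{adjusted_p}), e.g. from [deSignature()].
#' @param start first threshold (default 0.1).
#' @param step increment (default 0.05).
#' @param pCut optional p-value cut applied alongside the fold-change cut.
#' @param useAdjusted apply \code{pCut} to \code{adjusted_p} (default) or
#'   raw \code{p_value}.
#' @return list of \linkS4class{QuerySignature}, each with a
#'   \code{"threshold"} attribute; empty list when \code{start} exceeds the
#'   maximum |log2FC|.
#' @export
sizeSweepFc <- function(de, start = 0.1, step = 0.05, pCut = NULL,
                        useAdjusted = TRUE) {
  stopifnot(all(c("gene", "log2fc") %in% colnames(de)))
  keep <- rep(TRUE, nrow(de))
  if (!is.null(pCut)) {
    pcol <- if (useAdjusted) de$adjusted_p else de$p_value
    keep <- pcol < pCut
  }
  maxAbs <- max(abs(de$log2fc[keep]), 0)
  if (start > maxAbs) return(list())
  taus <- seq(start, maxAbs, by = step)
  sigs <- list()
  seen <- character(0)
  for (tau in taus) {
    up <- de$gene[keep & de$log2fc >= tau]
    down <- de$gene[keep & de$log2fc <= -tau]
    if (length(up) + length(down) == 0L) next
    fp <- paste(c(sort(up), "|", sort(down)), collapse = ";")
    if (fp %in% seen) next
    seen <- c(seen, fp)
    mag <- stats::setNames(de$log2fc, de$gene)[c(up, down)]
    sig <- querySignature(up, down, mag,
                          name = sprintf("fc_%.2f", tau))
    attr(sig, "threshold") <- tau
    sigs[[length(sigs) + 1L]] <- sig
  }
  sigs[order(-vapply(sigs, sigSize, numeric(1)))]
}
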