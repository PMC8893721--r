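#' Extreme trimming of a compound profile
#'
#' Keeps only the topN most-upregulated and topN most-downregulated genes of
#' a profile and sets every other value to zero, reflecting the view that
#' small expression changes are noise. Ties are resolved deterministically:
#' within a tied value, the gene with the lexicographically smaller
#' identifier is kept. When \code{2 * topN >= length(profile)} the profile
#' is returned unchanged.
#'
#' @param profile named numeric vector (gene -> z-score).
#' @param topN positive integer, number of genes kept per tail.
#' @return named numeric vector of the same length and order with at most
#'   \code{2 * topN} non-zero entries.
#' @examples
#' extremeTrim(c(a = 3, b = 2, c = 1, d = -1, e = -2, f = -3), topN = 1)
#' @export
extremeTrim <- function(profile, topN) {
  if (length(topN) != 1L || is.na(topN) || topN < 1)
    stopInput("topN must be a single integer >= 1")
  genes <- names(profile)
  if (is.null(genes)) stopInput("profile must be a named vector")
  n <- length(profile)
  if (2 * topN >= n) return(profile)
  keep_pos <- orderDesc(profile, genes)[seq_len(topN)]
  keep_neg <- orderAsc(profile, genes)[seq_len(topN)]
  out <- numeric(n)
  names(out) <- genes
  keep <- union(keep_pos, keep_neg)
  out[keep] <- profile[keep]
  out
}

#' Maximum-deviation (Kolmogorov-Smirnov) enrichment score
#'
#' The unweighted running-sum enrichment statistic of the original
#' connectivity-map study: with a gene set of size \code{t} at 1-based
#' positions \code{V(1) < ... < V(t)} of a ranked list of length \code{n},
#' \deqn{a = \max_j (j/t - V(j)/n), \quad b = \max_j (V(j)/n - (j-1)/t)}
#' and ES = \code{a} if \code{a > b}, else \code{-b}. Positive scores mean
#' the set concentrates at the top of the list. \code{|ES| <= 1}.
#'
#' @param positions integer vector of 1-based positions of the gene set in
#'   the ranked list (need not be sorted).
#' @param n ranked-list length.
#' @return single numeric in [-1, 1].
#' @examples
#' mdEnrichmentScore(c(1, 2), 10)   #  0.8
#' mdEnrichmentScore(c(9, 10), 10)  # -0.9
#' @export
mdEnrichmentScore <- function(positions, n) {
  if (length(positions) == 0L) stopInput("empty gene set")
  positions <- as.numeric(positions)
  if (any(positions < 1 | positions > n) || anyDuplicated(positions))
    stopInput("positions must be distinct and within [1, n]")
  v <- sort(positions)
  t <- length(v)
  j <- seq_len(t)
  a <- max(j / t - v / n)
  b <- max(v / n - (j - 1) / t)
  if (a > b) a else -b
}

#' eXtreme Sum score
#'
#' XSum = sum of trimmed profile values over the query's up genes minus the
#' sum over its down genes. More negative scores indicate stronger reversal
#' of the query signature.
#'
#' @param profile named numeric vector, typically the output of
#'   [extremeTrim()].
#' @param query an aligned \linkS4class{QuerySignature}.
#' @return single numeric score.
#' @export
scoreXsum <- function(profile, query) {
  .checkAligned(query, names(profile))
  sum(profile[query@up]) - sum(profile[query@down])
}

.checkAligned <- function(query, genes) {
  miss <- setdiff(sigGenes(query), genes)
  if (length(miss))
    stopInput("query not aligned to profile gene space (%d missing genes); run alignQuery()",
              length(miss))
}

#' eXtreme correlation scores (XCos, XCor, XSpe)
#'
#' Correlation between the query vector (log2FC magnitudes when present,
#' else +/-1) and the trimmed profile restricted to the query's genes,
#' zeros from trimming included. The correlation is already in "lower =
#' stronger reversal" orientation: a compound that reverses the disease
#' pattern anti-correlates with the query (-1 = perfect reversal, +1 =
#' perfect mimicry), consistent with the XSum sign convention. Returns
#' \code{NA} (marked missing) when either vector has zero norm (cosine) or
#' zero variance (Pearson/Spearman).
#'
#' @param profile named numeric vector, typically trimmed.
#' @param query an aligned \linkS4class{QuerySignature}.
#' @param method one of \code{"xcos"}, \code{"xcor"}, \code{"xspe"}.
#' @param useMagnitude use the query's stored magnitudes when available.
#' @return single numeric score in [-1, 1], or NA when undefined.
#' @export
scoreExtremeCorrelation <- function(profile, query,
                                    method = c("xcos", "xcor", "xspe"),
                                    useMagnitude = TRUE) {
  method <- match.arg(method)
  .checkAligned(query, names(profile))
  q <- queryVector(query, useMagnitude)
  p <- profile[names(q)]
  .rawCorrelation(q, p, method)
}

.rawCorrelation <- function(q, p, method) {
  if (method == "xcos") {
    nq <- sqrt(sum(q^2)); np <- sqrt(sum(p^2))
    if (nq == 0 || np == 0) return(NA_real_)
    sum(q * p) / (nq * np)
  } else {
    if (stats::sd(q) == 0 || stats::sd(p) == 0) return(NA_real_)
    meth <- if (method == "xcor") "pearson" else "spearman"
    stats::cor(q, p, method = meth)
  }
}

# Positions (1-based) of `genes` in the descending ranking of a full
# profile, ties broken by gene identifier ascending.
.rankedPositions <- function(profile, genes) {
  ord <- orderDesc(profile, names(profile))
  pos <- integer(length(profile))
  pos[ord] <- seq_along(ord)
  names(pos) <- names(profile)
  pos[genes]
}

.esUpDown <- function(profile, query) {
  .checkAligned(query, names(profile))
  n <- length(profile)
  if (length(query@up) == 0L || length(query@down) == 0L)
    stopInput("KS/RGES scoring requires non-empty up and down sets")
  list(
    es_up = mdEnrichmentScore(.rankedPositions(profile, query@up), n),
    es_down = mdEnrichmentScore(.rankedPositions(profile, query@down), n)
  )
}

#' Kolmogorov-Smirnov connectivity score
#'
#' The full profile is ranked by z-score descending (ties by gene
#' identifier); maximum-deviation enrichment scores of the up set
#' (\code{es_up}) and down set (\code{es_down}) are combined as: 0 when
#' both have the same algebraic sign, else \code{es_up - es_down}.
#' Negative = reversal.
#'
#' @param profile named numeric vector over the full gene space (untrimmed).
#' @param query an aligned \linkS4class{QuerySignature} with non-empty up
#'   and down sets.
#' @return single numeric score in [-2, 2].
#' @export
scoreKs <- function(profile, query) {
  es <- .esUpDown(profile, query)
  if (sign(es$es_up) == sign(es$es_down)) 0 else es$es_up - es$es_down
}

#' Reverse Gene Expression Score (RGES)
#'
#' As [scoreKs()] but always \code{es_up - es_down}, regardless of the signs
#' of the two enrichment scores.
#'
#' @inheritParams scoreKs
#' @return single numeric score in [-2, 2].
#' @export
scoreRges <- function(profile, query) {
  es <- .esUpDown(profile, query)
  es$es_up - es$es_down
}

# ---------------------------------------------------------------------------
# Batch scoring

.all_methods <- c("xsum", "xcos", "xcor", "xspe", "ks", "rges")

# Per-column descending/ascending rank matrices with the documented tie rule.
.rankMatrices <- function(values) {
  g <- rownames(values)
  n <- nrow(values)
  rdesc <- matrix(0L, n, ncol(values), dimnames = dimnames(values))
  rasc <- rdesc
  for (j in seq_len(ncol(values))) {
    od <- orderDesc(values[, j], g)
    rdesc[od, j] <- seq_len(n)
    oa <- orderAsc(values[, j], g)
    rasc[oa, j] <- seq_len(n)
  }
  list(desc = rdesc, asc = rasc)
}

#' Score every reference profile against a query signature
#'
#' Batch driver for the six matching methods. The eXtreme methods (xsum,
#' xcos, xcor, xspe) score extreme-trimmed profiles at the given
#' \code{topN}; KS and RGES use the complete profiles and ignore
#' \code{topN}. All methods are reported in "lower = stronger reversal"
#' orientation. Undefined scores are reported as \code{NA}, never silently
#' zero.
#'
#' @param refs a \linkS4class{ReferenceProfileSet}.
#' @param query a \linkS4class{QuerySignature}; aligned internally via
#'   [alignQuery()].
#' @param methods subset of \code{c("xsum","xcos","xcor","xspe","ks","rges")}.
#' @param topN genes kept per tail by extreme trimming (default 200).
#' @param useMagnitude use query magnitudes in correlation methods.
#' @return a \code{data.frame} with columns \code{profile_id},
#'   \code{compound_id}, one column per method, and attribute
#'   \code{"topN"}.
#' @examples
#' cfg <- simConfig(nGenes = 60, nCompounds = 20, nCellLines = 1,
#'                  nUp = 10, nDown = 5, seed = 1)
#' sim <- simulateReference(cfg)
#' scores <- scoreProfiles(sim$refs, sim$query, methods = "xsum", topN = 10)
#' head(scores)
#' @export
scoreProfiles <- function(refs, query, methods = .all_methods, topN = 200,
                          useMagnitude = TRUE) {
  methods <- match.arg(methods, .all_methods, several.ok = TRUE)
  query <- alignQuery(query, refs)
  values <- zscores(refs)
  cd <- profileMeta(refs)
  out <- data.frame(profile_id = cd$profile_id,
                    compound_id = cd$compound_id,
                    stringsAsFactors = FALSE)
  extreme <- intersect(methods, c("xsum", "xcos", "xcor", "xspe"))
  rankmat <- if (length(extreme) || any(c("ks", "rges") %in% methods))
    .rankMatrices(values) else NULL
  if (length(extreme)) {
    ext <- .scoreExtremeBatch(values, rankmat, query, extreme, topN,
                              useMagnitude)
    for (nm in colnames(ext)) out[[nm]] <- ext[, nm]
  }
  if (any(c("ks", "rges") %in% methods)) {
    if (length(query@up) == 0L || length(query@down) == 0L)
      stopInput("KS/RGES scoring requires non-empty up and down sets")
    esu <- apply(rankmat$desc[query@up, , drop = FALSE], 2,
                 mdEnrichmentScore, n = nrow(values))
    esd <- apply(rankmat$desc[query@down, , drop = FALSE], 2,
                 mdEnrichmentScore, n = nrow(values))
    if ("ks" %in% methods)
      out$ks <- ifelse(sign(esu) == sign(esd), 0, esu - esd)
    if ("rges" %in% methods)
      out$rges <- esu - esd
  }
  out <- out[, c("profile_id", "compound_id",
                 intersect(.all_methods, colnames(out)))]
  attr(out, "topN") <- topN
  out
}

# Vectorised eXtreme scoring over all profiles for one topN. `rankmat`
# holds per-column desc/asc ranks; the trimmed value of a gene is its value
# when its desc rank <= topN or asc rank <= topN, else 0.
.scoreExtremeBatch <- function(values, rankmat, query, methods, topN,
                               useMagnitude) {
  if (topN < 1) stopInput("topN must be >= 1")
  q <- queryVector(query, useMagnitude)
  genes <- names(q)
  n <- nrow(values)
  sub <- values[genes, , drop = FALSE]
  if (2 * topN >= n) {
    mask <- matrix(TRUE, length(genes), ncol(values))
  } else {
    mask <- rankmat$desc[genes, , drop = FALSE] <= topN |
      rankmat$asc[genes, , drop = FALSE] <= topN
  }
  trimmed <- sub * mask
  out <- list()
  if ("xsum" %in% methods) {
    upi <- genes %in% query@up
    out$xsum <- colSums(trimmed[upi, , drop = FALSE]) -
      colSums(trimmed[!upi, , drop = FALSE])
  }
  if ("xcos" %in% methods) {
    np <- sqrt(colSums(trimmed^2))
    raw <- as.numeric(crossprod(q, trimmed)) / (sqrt(sum(q^2)) * np)
    raw[np == 0] <- NA_real_
    out$xcos <- raw
  }
  if ("xcor" %in% methods)
    out$xcor <- .safeCor(q, trimmed, "pearson")
  if ("xspe" %in% methods)
    out$xspe <- .safeCor(q, trimmed, "spearman")
  do.call(cbind, out)
}

.safeCor <- function(q, m, method) {
  if (stats::sd(q) == 0) return(rep(NA_real_, ncol(m)))
  sds <- apply(m, 2, stats::sd)
  raw <- rep(NA_real_, ncol(m))
  ok <- sds > 0
  if (any(ok))
    raw[ok] <- suppressWarnings(
      as.numeric(stats::cor(q, m[, ok, drop = FALSE], method = method)))
  raw
}
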