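#' Differential-expression query signature
#'
#' Simplified two-group differential statistic for building query
#' signatures from a log2-scale expression matrix: per-gene log2 fold
#' change as the difference of group means, a Wilcoxon rank-sum p-value,
#' and Benjamini-Hochberg adjustment. The signature comprises the genes
#' passing both the (adjusted) p-value and |log2FC| cuts, split by fold
#' change sign. Default cuts follow the strict convention adjusted p < 0.01
#' and |log2FC| > 1; the relaxed convention (raw p < 0.01, |log2FC| > 0.5)
#' is obtained with \code{pCut = 0.01, fcCut = 0.5, useAdjusted = FALSE}.
#'
#' @param expr numeric matrix, genes x samples, log2 scale, with rownames.
#' @param groups two-level factor/character vector over samples; the log2FC
#'   is mean(second level) - mean(first level), i.e. the second level is
#'   the case group.
#' @param pCut p-value threshold (default 0.01).
#' @param fcCut |log2FC| threshold (default 1).
#' @param useAdjusted apply \code{pCut} to BH-adjusted p-values (default)
#'   or raw p-values.
#' @param name signature name.
#' @return list with \code{signature} (a \linkS4class{QuerySignature}; NULL
#'   when no gene passes) and \code{de} (the full DE table: \code{gene},
#'   \code{log2fc}, \code{p_value}, \code{adjusted_p}).
#' @export
deSignature <- function(expr, groups, pCut = 0.01, fcCut = 1,
                        useAdjusted = TRUE, name = "de_signature") {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stopInput("groups must have exactly 2 levels")
  if (any(table(groups) < 3L))
    stopInput("need >= 3 samples per group")
  if (is.null(rownames(expr))) stopInput("expr must have gene rownames")
  g1 <- expr[, groups == levels(groups)[1], drop = FALSE]
  g2 <- expr[, groups == levels(groups)[2], drop = FALSE]
  lfc <- rowMeans(g2) - rowMeans(g1)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    suppressWarnings(
      stats::wilcox.test(g2[i, ], g1[i, ], exact = FALSE)$p.value)
  }, numeric(1))
  de <- data.frame(gene = rownames(expr), log2fc = lfc, p_value = p,
                   adjusted_p = stats::p.adjust(p, method = "BH"),
                   stringsAsFactors = FALSE)
  rownames(de) <- NULL
  pcol <- if (useAdjusted) de$adjusted_p else de$p_value
  pass <- pcol < pCut & abs(de$log2fc) > fcCut
  sig <- NULL
  if (any(pass)) {
    up <- de$gene[pass & de$log2fc > 0]
    down <- de$gene[pass & de$log2fc < 0]
    mag <- stats::setNames(de$log2fc, de$gene)[c(up, down)]
    sig <- querySignature(up, down, mag, name)
  }
  list(signature = sig, de = de)
}

#' Random landmark query signatures
#'
#' Draws \code{reps} signatures of \code{size} distinct genes each from the
#' gene space by simple random sampling without replacement. Directions are
#' assigned by the configured rule: by default an independent fair coin per
#' gene, redrawing the coin vector until both directions are represented;
#' alternatively a fixed up-fraction (the \code{ceiling(size * upFraction)}
#' first-drawn genes are up).
#'
#' @param geneSpace character vector of gene identifiers (or a
#'   \linkS4class{ReferenceProfileSet}).
#' @param size genes per signature (default 100).
#' @param reps number of signatures (default 10000).
#' @param upFraction NULL for the fair-coin rule (default), or a fraction
#'   in (0, 1) fixing the up-set size.
#' @param seed integer seed; the collection is deterministic given it.
#' @return list of \linkS4class{QuerySignature}.
#' @export
randomLandmarkSignatures <- function(geneSpace, size = 100, reps = 10000,
                                     upFraction = NULL, seed = NULL) {
  if (is(geneSpace, "ReferenceProfileSet")) geneSpace <- rownames(geneSpace)
  if (size > length(geneSpace))
    stopInput("size exceeds the gene space")
  if (size < 2L)
    stopInput("size must be >= 2 so both directions can be represented")
  withSeed(seed, lapply(seq_len(reps), function(r) {
    genes <- sample(geneSpace, size)
    if (is.null(upFraction)) {
      repeat {
        isUp <- sample(c(TRUE, FALSE), size, replace = TRUE)
        if (any(isUp) && !all(isUp)) break
      }
    } else {
      nUp <- max(1L, min(size - 1L, ceiling(size * upFraction)))
      isUp <- c(rep(TRUE, nUp), rep(FALSE, size - nUp))
    }
    querySignature(genes[isUp], genes[!isUp],
                   name = sprintf("random_%d", r))
  }))
}

#' Select the optimal signature by the DR-AUC x DR-ES criterion
#'
#' Evaluates every candidate signature against the reference set with one
#' matching method and both benchmarking standards, and returns the
#' candidate minimising \code{dr_auc * dr_es} (a high AUC combined with a
#' strongly negative ES gives the most negative product). Ties are broken
#' by the earliest candidate index; candidates whose evaluation fails are
#' skipped with a warning. When no candidate achieves a negative product
#' the least-bad minimum is still returned, flagged in the result.
#'
#' @param candidates list of \linkS4class{QuerySignature} (e.g. from
#'   [randomLandmarkSignatures()]).
#' @param refs a \linkS4class{ReferenceProfileSet}.
#' @param labels a [benchmarkLabels()] object.
#' @param agents an [agentSet()].
#' @param method matching method (default "xsum").
#' @param topN trimming parameter (default 200).
#' @return list of class \code{"SignatureSelection"}: \code{signature} (the
#'   winner), \code{index}, \code{objective} (full table with
#'   \code{candidate}, \code{dr_auc}, \code{dr_es}, \code{objective}),
#'   \code{all_nonnegative} flag.
#' @export
selectOptimalSignature <- function(candidates, refs, labels, agents,
                                   method = "xsum", topN = 200) {
  if (!length(candidates)) stopInput("no candidates supplied")
  pre <- .precomputeScoring(refs, topN)
  recs <- lapply(seq_along(candidates), function(i) {
    tryCatch({
      sv <- .scorePrecomputed(pre, candidates[[i]], method)
      a <- drAuc(sv, labels)
      e <- drEs(sv, agents)
      data.frame(candidate = i, dr_auc = a, dr_es = e, objective = a * e)
    }, error = function(cond) {
      warning(sprintf("candidate %d not evaluable: %s", i,
                      conditionMessage(cond)))
      NULL
    })
  })
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) stopInput("no candidate is evaluable")
  tab <- do.call(rbind, recs)
  best <- tab$candidate[which.min(tab$objective)]
  structure(list(
    signature = candidates[[best]],
    index = best,
    objective = tab,
    all_nonnegative = all(tab$dr_es >= 0)
  ), class = "SignatureSelection")
}

#' @export
print.SignatureSelection <- function(x, ...) {
  row <- x$objective[x$objective$candidate == x$index, ]
  cat(sprintf(
    "SignatureSelection: candidate %d of %d (DR-AUC %.3f x DR-ES %.3f = %.4f)%s\n",
    x$index, nrow(x$objective), row$dr_auc, row$dr_es, row$objective,
    if (x$all_nonnegative) " [no candidate reached negative DR-ES]" else ""))
  invisible(x)
}
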