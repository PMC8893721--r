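#' Cosine similarity and distance
#'
#' \code{dot(u, v) / (||u|| ||v||)}; returns \code{NA} (marked missing)
#' when either vector has zero norm. \code{cosineDistance} is
#' \code{1 - cosineSimilarity}.
#'
#' @param u,v numeric vectors of equal length >= 2.
#' @return single numeric in [-1, 1] (or NA).
#' @examples
#' cosineSimilarity(c(1, 0), c(1, 1))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v) || length(u) < 2L)
    stopInput("vectors must have equal length >= 2")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' @rdname cosineSimilarity
#' @export
cosineDistance <- function(u, v) 1 - cosineSimilarity(u, v)

#' Multi-level similarity of perturbation responses (L1-L5)
#'
#' Quantifies how consistently compounds perturb expression across cell
#' lines, from pairwise to cell-line level:
#' \describe{
#'   \item{L1}{per (compound, cell-line pair): cosine similarity of the two
#'     profiles; replicate pair combinations within a cell line are
#'     averaged before the value is recorded.}
#'   \item{L2}{per compound: median of its L1 values across cell-line
#'     pairs.}
#'   \item{L3}{per MOA: median of member compounds' L2 values; MOAs with
#'     fewer than \code{minMoaSize} compounds are flagged and excluded from
#'     ranked reports but kept in the table.}
#'   \item{L4}{per cell-line pair: median over shared compounds of their L1
#'     value for that pair (default); \code{l4AllPairs = TRUE} instead takes
#'     the median cosine over all cross-cell profile pairs.}
#'   \item{L5}{per cell line: median of all L1 values from pairs involving
#'     it (default), or of its L4 values (\code{l5From = "l4"}).}
#' }
#' All values lie in [-1, 1]; medians are over non-missing entries only.
#' Profiles are restricted to one (dose, time) stratum, 10 uM / 6 h by
#' default; set \code{dose}/\code{time} to NULL (with
#' \code{allowCrossStratum = TRUE}) to compare across strata.
#'
#' @param refs a \linkS4class{ReferenceProfileSet}.
#' @param dose,time perturbation stratum (uM, hours).
#' @param minMoaSize minimum compounds per MOA for ranked L3 output.
#' @param l4AllPairs use all cross-compound profile pairs for L4.
#' @param l5From \code{"l1"} (default) or \code{"l4"}.
#' @param allowCrossStratum must be TRUE to skip the stratum filter.
#' @return list of class \code{"SimilarityLevels"} with data.frames
#'   \code{l1}, \code{l2}, \code{l3}, \code{l4}, \code{l5}.
#' @export
similarityLevels <- function(refs, dose = 10, time = 6, minMoaSize = 5,
                             l4AllPairs = FALSE, l5From = c("l1", "l4"),
                             allowCrossStratum = FALSE) {
  l5From <- match.arg(l5From)
  if ((is.null(dose) || is.null(time)) && !allowCrossStratum)
    stopInput("cross-stratum comparison requires allowCrossStratum = TRUE")
  refs <- filterProfiles(refs, isGold = NULL, dose = dose, time = time,
                         verbose = FALSE)
  values <- zscores(refs)
  cd <- profileMeta(refs)
  norms <- sqrt(colSums(values^2))
  unit <- sweep(values, 2, ifelse(norms == 0, NA, norms), "/")

  l1 <- .l1Pairwise(unit, cd)
  l2 <- .aggregateMedian(l1, "compound_id", "l1", "l2")
  l3 <- .l3Moa(l2, cd, minMoaSize)
  l4 <- if (l4AllPairs) .l4AllPairs(unit, cd) else
    .aggregateMedianPair(l1, "l4")
  l5 <- if (l5From == "l4") .l5FromPairs(l4, "l4") else .l5FromL1(l1)
  structure(list(l1 = l1, l2 = l2, l3 = l3, l4 = l4, l5 = l5),
            class = "SimilarityLevels")
}

# L1: same compound, two cell lines; replicate combinations averaged.
.l1Pairwise <- function(unit, cd) {
  rows <- list()
  for (cmpd in unique(cd$compound_id)) {
    idx <- which(cd$compound_id == cmpd)
    cells <- sort(unique(cd$cell_line[idx]))
    if (length(cells) < 2L) next
    byCell <- split(idx, cd$cell_line[idx])
    for (i in seq_len(length(cells) - 1L)) for (j in seq(i + 1L, length(cells))) {
      ia <- byCell[[cells[i]]]; ib <- byCell[[cells[j]]]
      cc <- crossprod(unit[, ia, drop = FALSE], unit[, ib, drop = FALSE])
      v <- mean(cc, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        compound_id = cmpd, cell_a = cells[i], cell_b = cells[j],
        l1 = if (is.nan(v)) NA_real_ else v, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(compound_id = character(0), cell_a = character(0),
                      cell_b = character(0), l1 = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.aggregateMedian <- function(df, keyCol, valCol, outCol) {
  vals <- split(df[[valCol]], df[[keyCol]])
  out <- data.frame(
    key = names(vals),
    val = vapply(vals, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    n = vapply(vals, function(v) sum(!is.na(v)), numeric(1)),
    stringsAsFactors = FALSE)
  names(out) <- c(keyCol, outCol, "n_pairs")
  rownames(out) <- NULL
  out
}

.l3Moa <- function(l2, cd, minMoaSize) {
  if (!"moa" %in% colnames(cd)) cd$moa <- NA_character_
  moaMap <- unique(cd[, c("compound_id", "moa")])
  m <- merge(l2, moaMap, by = "compound_id")
  m <- m[!is.na(m$moa), ]
  if (nrow(m) == 0L)
    return(data.frame(moa = character(0), l3 = numeric(0),
                      n_compounds = integer(0), ranked = logical(0)))
  grp <- split(m$l2, m$moa)
  out <- data.frame(
    moa = names(grp),
    l3 = vapply(grp, function(v) stats::median(v, na.rm = TRUE), numeric(1)),
    n_compounds = vapply(grp, length, integer(1)),
    stringsAsFactors = FALSE)
  out$ranked <- out$n_compounds >= minMoaSize
  out <- out[order(-out$l3), ]
  rownames(out) <- NULL
  out
}

.aggregateMedianPair <- function(l1, outCol) {
  key <- paste(l1$cell_a, l1$cell_b, sep = "\r")
  vals <- split(l1$l1, key)
  parts <- strsplit(names(vals), "\r", fixed = TRUE)
  out <- data.frame(
    cell_a = vapply(parts, `[`, character(1), 1),
    cell_b = vapply(parts, `[`, character(1), 2),
    val = vapply(vals, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    n_compounds = vapply(vals, function(v) sum(!is.na(v)), numeric(1)),
    stringsAsFactors = FALSE)
  names(out)[3] <- outCol
  rownames(out) <- NULL
  out
}

.l4AllPairs <- function(unit, cd) {
  cells <- sort(unique(cd$cell_line))
  rows <- list()
  for (i in seq_len(length(cells) - 1L)) for (j in seq(i + 1L, length(cells))) {
    ia <- which(cd$cell_line == cells[i])
    ib <- which(cd$cell_line == cells[j])
    cc <- crossprod(unit[, ia, drop = FALSE], unit[, ib, drop = FALSE])
    rows[[length(rows) + 1L]] <- data.frame(
      cell_a = cells[i], cell_b = cells[j],
      l4 = stats::median(cc, na.rm = TRUE),
      n_compounds = length(unique(
        intersect(cd$compound_id[ia], cd$compound_id[ib]))),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.l5FromL1 <- function(l1) {
  cells <- sort(unique(c(l1$cell_a, l1$cell_b)))
  out <- data.frame(
    cell_line = cells,
    l5 = vapply(cells, function(cl) {
      v <- l1$l1[l1$cell_a == cl | l1$cell_b == cl]
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.l5FromPairs <- function(l4, col) {
  cells <- sort(unique(c(l4$cell_a, l4$cell_b)))
  out <- data.frame(
    cell_line = cells,
    l5 = vapply(cells, function(cl) {
      v <- l4[[col]][l4$cell_a == cl | l4$cell_b == cl]
      v <- v[!is.na(v)]
      if (length(v)) stats::median(v) else NA_real_
    }, numeric(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @export
print.SimilarityLevels <- function(x, ...) {
  cat(sprintf(paste0(
    "SimilarityLevels: %d L1 pairs, %d compounds (L2), %d MOAs (L3), ",
    "%d cell pairs (L4), %d cell lines (L5)\n"),
    nrow(x$l1), nrow(x$l2), nrow(x$l3), nrow(x$l4), nrow(x$l5)))
  if (nrow(x$l2))
    cat(sprintf("  median L2 = %.4f\n", stats::median(x$l2$l2, na.rm = TRUE)))
  invisible(x)
}

#' Rank correlation between L4 and a basal-expression similarity table
#'
#' Hook for relating perturbed-expression similarity (L4) of cell-line
#' pairs to an externally computed basal-expression similarity (e.g.
#' Spearman correlation of baseline expression): joins the two tables on
#' the unordered cell pair and reports the Spearman rank correlation.
#'
#' @param l4 data.frame with \code{cell_a}, \code{cell_b}, \code{l4}.
#' @param basal data.frame with \code{cell_a}, \code{cell_b},
#'   \code{similarity}.
#' @return list with \code{rho}, \code{p_value}, \code{n_pairs}.
#' @export
l4BasalCorrelation <- function(l4, basal) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "|")
  m <- merge(
    data.frame(k = key(l4$cell_a, l4$cell_b), l4 = l4$l4),
    data.frame(k = key(basal$cell_a, basal$cell_b),
               basal = basal$similarity), by = "k")
  if (nrow(m) < 3L) stopInput("fewer than 3 shared cell pairs")
  ct <- suppressWarnings(
    stats::cor.test(m$l4, m$basal, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n_pairs = nrow(m))
}
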