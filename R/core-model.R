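#' Construct a query signature
#'
#' @param up character vector of upregulated gene identifiers.
#' @param down character vector of downregulated gene identifiers.
#' @param magnitude optional named numeric vector of log2 fold changes;
#'   positive for up genes, negative for down genes.
#' @param name signature name.
#'
#' @return A \linkS4class{QuerySignature}.
#' @examples
#' sig <- querySignature(up = c("g1", "g2"), down = "g3",
#'                       magnitude = c(g1 = 1.2, g2 = 0.8, g3 = -0.5))
#' sigSize(sig)
#' @export
querySignature <- function(up, down, magnitude = numeric(0), name = "query") {
  new("QuerySignature",
      up = as.character(up), down = as.character(down),
      magnitude = magnitude, name = as.character(name))
}

#' @rdname querySignature
#' @param x a QuerySignature.
#' @export
upGenes <- function(x) x@up

#' @rdname querySignature
#' @export
downGenes <- function(x) x@down

#' @rdname querySignature
#' @export
sigGenes <- function(x) c(x@up, x@down)

#' @rdname querySignature
#' @export
sigSize <- function(x) length(x@up) + length(x@down)

#' @rdname querySignature
#' @export
sigName <- function(x) x@name

#' Query vector of a signature
#'
#' Numeric vector over the signature's genes used by the correlation-based
#' eXtreme methods: the stored log2 fold-change magnitudes when present
#' (and \code{useMagnitude = TRUE}), else +1 for up genes and -1 for down
#' genes.
#'
#' @param x a \linkS4class{QuerySignature}.
#' @param useMagnitude use stored magnitudes when available.
#' @return named numeric vector over \code{sigGenes(x)}.
#' @export
queryVector <- function(x, useMagnitude = TRUE) {
  genes <- sigGenes(x)
  v <- ifelse(genes %in% x@up, 1, -1)
  names(v) <- genes
  if (useMagnitude && length(x@magnitude) > 0L) {
    hit <- intersect(genes, names(x@magnitude))
    v[hit] <- x@magnitude[hit]
  }
  v
}

setMethod("show", "QuerySignature", function(object) {
  cat(sprintf("QuerySignature '%s': %d up, %d down%s\n",
              object@name, length(object@up), length(object@down),
              if (length(object@magnitude)) ", with magnitudes" else ""))
})

#' Align a query signature onto a reference gene space
#'
#' Drops query genes absent from the gene space (exact, case-sensitive
#' string match) and reports what was dropped. Aligning an already aligned
#' signature is a no-op.
#'
#' @param query a \linkS4class{QuerySignature}.
#' @param geneSpace character vector of reference gene identifiers, or a
#'   \linkS4class{ReferenceProfileSet} whose rownames are used.
#' @param verbose log the drop counts to stderr.
#'
#' @return The aligned \linkS4class{QuerySignature} with a
#'   \code{"alignment"} attribute: a list with \code{dropped_up},
#'   \code{dropped_down} and \code{n_dropped}.
#' @examples
#' sig <- querySignature(up = c("g1", "g2"), down = "g3")
#' alignQuery(sig, c("g1", "g3"))
#' @export
alignQuery <- function(query, geneSpace, verbose = FALSE) {
  if (is(geneSpace, "ReferenceProfileSet")) geneSpace <- rownames(geneSpace)
  stopifnot(is.character(geneSpace))
  dropped_up <- setdiff(query@up, geneSpace)
  dropped_down <- setdiff(query@down, geneSpace)
  up <- intersect(query@up, geneSpace)
  down <- intersect(query@down, geneSpace)
  if (length(up) + length(down) == 0L)
    stopInput("no query gene overlaps the reference gene space")
  mag <- query@magnitude
  if (length(mag)) mag <- mag[names(mag) %in% c(up, down)]
  out <- querySignature(up, down, mag, query@name)
  report <- list(dropped_up = dropped_up, dropped_down = dropped_down,
                 n_dropped = length(dropped_up) + length(dropped_down))
  if (verbose && report$n_dropped > 0L)
    message(sprintf("alignQuery: dropped %d/%d genes (%d up, %d down)",
                    report$n_dropped, sigSize(query),
                    length(dropped_up), length(dropped_down)))
  attr(out, "alignment") <- report
  out
}

#' Construct a reference profile set
#'
#' @param values numeric matrix, genes x profiles; rownames are gene
#'   identifiers, colnames (if absent, taken from \code{meta$profile_id})
#'   the profile identifiers.
#' @param meta data.frame with one row per profile and columns
#'   \code{profile_id}, \code{compound_id}, \code{cell_line}, \code{dose}
#'   (uM), \code{time} (h), \code{is_gold}; optional \code{moa},
#'   \code{clinical_phase}.
#'
#' @return A \linkS4class{ReferenceProfileSet}.
#' @export
referenceProfileSet <- function(values, meta) {
  values <- as.matrix(values)
  meta <- as.data.frame(meta)
  if (ncol(values) != nrow(meta))
    stopInput("number of profiles in matrix and metadata differ")
  if (is.null(colnames(values))) colnames(values) <- meta$profile_id
  if (!identical(colnames(values), as.character(meta$profile_id)))
    stopInput("matrix column names do not match meta$profile_id")
  meta$is_gold <- as.logical(meta$is_gold)
  cd <- S4Vectors::DataFrame(meta, row.names = meta$profile_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(zscore = values), colData = cd)
  new("ReferenceProfileSet", se)
}

#' @rdname referenceProfileSet
#' @param x a ReferenceProfileSet.
#' @export
zscores <- function(x) SummarizedExperiment::assay(x, "zscore")

#' @rdname referenceProfileSet
#' @export
profileMeta <- function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
}

#' Filter profiles on quality, dose and time
#'
#' Mirrors the LINCS selection used throughout: keep high-quality
#' (\code{is_gold}) profiles from one perturbation stratum (default 10 uM,
#' 6 h). All filters are optional; pass \code{NULL} to skip one. The number
#' of excluded profiles is reported via \code{message()}.
#'
#' @param x a \linkS4class{ReferenceProfileSet}.
#' @param isGold require the quality flag (default TRUE).
#' @param dose,time keep only this dose (uM) / time (h); NULL keeps all.
#' @param cellLine optionally restrict to one or more cell lines.
#' @param verbose log the exclusion count.
#' @return the filtered \linkS4class{ReferenceProfileSet}.
#' @export
filterProfiles <- function(x, isGold = TRUE, dose = 10, time = 6,
                           cellLine = NULL, verbose = TRUE) {
  cd <- profileMeta(x)
  keep <- rep(TRUE, nrow(cd))
  if (isTRUE(isGold)) keep <- keep & cd$is_gold
  if (!is.null(dose)) keep <- keep & cd$dose == dose
  if (!is.null(time)) keep <- keep & cd$time == time
  if (!is.null(cellLine)) keep <- keep & cd$cell_line %in% cellLine
  if (verbose)
    message(sprintf("filterProfiles: kept %d/%d profiles (excluded %d)",
                    sum(keep), length(keep), sum(!keep)))
  if (!any(keep)) stopInput("no profile passes the configured filters")
  x[, keep]
}

setMethod("show", "ReferenceProfileSet", function(object) {
  cd <- profileMeta(object)
  cat(sprintf(paste0(
    "ReferenceProfileSet: %d genes x %d profiles\n",
    "  compounds: %d  cell lines: %d  is_gold: %d\n"),
    nrow(object), ncol(object),
    length(unique(cd$compound_id)), length(unique(cd$cell_line)),
    sum(cd$is_gold)))
})
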