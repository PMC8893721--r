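#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Query signature: disjoint up/down gene sets with optional magnitudes
#'
#' A disease (query) signature for connectivity mapping: a set of
#' upregulated and a set of downregulated gene identifiers, optionally
#' annotated with signed log2 fold-change magnitudes. The up and down sets
#' must be disjoint and their union non-empty; when magnitudes are supplied
#' they must be positive for up genes and negative for down genes.
#'
#' @slot up character vector of upregulated gene identifiers.
#' @slot down character vector of downregulated gene identifiers.
#' @slot magnitude named numeric vector of log2 fold changes (may be empty).
#' @slot name single string naming the signature.
#'
#' @seealso [querySignature()] for the user constructor, [alignQuery()].
#' @exportClass QuerySignature
setClass("QuerySignature",
  representation(
    up = "character",
    down = "character",
    magnitude = "numeric",
    name = "character"
  ),
  prototype(magnitude = numeric(0), name = "query")
)

setValidity("QuerySignature", function(object) {
  msgs <- character(0)
  up <- object@up
  down <- object@down
  if (anyDuplicated(up) || anyDuplicated(down))
    msgs <- c(msgs, "duplicated gene identifiers within a direction")
  if (length(intersect(up, down)) > 0L)
    msgs <- c(msgs, "up and down gene sets must be disjoint")
  if (length(up) + length(down) == 0L)
    msgs <- c(msgs, "up ∪ down must be non-empty")
  if (any(!nzchar(c(up, down))))
    msgs <- c(msgs, "gene identifiers must be non-empty strings")
  mag <- object@magnitude
  if (length(mag) > 0L) {
    if (is.null(names(mag)) || any(!nzchar(names(mag))))
      msgs <- c(msgs, "magnitudes must be named by gene")
    else {
      bad_up <- intersect(names(mag), up)
      bad_up <- bad_up[mag[bad_up] <= 0]
      bad_dn <- intersect(names(mag), down)
      bad_dn <- bad_dn[mag[bad_dn] >= 0]
      if (length(bad_up))
        msgs <- c(msgs, sprintf(
          "up genes with non-positive magnitude: %s",
          paste(utils::head(bad_up, 5), collapse = ", ")))
      if (length(bad_dn))
        msgs <- c(msgs, sprintf(
          "down genes with non-negative magnitude: %s",
          paste(utils::head(bad_dn, 5), collapse = ", ")))
    }
  }
  if (length(object@name) != 1L)
    msgs <- c(msgs, "name must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' LINCS-like reference profile set
#'
#' Container for a genes x perturbation-profiles matrix of
#' differential-expression z-scores (LINCS level-5 style "moderated
#' Z-scores") with per-profile metadata, built on
#' \linkS4class{SummarizedExperiment}. The single assay is named
#' \code{"zscore"}; rownames define the gene space (ordered, unique,
#' non-empty identifiers) and colData carries one row per profile with the
#' columns \code{profile_id}, \code{compound_id}, \code{cell_line},
#' \code{dose} (uM), \code{time} (hours), \code{is_gold} (logical quality
#' flag) and optionally \code{moa} and \code{clinical_phase}.
#'
#' @seealso [referenceProfileSet()], [loadReferenceProfiles()],
#'   [filterProfiles()], [scoreProfiles()].
#' @exportClass ReferenceProfileSet
setClass("ReferenceProfileSet", contains = "SummarizedExperiment")

.required_meta_cols <- c("profile_id", "compound_id", "cell_line",
                         "dose", "time", "is_gold")

setValidity("ReferenceProfileSet", function(object) {
  msgs <- character(0)
  if (!"zscore" %in% SummarizedExperiment::assayNames(object))
    return("assay 'zscore' is required")
  m <- SummarizedExperiment::assay(object, "zscore")
  g <- rownames(object)
  if (is.null(g) || anyDuplicated(g) || any(!nzchar(g)))
    msgs <- c(msgs, "rownames must be unique non-empty gene identifiers")
  if (!all(is.finite(m)))
    msgs <- c(msgs, "all z-score values must be finite")
  cd <- SummarizedExperiment::colData(object)
  missing_cols <- setdiff(.required_meta_cols, colnames(cd))
  if (length(missing_cols))
    msgs <- c(msgs, paste0("missing metadata columns: ",
                           paste(missing_cols, collapse = ", ")))
  else {
    if (anyDuplicated(cd$profile_id))
      msgs <- c(msgs, "profile_id must be unique")
    if (any(cd$dose <= 0) || any(cd$time <= 0))
      msgs <- c(msgs, "dose and time must be positive")
    if (!is.logical(cd$is_gold))
      msgs <- c(msgs, "is_gold must be logical")
  }
  if (length(msgs)) msgs else TRUE
})
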