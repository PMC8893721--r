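#' Read and write GCT 1.2 matrices
#'
#' Strict reader/writer for the tab-separated GCT 1.2 text format used for
#' perturbation z-score matrices: a \code{#1.2} version line, a dimensions
#' line, then a table with \code{Name} and \code{Description} columns
#' followed by one column per profile. Values are written at full double
#' precision (\code{\%.17g}), so a write/read round trip is bit-identical.
#'
#' @param path file path.
#' @return \code{readGct}: numeric matrix with gene rownames and profile
#'   colnames, with a \code{"description"} attribute.
#' @export
readGct <- function(path) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  header <- readLines(path, n = 2L)
  if (length(header) < 2L || trimws(header[1]) != "#1.2")
    stopInput("malformed GCT header: expected '#1.2' on line 1 of %s", path)
  dims <- suppressWarnings(as.integer(strsplit(header[2], "\t")[[1]]))
  if (length(dims) < 2L || anyNA(dims[1:2]))
    stopInput("malformed GCT dimensions line in %s", path)
  nr <- dims[1]; nc <- dims[2]
  tab <- utils::read.delim(path, skip = 2L, header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (ncol(tab) != nc + 2L)
    stopInput("GCT dimension mismatch in %s: dims line claims %d profiles, %d found",
              path, nc, ncol(tab) - 2L)
  if (nrow(tab) != nr)
    stopInput("GCT dimension mismatch in %s: dims line claims %d rows, %d found",
              path, nr, nrow(tab))
  vals <- as.matrix(tab[, -(1:2), drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(vals), nrow = nr,
                               dimnames = list(tab[[1]], colnames(vals))))
  bad <- is.na(m) & !(vals %in% c("NA", "NaN"))
  if (any(bad))
    stopInput("non-numeric cell in %s (first at row %d)", path,
              which(rowSums(bad) > 0)[1])
  attr(m, "description") <- tab[[2]]
  m
}

#' @rdname readGct
#' @param x numeric matrix (genes x profiles) or a
#'   \linkS4class{ReferenceProfileSet}.
#' @param description optional per-gene description column (defaults to
#'   the gene identifier).
#' @export
writeGct <- function(x, path, description = NULL) {
  if (is(x, "ReferenceProfileSet")) x <- zscores(x)
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stopInput("matrix must have row and column names")
  if (is.null(description)) description <- rownames(x)
  con <- file(path, open = "wb")  # binary: LF endings on every platform
  on.exit(close(con))
  writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
  writeLines(paste(c("Name", "Description", colnames(x)), collapse = "\t"),
             con)
  body <- vapply(seq_len(nrow(x)), function(i) {
    paste(c(rownames(x)[i], description[i], formatFull(x[i, ])),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read and write profile metadata TSVs
#'
#' Sidecar metadata keyed by \code{profile_id}, one row per profile, with
#' the columns required by [referenceProfileSet()]. Lines starting with
#' \code{#} are treated as comments (provenance blocks).
#'
#' @param path file path.
#' @return \code{readProfileMeta}: a data.frame.
#' @export
readProfileMeta <- function(path) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  meta <- utils::read.delim(path, header = TRUE, comment.char = "#",
                            stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_meta_cols, colnames(meta))
  if (length(missing_cols))
    stopInput("metadata %s lacks columns: %s", path,
              paste(missing_cols, collapse = ", "))
  meta$is_gold <- as.logical(meta$is_gold)
  meta
}

#' @rdname readProfileMeta
#' @param meta data.frame of profile metadata.
#' @export
writeProfileMeta <- function(meta, path) {
  .writeTsv(meta, path)
}

# Deterministic TSV writer (LF endings, full numeric precision).
.writeTsv <- function(df, path, comments = character(0)) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  num <- vapply(df, is.double, logical(1))
  for (j in which(num)) df[[j]] <- formatFull(df[[j]])
  writeLines(paste(colnames(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(lapply(df, as.character), sep = "\t")), con)
  invisible(path)
}

#' Read and write GMT gene/agent sets
#'
#' Standard GMT: one set per line, \code{name<TAB>description<TAB>member...}.
#' Reading is delegated to \code{fgsea::gmtPathways}.
#'
#' @param path file path.
#' @return \code{readGmt}: named list of character vectors.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  fgsea::gmtPathways(path)
}

#' @rdname readGmt
#' @param sets named list of character vectors.
#' @export
writeGmt <- function(sets, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1)), con)
  invisible(path)
}

#' Assemble a query signature from GMT entries
#'
#' Merges the \code{<name>_up} and \code{<name>_down} entries of a GMT set
#' list into one \linkS4class{QuerySignature}; both must exist and satisfy
#' the signature invariants (disjoint, non-empty union).
#'
#' @param sets named list from [readGmt()].
#' @param name base signature name (without the _up/_down suffix).
#' @return a \linkS4class{QuerySignature}.
#' @export
gmtSignature <- function(sets, name) {
  upName <- paste0(name, "_up"); dnName <- paste0(name, "_down")
  if (!upName %in% names(sets) || !dnName %in% names(sets))
    stopInput("GMT lacks '%s' and/or '%s' entries", upName, dnName)
  querySignature(sets[[upName]], sets[[dnName]], name = name)
}

#' @rdname gmtSignature
#' @param sig a \linkS4class{QuerySignature}.
#' @param path file path.
#' @export
writeSignatureGmt <- function(sig, path) {
  writeGmt(stats::setNames(list(sig@up, sig@down),
                           paste0(sig@name, c("_up", "_down"))), path)
}

#' Read and write signature TSVs
#'
#' Three-column format \code{gene<TAB>direction<TAB>log2fc} (log2fc
#' optional). Direction/magnitude sign conflicts and duplicate genes are
#' rejected with the offending line numbers.
#'
#' @param path file path.
#' @param name signature name (default: file base name).
#' @return \code{readSignatureTsv}: a \linkS4class{QuerySignature}.
#' @export
readSignatureTsv <- function(path, name = NULL) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("gene", "direction") %in% colnames(tab)))
    stopInput("signature TSV %s needs columns gene, direction", path)
  if (!all(tab$direction %in% c("up", "down")))
    stopInput("invalid direction values in %s (lines %s)", path,
              paste(which(!tab$direction %in% c("up", "down")), collapse = ", "))
  dup <- duplicated(tab$gene)
  if (any(dup))
    stopInvariant("duplicate genes in %s (lines %s)", path,
                  paste(which(dup), collapse = ", "))
  if ("log2fc" %in% colnames(tab) && !all(is.na(tab$log2fc))) {
    conflict <- (tab$direction == "up" & tab$log2fc <= 0) |
      (tab$direction == "down" & tab$log2fc >= 0)
    if (any(conflict, na.rm = TRUE))
      stopInvariant("direction/log2fc sign conflict in %s (lines %s)", path,
                    paste(which(conflict), collapse = ", "))
    mag <- stats::setNames(tab$log2fc, tab$gene)
    mag <- mag[!is.na(mag)]
  } else mag <- numeric(0)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  querySignature(tab$gene[tab$direction == "up"],
                 tab$gene[tab$direction == "down"], mag, name)
}

#' @rdname readSignatureTsv
#' @param sig a \linkS4class{QuerySignature}.
#' @param comments optional provenance comment lines.
#' @export
writeSignatureTsv <- function(sig, path, comments = character(0)) {
  genes <- sigGenes(sig)
  mag <- rep(NA_real_, length(genes))
  if (length(sig@magnitude)) {
    hit <- match(names(sig@magnitude), genes)
    mag[hit] <- sig@magnitude
  }
  .writeTsv(data.frame(gene = genes,
                       direction = ifelse(genes %in% sig@up, "up", "down"),
                       log2fc = mag, stringsAsFactors = FALSE),
            path, comments)
}

#' Read benchmark labels from a TSV
#'
#' Expects columns \code{compound_id} and \code{ic50} (uM); the
#' effective/ineffective split is derived from the threshold.
#'
#' @param path file path.
#' @param threshold IC50 cutoff in uM (default 10).
#' @return a [benchmarkLabels()] object.
#' @export
readBenchmarkLabels <- function(path, threshold = 10) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("compound_id", "ic50") %in% colnames(tab)))
    stopInput("labels TSV %s needs columns compound_id, ic50", path)
  benchmarkLabels(tab$compound_id, ic50 = tab$ic50, threshold = threshold)
}

#' @rdname readBenchmarkLabels
#' @param labels a [benchmarkLabels()] object.
#' @export
writeBenchmarkLabels <- function(labels, path) {
  .writeTsv(as.data.frame(labels), path)
}

#' Load a reference profile set from GCT + metadata TSV
#'
#' Reads the matrix and sidecar metadata, checks that profile identifiers
#' agree, and applies the configured load-time filters (quality flag,
#' dose, time) with a logged exclusion count.
#'
#' @param gctPath GCT 1.2 matrix path.
#' @param metaPath metadata TSV path.
#' @param isGold,dose,time filters passed to [filterProfiles()]; use NULL
#'   to disable one.
#' @param verbose log the exclusion count.
#' @return a \linkS4class{ReferenceProfileSet}.
#' @export
loadReferenceProfiles <- function(gctPath, metaPath, isGold = TRUE,
                                  dose = 10, time = 6, verbose = TRUE) {
  values <- readGct(gctPath)
  meta <- readProfileMeta(metaPath)
  if (!setequal(colnames(values), meta$profile_id))
    stopInput("GCT columns and metadata profile_id disagree")
  meta <- meta[match(colnames(values), meta$profile_id), ]
  refs <- referenceProfileSet(values, meta)
  filterProfiles(refs, isGold = isGold, dose = dose, time = time,
                 verbose = verbose)
}

#' Write a score table as TSV
#'
#' @param scores data.frame from [scoreProfiles()].
#' @param path file path.
#' @param comments optional provenance comment lines.
#' @export
writeScoreTable <- function(scores, path, comments = character(0)) {
  .writeTsv(scores, path, comments)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  if (!file.exists(path)) stopInput("file not found: %s", path)
  utils::read.delim(path, header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
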