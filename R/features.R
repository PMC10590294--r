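#' Normalize a count matrix to log2 counts-per-million
#'
#' \code{value = log2(1e6 * count / librarySize + 1)}, so a zero count maps
#' to exactly 0 and values are invariant to per-sample sequencing depth.
#'
#' @param counts genes x samples matrix of non-negative counts with gene
#'   and sample names.
#' @return matrix of the same shape, log2-CPM values.
#' @export
normalizeExpression <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 2L)
    failValidation("counts", "needs at least 1 gene and 2 samples")
  if (anyDuplicated(rownames(counts)))
    failValidation("counts", "duplicate gene ids")
  if (anyDuplicated(colnames(counts)))
    failValidation("counts", "duplicate sample ids")
  if (any(counts < 0))
    failValidation("counts", "counts must be non-negative")
  lib <- colSums(counts)
  if (any(lib <= 0)) {
    bad <- colnames(counts)[lib <= 0]
    stop(sprintf("zero library size for sample(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
}

#' Read and write gene-set (GMT) panels
#'
#' \code{readGeneSets} parses a GMT file into a named list of member
#' genes; \code{writeGMT} writes one (set name, description, member
#' genes, tab-separated).
#'
#' @param path GMT file path.
#' @param geneSets named list of character vectors.
#' @param description description field written for every set.
#' @return \code{readGeneSets}: named list; \code{writeGMT}: the path,
#'   invisibly.
#' @export
readGeneSets <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGeneSets
#' @export
writeGMT <- function(geneSets, path, description = "na") {
  lines <- vapply(names(geneSets), function(nm)
    paste(c(nm, description, geneSets[[nm]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' The default 62-feature signature panel
#'
#' A configurable panel of 8 immune-cell-type signature sets, 5 T-cell
#' state signature sets, and 49 single-gene features (62 features in
#' total), populated with placeholder gene ids for synthetic runs. Real
#' analyses supply their own GMT.
#'
#' @param genesPerSet member genes per signature set.
#' @return named list of gene sets (single-gene features are sets of
#'   size 1).
#' @export
defaultSignaturePanel <- function(genesPerSet = 10) {
  cellTypes <- c("Bcell", "CD4Tcell", "CD8Tcell", "NKcell", "Monocyte",
                 "Macrophage", "Dendritic", "Treg")
  tStates <- c("Texhausted", "Tnaive", "Tmemory", "Teffector", "Tcytotoxic")
  panel <- list()
  for (s in c(cellTypes, tStates))
    panel[[paste0("sig_", s)]] <-
      sprintf("%s_g%02d", s, seq_len(genesPerSet))
  for (i in seq_len(49))
    panel[[sprintf("gene_IMM%02d", i)]] <- sprintf("IMM%02d", i)
  panel
}

#' Score signature features on a normalized expression matrix
#'
#' Each gene row is z-scored across samples using the population SD
#' (ddof = 0). A signature feature is the mean of its member genes'
#' z-scores; a single-gene feature is that gene's z-score. Genes absent
#' from the matrix or with zero variance are dropped from their sets with
#' a warning; a set losing all members yields an all-NA feature, reported
#' in the \code{missing_features} attribute.
#'
#' @param normalized genes x samples matrix (e.g. from
#'   \code{\link{normalizeExpression}}).
#' @param panel named list of gene sets (see
#'   \code{\link{defaultSignaturePanel}}).
#' @return samples x features numeric matrix, with attributes
#'   \code{dropped_genes} (unresolvable or zero-variance member genes) and
#'   \code{missing_features}.
#' @export
scoreSignatures <- function(normalized, panel) {
  normalized <- as.matrix(normalized)
  if (ncol(normalized) < 2L)
    failValidation("normalized", "z-scoring needs at least 2 samples")
  if (!length(panel))
    stop("empty signature panel", call. = FALSE)

  mu <- rowMeans(normalized)
  sdPop <- sqrt(rowMeans((normalized - mu)^2))
  z <- (normalized - mu) / ifelse(sdPop == 0, 1, sdPop)
  usable <- sdPop > 0

  dropped <- character()
  missingFeatures <- character()
  out <- matrix(NA_real_, ncol(normalized), length(panel),
                dimnames = list(colnames(normalized), names(panel)))
  for (f in names(panel)) {
    members <- panel[[f]]
    found <- members[members %in% rownames(normalized)]
    lost <- c(setdiff(members, found),
              found[!usable[found]])
    found <- found[usable[found]]
    dropped <- c(dropped, lost)
    if (!length(found)) {
      missingFeatures <- c(missingFeatures, f)
      next
    }
    out[, f] <- colMeans(z[found, , drop = FALSE])
  }
  if (length(dropped))
    warning(sprintf("dropped %d unresolvable/zero-variance member gene(s): %s",
                    length(dropped),
                    paste(utils::head(unique(dropped), 10), collapse = ", ")),
            call. = FALSE)
  if (length(missingFeatures))
    warning(sprintf("feature(s) with no usable member genes: %s",
                    paste(missingFeatures, collapse = ", ")), call. = FALSE)
  attr(out, "dropped_genes") <- unique(dropped)
  attr(out, "missing_features") <- missingFeatures
  out
}

#' Join a feature matrix with a clinical table
#'
#' Inner join on sample id; ids present on only one side are dropped and
#' reported. Duplicate sample ids on either side are an error.
#'
#' @param featureMatrix samples x features matrix with rownames.
#' @param clinical data.frame with a \code{sample_id} column (or
#'   rownames).
#' @return list with \code{features} (matrix), \code{clinical}
#'   (data.frame, same row order), \code{dropped_features_ids},
#'   \code{dropped_clinical_ids}.
#' @export
assembleFeatureMatrix <- function(featureMatrix, clinical) {
  featureMatrix <- as.matrix(featureMatrix)
  fids <- rownames(featureMatrix)
  if (is.null(fids))
    failValidation("featureMatrix", "must have sample rownames")
  cids <- clinical$sample_id
  if (is.null(cids)) cids <- rownames(clinical)
  if (is.null(cids))
    failValidation("clinical", "needs a sample_id column or rownames")
  if (anyDuplicated(fids))
    failValidation("featureMatrix", "duplicated sample id")
  if (anyDuplicated(cids))
    failValidation("clinical", "duplicated sample id")
  common <- intersect(fids, cids)
  if (!length(common))
    stop("no overlapping sample ids between features and clinical table",
         call. = FALSE)
  clin <- clinical[match(common, cids), , drop = FALSE]
  rownames(clin) <- common
  list(features = featureMatrix[common, , drop = FALSE],
       clinical = clin,
       dropped_features_ids = setdiff(fids, common),
       dropped_clinical_ids = setdiff(cids, common))
}
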