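#' Read / write an expression count matrix
#'
#' TSV (genes in rows, first column gene id) or MatrixMarket (.mtx with
#' sibling \code{<stem>.rownames.txt} / \code{<stem>.colnames.txt} files).
#'
#' @param path file path (.tsv/.txt or .mtx).
#' @param counts genes x samples matrix.
#' @return \code{readExpressionMatrix}: an integer matrix;
#'   \code{writeExpressionMatrix}: the path, invisibly.
#' @export
readExpressionMatrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".rownames.txt"))
    colnames(m) <- readLines(paste0(stem, ".colnames.txt"))
    return(m)
  }
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname readExpressionMatrix
#' @export
writeExpressionMatrix <- function(counts, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(counts), paste0(stem, ".rownames.txt"))
    writeLines(colnames(counts), paste0(stem, ".colnames.txt"))
    return(invisible(path))
  }
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE)
  writeTsv(df, path)
}

#' Write a samples-x-features matrix / clinical table as TSV
#'
#' @param features samples x features matrix with sample rownames.
#' @param clinical data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFeatureMatrix <- function(features, path) {
  writeTsv(data.frame(sample_id = rownames(features), features,
                      check.names = FALSE), path)
}

#' @rdname writeFeatureMatrix
#' @export
writeClinicalTable <- function(clinical, path) {
  if (is.null(clinical$sample_id))
    clinical <- cbind(sample_id = rownames(clinical), clinical)
  writeTsv(clinical, path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
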