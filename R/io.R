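#' Write a samples x genes matrix as TSV
#'
#' First column `sample_id`, remaining columns one per gene.
#'
#' @param mat matrix with row and column names.
#' @param path output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat), as.data.frame(as.matrix(mat)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a samples x genes matrix from TSV
#'
#' @param path TSV written by [write_matrix_tsv()] (first column = ids).
#' @return numeric matrix with rownames from the first column.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write a sparse UMI matrix as a MatrixMarket triplet
#'
#' Produces `matrix.mtx`, `genes.tsv` and `barcodes.tsv` in `dir`, the
#' plain-text exchange layout used for droplet single-cell data.
#'
#' @param umi genes x cells matrix (coerced to sparse).
#' @param dir output directory (created if needed).
#' @export
write_mtx_triplet <- function(umi, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  umi <- methods::as(Matrix::Matrix(umi, sparse = TRUE), "CsparseMatrix")
  Matrix::writeMM(umi, file.path(dir, "matrix.mtx"))
  writeLines(rownames(umi), file.path(dir, "genes.tsv"))
  writeLines(colnames(umi), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a MatrixMarket UMI triplet
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return sparse genes x cells matrix.
#' @export
read_mtx_triplet <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  rownames(m) <- readLines(file.path(dir, "genes.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  methods::as(m, "CsparseMatrix")
}

#' Write a signature as a plain gene list plus JSON provenance
#'
#' @param signature a [signature_def()].
#' @param path path of the gene-list file (one symbol per line); a
#'   `<path>.json` sidecar records name, direction and provenance.
#' @export
write_signature <- function(signature, path) {
  writeLines(signature$genes, path)
  jsonlite::write_json(list(name = signature$name,
                            direction = signature$direction,
                            provenance = signature$provenance,
                            n_genes = length(signature$genes)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a signature written by [write_signature()]
#'
#' @param path gene-list path; the JSON sidecar is used when present.
#' @return a [signature_def()].
#' @export
read_signature <- function(path) {
  genes <- readLines(path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    signature_def(meta$name, genes, meta$direction,
                  provenance = meta$provenance %||% character())
  } else {
    signature_def(basename(path), genes, "up")
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
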