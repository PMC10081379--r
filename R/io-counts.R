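#' Read a UMI count matrix from MatrixMarket triplet files
#'
#' Reads the standard MTX triplet + sidecar layout produced by bacterial
#' split-pool scRNA-seq pipelines: a sparse genes x cells matrix of UMI
#' counts, a genes TSV and a barcodes TSV (first column used as identifier).
#'
#' @param mtx_path Path to the `.mtx` file (genes in rows, cells in columns).
#' @param genes_path Path to a TSV whose first column holds gene identifiers,
#'   one per matrix row, no header.
#' @param barcodes_path Path to a TSV whose first column holds cell barcodes,
#'   one per matrix column, no header.
#' @return A validated sparse `Matrix::dgCMatrix` of integer counts with
#'   gene/barcode dimnames; per-cell totals via [cell_totals()].
#' @export
read_count_matrix <- function(mtx_path, genes_path, barcodes_path) {
  m <- Matrix::readMM(mtx_path)
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             colClasses = "character")[[1]]
  barcodes <- utils::read.table(barcodes_path, sep = "\t", header = FALSE,
                                colClasses = "character")[[1]]
  if (nrow(m) != length(genes)) {
    stop("count matrix declares ", nrow(m), " genes but sidecar lists ",
         length(genes), call. = FALSE)
  }
  if (ncol(m) != length(barcodes)) {
    stop("count matrix declares ", ncol(m), " cells but sidecar lists ",
         length(barcodes), call. = FALSE)
  }
  count_matrix(m, gene_ids = genes, barcodes = barcodes)
}

#' Construct a validated count matrix
#'
#' @param counts A genes x cells matrix (dense or sparse) of non-negative
#'   integer UMI counts.
#' @param gene_ids,barcodes Unique row / column identifiers; taken from
#'   dimnames when omitted.
#' @return A validated sparse `dgCMatrix` with dimnames set.
#' @export
count_matrix <- function(counts, gene_ids = rownames(counts),
                         barcodes = colnames(counts)) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  if (methods::is(counts, "nMatrix")) counts <- counts * 1  # pattern MTX
  counts <- methods::as(methods::as(counts, "generalMatrix"),
                        "CsparseMatrix")
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(nrow(counts)))
  if (is.null(barcodes)) barcodes <- paste0("cell_", seq_len(ncol(counts)))
  vals <- counts@x
  if (any(vals < 0)) stop("negative entries in count matrix", call. = FALSE)
  if (any(vals != round(vals))) {
    stop("non-integer entries in count matrix", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("gene identifiers not unique", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("barcodes not unique", call. = FALSE)
  stopifnot(length(gene_ids) == nrow(counts), length(barcodes) == ncol(counts))
  dimnames(counts) <- list(gene_ids, barcodes)
  counts
}

#' Per-cell total UMI of a count matrix
#' @param x A count matrix.
#' @return Named numeric vector of column sums.
#' @export
cell_totals <- function(x) Matrix::colSums(x)

#' Write a count matrix as MTX + sidecar TSVs
#'
#' @param x A count matrix.
#' @param dir Output directory (created if missing). Writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(x, "CsparseMatrix"), file.path(dir, "matrix.mtx"))
  utils::write.table(rownames(x), file.path(dir, "genes.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(colnames(x), file.path(dir, "barcodes.tsv"),
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
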