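#' Single-cell UMI count container
#'
#' Bundles a sparse gene x cell UMI count matrix with per-gene annotation
#' (symbol, chromosome, TSS, mitochondrial/ribosomal flags) and per-cell
#' metadata (sample of origin, cluster label, batch). This is the raw
#' substrate of QC filtering, downsampling and pseudobulk construction.
#'
#' @param counts sparse (or dense) non-negative integer matrix, genes in rows,
#'   cells in columns; rownames are gene symbols, colnames are cell barcodes.
#' @param gene_meta data.frame with columns `symbol`, `chrom`, `tss_pos`
#'   (1-based), and logical flags `mito`, `rpl`, `rps`. Flags default to a
#'   symbol-prefix match (`mt-`, `Rpl`, `Rps`, mouse capitalization).
#' @param cell_meta data.frame with columns `cell_id`, `sample_id`,
#'   `cluster`, `batch`.
#' @return object of class `cell_counts`.
#' @export
cell_counts <- function(counts, gene_meta = NULL, cell_meta) {
  counts <- methods::as(methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
    "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (any(counts@x < 0)) stopf("counts must be non-negative")
  if (any(counts@x != round(counts@x))) stopf("counts must be integral")
  if (is.null(rownames(counts))) stopf("counts must have gene symbols as rownames")
  if (anyDuplicated(rownames(counts))) stopf("duplicate gene symbols in counts")
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(symbol = rownames(counts))
  }
  stopifnot(is.data.frame(gene_meta), is.data.frame(cell_meta))
  if (!"symbol" %in% names(gene_meta)) stopf("gene_meta needs a 'symbol' column")
  if (!identical(gene_meta$symbol, rownames(counts)))
    gene_meta <- gene_meta[match(rownames(counts), gene_meta$symbol), , drop = FALSE]
  if (anyNA(gene_meta$symbol)) stopf("gene_meta does not cover all genes")
  if (is.null(gene_meta$mito)) gene_meta$mito <- startsWith(gene_meta$symbol, "mt-")
  if (is.null(gene_meta$rpl)) gene_meta$rpl <- startsWith(gene_meta$symbol, "Rpl")
  if (is.null(gene_meta$rps)) gene_meta$rps <- startsWith(gene_meta$symbol, "Rps")
  need <- c("cell_id", "sample_id", "cluster")
  miss <- setdiff(need, names(cell_meta))
  if (length(miss)) stopf("cell_meta is missing column(s): %s", paste(miss, collapse = ", "))
  if (is.null(cell_meta$batch)) cell_meta$batch <- "batch1"
  if (nrow(cell_meta) != ncol(counts)) stopf("cell_meta rows must match count columns")
  if (anyNA(cell_meta$sample_id) || anyNA(cell_meta$cluster))
    stopf("every cell needs a sample_id and cluster label")
  rownames(gene_meta) <- NULL
  rownames(cell_meta) <- NULL
  structure(list(counts = counts, gene_meta = gene_meta, cell_meta = cell_meta),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("<cell_counts> %d genes x %d cells, %d samples, %d clusters\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$cell_meta$sample_id)),
              length(unique(x$cell_meta$cluster))))
  invisible(x)
}

#' @export
dim.cell_counts <- function(x) dim(x$counts)

subset_cells <- function(x, keep) {
  x$counts <- x$counts[, keep, drop = FALSE]
  x$cell_meta <- x$cell_meta[keep, , drop = FALSE]
  rownames(x$cell_meta) <- NULL
  x
}

subset_genes <- function(x, keep) {
  x$counts <- x$counts[keep, , drop = FALSE]
  x$gene_meta <- x$gene_meta[keep, , drop = FALSE]
  rownames(x$gene_meta) <- NULL
  x
}

#' Write counts in 10x-style triplet format
#'
#' Writes `matrix.mtx` (MatrixMarket), `genes.tsv`, `barcodes.tsv` plus
#' `cell_metadata.csv` and `gene_metadata.csv` into a directory.
#'
#' @param x a [cell_counts()] object.
#' @param dir output directory, created if absent.
#' @return `dir`, invisibly.
#' @export
write_cell_counts <- function(x, dir) {
  stopifnot(inherits(x, "cell_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write.table(x$gene_meta["symbol"], file.path(dir, "genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(data.frame(colnames(x$counts)), file.path(dir, "barcodes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.csv(x$cell_meta, file.path(dir, "cell_metadata.csv"), row.names = FALSE)
  write.csv(x$gene_meta, file.path(dir, "gene_metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read counts written by [write_cell_counts()]
#'
#' @param dir directory holding `matrix.mtx`, `genes.tsv`, `barcodes.tsv` and
#'   the metadata CSVs.
#' @return a [cell_counts()] object.
#' @export
read_cell_counts <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  genes <- read.delim(file.path(dir, "genes.tsv"), header = FALSE)[[1]]
  barcodes <- read.delim(file.path(dir, "barcodes.tsv"), header = FALSE)[[1]]
  dimnames(m) <- list(genes, barcodes)
  gm <- read.csv(file.path(dir, "gene_metadata.csv"))
  cm <- read.csv(file.path(dir, "cell_metadata.csv"))
  cell_counts(m, gene_meta = gm, cell_meta = cm)
}
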