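# Cell- and gene-level QC on the raw UMI matrix. "Reads" here means total
# UMI counts per cell, since the filters operate on the count matrix.

#' Filter cells on library size, feature count and mito/ribosomal content
#'
#' Retains cells whose total UMI count lies inside `[min_reads, max_reads]`
#' (cells equal to either bound are kept; only cells strictly beyond them are
#' dropped), whose mitochondrial fraction is at most `max_mito`, whose Rpl and
#' Rps ribosomal-protein fractions are at most `max_rpl` / `max_rps`, and with
#' at least `min_features` detected genes. The gene set is unchanged.
#'
#' @param counts a [cell_counts()] object with `mito`, `rpl`, `rps` flags in
#'   `gene_meta`.
#' @param min_reads,max_reads inclusive library-size bounds (UMI).
#' @param max_mito,max_rpl,max_rps maximum content fractions.
#' @param min_features minimum detected genes per cell.
#' @return the filtered [cell_counts()] object.
#' @export
filter_cells <- function(counts, min_reads = 400, max_reads = 6200,
                         max_mito = 0.10, max_rpl = 0.20, max_rps = 0.15,
                         min_features = 200) {
  stopifnot(inherits(counts, "cell_counts"))
  gm <- counts$gene_meta
  if (!all(c("mito", "rpl", "rps") %in% names(gm)))
    stopf("gene_meta must carry 'mito', 'rpl' and 'rps' flags")
  tot <- Matrix::colSums(counts$counts)
  feat <- Matrix::colSums(counts$counts > 0)
  frac_of <- function(flag) {
    if (!any(flag)) return(rep(0, length(tot)))
    s <- Matrix::colSums(counts$counts[flag, , drop = FALSE])
    ifelse(tot > 0, s / tot, 0)
  }
  keep <- tot >= min_reads & tot <= max_reads &
    frac_of(gm$mito) <= max_mito &
    frac_of(gm$rpl) <= max_rpl &
    frac_of(gm$rps) <= max_rps &
    feat >= min_features
  subset_cells(counts, keep)
}

#' Keep genes detected in a minimum number of cells
#'
#' @param counts a [cell_counts()] object.
#' @param min_cells minimum number of cells with a non-zero count.
#' @return the filtered [cell_counts()] object.
#' @export
filter_genes_min_cells <- function(counts, min_cells = 3) {
  stopifnot(inherits(counts, "cell_counts"))
  keep <- Matrix::rowSums(counts$counts > 0) >= min_cells
  subset_genes(counts, keep)
}

#' Randomly downsample cells
#'
#' Uniform subsample without replacement across all cells (all clusters
#' pooled), used to cap the cost of the spline tests.
#'
#' @param counts a [cell_counts()] object.
#' @param target number of cells to keep.
#' @param seed integer seed for reproducibility.
#' @return a [cell_counts()] object with `target` cells (identity with a
#'   warning when `target` exceeds the number of cells).
#' @export
downsample_cells <- function(counts, target = 10000, seed = 1) {
  stopifnot(inherits(counts, "cell_counts"))
  n <- ncol(counts$counts)
  if (target > n) {
    warnf("target (%d) exceeds number of cells (%d); returning input", target, n)
    return(counts)
  }
  keep <- sort(with_seed(seed, sample.int(n, target)))
  subset_cells(counts, keep)
}
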