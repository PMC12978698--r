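# Final prioritization: intersect DDG calls with the GWAS-colocalization
# gene table, annotate best tissues per modality, flag knockout-phenotype
# genes and summarize per boundary.

#' Read a colocalization gene table
#'
#' Expected columns: `gene`, `modality` (eQTL/sQTL), `tissue`, `score`
#' (RCP or H4 posterior probability in \[0, 1\]).
#'
#' @param x path to a CSV or a data.frame.
#' @return validated data.frame of class `coloc_table`.
#' @export
read_coloc_table <- function(x) {
  df <- if (is.character(x)) read.csv(x) else as.data.frame(x)
  need <- c("gene", "modality", "tissue", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("coloc table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(df$score < 0 | df$score > 1, na.rm = TRUE))
    stopf("coloc scores must lie in [0, 1]")
  if (!all(df$modality %in% c("eQTL", "sQTL")))
    stopf("modality must be 'eQTL' or 'sQTL'")
  class(df) <- c("coloc_table", "data.frame")
  df
}

#' Intersect DDG calls with a colocalization table
#'
#' One output row per (boundary, DDG) whose gene appears in the coloc table
#' (case-insensitive symbol match, with an optional two-column mapping
#' table), annotated with the best-scoring tissue per modality (ties broken
#' alphabetically by tissue).
#'
#' @param ddgs data.frame of DDG calls with columns `focal_gene`, `boundary`
#'   and optionally `lineage`/`trajectory` and `cluster` (e.g. filtered
#'   [call_ddgs()] output).
#' @param coloc a [read_coloc_table()] table.
#' @param mapping optional data.frame with columns `from`, `to` mapping DDG
#'   symbols into the coloc table's symbol space.
#' @return data.frame of prioritized rows (`trajectory`, `boundary`, `gene`,
#'   `eqtl_tissue`, `eqtl_rcp`, `sqtl_tissue`, `sqtl_h4pp`).
#' @export
intersect_coloc <- function(ddgs, coloc, mapping = NULL) {
  if (!nrow(ddgs)) return(empty_prioritized())
  sym <- ddgs$focal_gene
  if (!is.null(mapping)) {
    i <- match(tolower(sym), tolower(mapping$from))
    sym[!is.na(i)] <- mapping$to[i[!is.na(i)]]
  }
  key <- tolower(sym)
  hit <- key %in% tolower(coloc$gene)
  if (!any(hit)) return(empty_prioritized())
  dd <- ddgs[hit, , drop = FALSE]
  key <- key[hit]
  best_by <- function(gene_key, mod) {
    sub <- coloc[tolower(coloc$gene) == gene_key & coloc$modality == mod, ,
                 drop = FALSE]
    if (!nrow(sub)) return(list(tissue = NA_character_, score = NA_real_))
    sub <- sub[order(-sub$score, sub$tissue), , drop = FALSE]
    list(tissue = sub$tissue[1], score = sub$score[1])
  }
  rows <- lapply(seq_len(nrow(dd)), function(i) {
    e <- best_by(key[i], "eQTL")
    s <- best_by(key[i], "sQTL")
    data.frame(
      trajectory = dd$trajectory[i] %||% dd$lineage[i] %||% NA,
      boundary = dd$boundary[i],
      gene = dd$focal_gene[i],
      eqtl_tissue = e$tissue, eqtl_rcp = e$score,
      sqtl_tissue = s$tissue, sqtl_h4pp = s$score
    )
  })
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

empty_prioritized <- function() {
  data.frame(trajectory = character(0), boundary = character(0),
             gene = character(0), eqtl_tissue = character(0),
             eqtl_rcp = numeric(0), sqtl_tissue = character(0),
             sqtl_h4pp = numeric(0))
}

#' Summarize a prioritized DDG table
#'
#' Pure aggregation: total rows, distinct genes, and per-boundary row
#' counts. Invariant to row order.
#'
#' @param rows prioritized rows ([intersect_coloc()] output or a transcribed
#'   table with `boundary` and `gene` columns).
#' @return list with `rows_total`, `distinct_genes`, `per_boundary` (named
#'   counts).
#' @export
summarize_prioritized <- function(rows) {
  if (!nrow(rows))
    return(list(rows_total = 0L, distinct_genes = 0L,
                per_boundary = integer(0)))
  per <- table(rows$boundary)
  list(rows_total = nrow(rows),
       distinct_genes = length(unique(rows$gene)),
       per_boundary = setNames(as.integer(per), names(per)))
}

#' Flag genes present in a knockout-phenotype list
#'
#' @param rows prioritized rows with a `gene` column.
#' @param impc_genes character vector of gene symbols with a significant
#'   knockout bone phenotype (duplicates are deduplicated; matching is
#'   case-insensitive).
#' @return `rows` with a logical `impc_flag` column.
#' @export
flag_impc <- function(rows, impc_genes) {
  impc_genes <- unique(tolower(impc_genes))
  rows$impc_flag <- tolower(rows$gene) %in% impc_genes
  rows
}
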