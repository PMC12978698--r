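# Differentiation driver gene calling: prune each module network, extract
# three-step ego neighborhoods, keep the unusually large ones, and test each
# for enrichment of boundary-dynamic genes with the upper-tail
# hypergeometric.

#' Remove weakly connected nodes from a network
#'
#' Drops nodes with total degree (in + out) of at most one. By default a
#' single pass is applied; `iterate = TRUE` repeats to a fixed point.
#'
#' @param dag a `gene_dag`.
#' @param iterate repeat until no degree-<=1 nodes remain.
#' @return the pruned `gene_dag`.
#' @export
prune_network <- function(dag, iterate = FALSE) {
  stopifnot(inherits(dag, "gene_dag"))
  repeat {
    deg <- setNames(rep(0L, length(dag$nodes)), dag$nodes)
    tab <- table(c(dag$edges$parent, dag$edges$child))
    deg[names(tab)] <- as.integer(tab)
    drop <- names(deg)[deg <= 1]
    if (!length(drop)) break
    dag$nodes <- setdiff(dag$nodes, drop)
    dag$edges <- dag$edges[!(dag$edges$parent %in% drop | dag$edges$child %in% drop), ,
                           drop = FALSE]
    if (!iterate) break
  }
  rownames(dag$edges) <- NULL
  dag
}

#' Three-step neighborhood of a focal gene
#'
#' All nodes reachable from the focal gene within three edges, including the
#' focal gene. `mode = "all"` ignores edge direction (the default); `"out"` /
#' `"in"` follow / oppose edge direction.
#'
#' @param dag a `gene_dag`.
#' @param focal focal gene (must be a node).
#' @param mode `"all"`, `"out"` or `"in"`.
#' @param order neighborhood radius in edges.
#' @return character vector of member genes.
#' @export
three_step_neighborhood <- function(dag, focal, mode = c("all", "out", "in"),
                                    order = 3) {
  stopifnot(inherits(dag, "gene_dag"))
  mode <- match.arg(mode)
  if (!focal %in% dag$nodes) stopf("focal gene '%s' not in network", focal)
  g <- dag_igraph(dag)
  sort(names(igraph::ego(g, order = order, nodes = focal, mode = mode)[[1]]))
}

#' Extract and size-filter all neighborhoods of a network
#'
#' Builds the radius-3 neighborhood of every node of the (pruned) network and
#' retains those whose size exceeds the across-neighborhood mean by more than
#' one sample standard deviation.
#'
#' @param dag a (pruned) `gene_dag`.
#' @param mode neighborhood traversal mode, see [three_step_neighborhood()].
#' @param sd_mult size threshold in standard deviations above the mean.
#' @return list with `neighborhoods` (named list of all member sets),
#'   `retained` (names of the focal genes passing the size filter), `k`
#'   (named sizes).
#' @export
filter_neighborhoods <- function(dag, mode = "all", sd_mult = 1) {
  stopifnot(inherits(dag, "gene_dag"))
  if (length(dag$nodes) < 2) {
    warnf("fewer than 2 nodes; no neighborhoods")
    return(list(neighborhoods = list(), retained = character(0), k = integer(0)))
  }
  g <- dag_igraph(dag)
  nb <- igraph::ego(g, order = 3, nodes = dag$nodes, mode = mode)
  nb <- lapply(nb, names)
  names(nb) <- dag$nodes
  k <- lengths(nb)
  retained <- names(k)[sizes_above_mean_sd(k, sd_mult)]
  list(neighborhoods = nb, retained = retained, k = k)
}

#' Size-filter rule for neighborhoods
#'
#' Marks sizes strictly greater than `mean(k) + sd_mult * sd(k)` (sample
#' standard deviation). When all sizes are equal nothing passes (with a
#' warning).
#'
#' @param k integer vector of neighborhood sizes.
#' @param sd_mult standard-deviation multiplier.
#' @return logical vector.
#' @export
sizes_above_mean_sd <- function(k, sd_mult = 1) {
  if (length(k) < 2) stopf("need at least 2 neighborhoods")
  if (sd(k) == 0) {
    warnf("all neighborhood sizes equal; none exceed mean + %g sd", sd_mult)
    return(rep(FALSE, length(k)))
  }
  k > mean(k) + sd_mult * sd(k)
}

#' Upper-tail hypergeometric enrichment of one neighborhood
#'
#' Tests whether a neighborhood contains more boundary-dynamic genes than
#' expected by chance: `p = P(X >= overlap)` for X hypergeometric with `m`
#' successes (dynamic genes), `n` failures and `k` draws (the neighborhood
#' size), evaluated as the upper tail at `q = overlap - 1`
#' (`phyper(..., lower.tail = FALSE)`).
#'
#' The population depends on `population_mode`. `"union"` (default) draws
#' from the union of genes in retained neighborhoods and `"network"` from all
#' network genes; for both, `m` counts the dynamic genes inside that gene
#' universe and `n` its complement. `"literal"` uses the neighborhood-count
#' population printed in the source protocol verbatim: `n` = number of
#' retained neighborhoods minus the genome-wide `m`. Whenever a mode yields
#' an infeasible population, `n` is floored at `max(0, k - overlap)` and the
#' adjustment is recorded in the result.
#'
#' @param members neighborhood gene set.
#' @param dynamic_set significant dynamic genes for the boundary.
#' @param m number of dynamic genes for the boundary (defaults to
#'   `length(dynamic_set)`).
#' @param population size of the population the mode refers to (count of
#'   retained neighborhoods, union-of-genes size, or network size).
#' @param population_mode one of `"union"`, `"literal"`, `"network"` (label
#'   recorded in the output; the caller supplies the matching `population`).
#' @return one-row data.frame: `k`, `overlap`, `m`, `n`, `p`, `n_adjusted`.
#' @export
hypergeom_enrichment <- function(members, dynamic_set, m = length(dynamic_set),
                                 population, population_mode = "union") {
  k <- length(members)
  if (k < 1) stopf("empty neighborhood")
  overlap <- length(intersect(members, dynamic_set))
  n <- population - m
  adjusted <- FALSE
  if (n < k - overlap) {
    n <- max(0, k - overlap)
    adjusted <- TRUE
  }
  if (k > m + n)
    stopf("infeasible hypergeometric population under mode '%s' (k=%d > m+n=%d)",
          population_mode, k, m + n)
  p <- phyper(overlap - 1, m, n, k, lower.tail = FALSE)
  data.frame(k = k, overlap = overlap, m = m, n = n, p = p,
             n_adjusted = adjusted, population_mode = population_mode)
}

#' Neighborhood enrichment for every retained neighborhood of a network
#'
#' @param dag a (pruned) `gene_dag`.
#' @param dynamic_sets named list: boundary label -> character vector of
#'   significant dynamic genes.
#' @param mode neighborhood traversal mode.
#' @param population_mode `"union"`, `"literal"` or `"network"`, see
#'   [hypergeom_enrichment()].
#' @param sd_mult neighborhood size filter, see [filter_neighborhoods()].
#' @return data.frame with one row per (retained focal gene, boundary).
#' @export
neighborhood_enrichment <- function(dag, dynamic_sets, mode = "all",
                                    population_mode = c("union", "literal", "network"),
                                    sd_mult = 1) {
  population_mode <- match.arg(population_mode)
  fn <- filter_neighborhoods(dag, mode = mode, sd_mult = sd_mult)
  if (!length(fn$retained)) return(empty_enrichment())
  # gene universe the draws come from; under "literal" the printed
  # neighborhood-count population is used verbatim with the genome-wide m
  universe <- switch(population_mode,
    literal = NULL,
    union = unique(unlist(fn$neighborhoods[fn$retained])),
    network = dag$nodes)
  rows <- list()
  for (focal in fn$retained) {
    memb <- fn$neighborhoods[[focal]]
    for (b in names(dynamic_sets)) {
      dyn <- dynamic_sets[[b]]
      if (is.null(universe)) {
        m <- length(dyn)
        population <- length(fn$retained)
      } else {
        m <- length(intersect(dyn, universe))
        population <- length(universe)
      }
      r <- hypergeom_enrichment(memb, dyn, m = m,
                                population = population,
                                population_mode = population_mode)
      r$focal_gene <- focal
      r$boundary <- b
      r$module <- dag$module %||% NA_character_
      rows[[length(rows) + 1]] <- r
    }
  }
  do.call(rbind, rows)
}

empty_enrichment <- function() {
  data.frame(k = integer(0), overlap = integer(0), m = integer(0),
             n = integer(0), p = numeric(0), n_adjusted = logical(0),
             population_mode = character(0), focal_gene = character(0),
             boundary = character(0), module = character(0))
}

#' Call differentiation driver genes
#'
#' BH-adjusts neighborhood enrichment p-values within each (cluster,
#' boundary) family and flags `is_ddg = p_adj < alpha`. A focal gene may be a
#' DDG for several boundaries.
#'
#' @param enrichments row-bound output of [neighborhood_enrichment()] with a
#'   `cluster` column (added by the caller when combining networks).
#' @param alpha FDR level.
#' @return the input with `p_adj` and `is_ddg` columns.
#' @export
call_ddgs <- function(enrichments, alpha = 0.05) {
  if (!nrow(enrichments)) {
    enrichments$p_adj <- numeric(0)
    enrichments$is_ddg <- logical(0)
    return(enrichments)
  }
  if (is.null(enrichments$cluster)) enrichments$cluster <- "all"
  fam <- paste(enrichments$cluster, enrichments$boundary)
  enrichments$p_adj <- NA_real_
  for (f in unique(fam)) {
    idx <- which(fam == f)
    enrichments$p_adj[idx] <- bh_adjust(enrichments$p[idx])
  }
  enrichments$is_ddg <- enrichments$p_adj < alpha
  enrichments
}
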