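# Lineage inference over cluster centroids: minimum spanning tree in a
# reduced space, root-to-leaf paths, per-cell pseudotime by orthogonal
# projection onto the piecewise-linear centroid path.

#' Principal-component reduction of a QC'd count matrix
#'
#' log1p of per-cell CPM, gene-centered, truncated PCA. Used as the default
#' reduced space when none is supplied.
#'
#' @param counts a [cell_counts()] object.
#' @param n_components number of principal components.
#' @return cells x `n_components` matrix.
#' @export
reduce_pca <- function(counts, n_components = 15) {
  stopifnot(inherits(counts, "cell_counts"))
  m <- counts$counts
  cpm <- sweep(as.matrix(m), 2, pmax(Matrix::colSums(m), 1), `/`) * 1e4
  x <- t(log1p(cpm))
  x <- sweep(x, 2, colMeans(x))
  p <- prcomp(x, center = FALSE, rank. = min(n_components, dim(x) - 1))
  s <- p$x
  rownames(s) <- counts$cell_meta$cell_id
  s
}

#' Infer lineages and pseudotime from a reduced space
#'
#' Builds the Euclidean minimum spanning tree over cluster centroids in the
#' reduced space; lineages are the root-to-leaf paths of that tree. Each
#' cell's pseudotime along a lineage is the arc-length position of its
#' orthogonal projection onto the piecewise-linear path through the lineage's
#' centroids. Cells whose cluster lies on several lineages receive a
#' pseudotime per lineage and weights proportional to inverse squared
#' distance to each lineage path (normalized per cell).
#'
#' @param reduced cells x components numeric matrix (rownames are cell ids).
#' @param clusters cluster label per cell.
#' @param root root cluster label.
#' @param outlier_quantile optional distance quantile in (0, 1\]; cells of the
#'   root cluster farther from their centroid than this quantile are dropped
#'   from centroid estimation (off by default).
#' @return object of class `trajectory_set` with elements `lineages`
#'   (ordered cluster paths), `pseudotime` and `weights` (cells x lineages,
#'   NA off-lineage), `reduced_space`, `clusters`, `root`, `mst_edges`.
#' @export
infer_lineages <- function(reduced, clusters, root, outlier_quantile = NULL) {
  stopifnot(is.matrix(reduced), nrow(reduced) == length(clusters))
  labs <- unique(clusters)
  if (!root %in% labs) stopf("root cluster '%s' not among labels", root)
  if (length(labs) < 2) stopf("need at least 2 clusters")
  cent_cells <- seq_len(nrow(reduced))
  if (!is.null(outlier_quantile)) {
    rc <- which(clusters == root)
    ctr <- colMeans(reduced[rc, , drop = FALSE])
    d <- sqrt(rowSums(sweep(reduced[rc, , drop = FALSE], 2, ctr)^2))
    drop <- rc[d > quantile(d, outlier_quantile)]
    cent_cells <- setdiff(cent_cells, drop)
  }
  cents <- t(sapply(labs, function(l) {
    idx <- intersect(which(clusters == l), cent_cells)
    colMeans(reduced[idx, , drop = FALSE])
  }))
  rownames(cents) <- labs
  d <- as.matrix(dist(cents))
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  mst <- igraph::mst(g)
  leaves <- setdiff(names(which(igraph::degree(mst) == 1)), root)
  if (!length(leaves)) leaves <- setdiff(labs, root)
  lineages <- lapply(leaves, function(lf)
    names(igraph::shortest_paths(mst, from = root, to = lf)$vpath[[1]]))
  names(lineages) <- paste0("lineage_", seq_along(lineages))

  n <- nrow(reduced)
  pt <- matrix(NA_real_, n, length(lineages),
               dimnames = list(rownames(reduced), names(lineages)))
  dist2 <- matrix(NA_real_, n, length(lineages))
  for (li in seq_along(lineages)) {
    path <- lineages[[li]]
    on_lin <- which(clusters %in% path)
    proj <- project_polyline(reduced[on_lin, , drop = FALSE],
                             cents[path, , drop = FALSE])
    pt[on_lin, li] <- proj$arc
    dist2[on_lin, li] <- proj$dist2
  }
  inv <- 1 / pmax(dist2, 1e-12)
  inv[is.na(dist2)] <- NA
  w <- inv / rowSums(inv, na.rm = TRUE)
  dimnames(w) <- dimnames(pt)
  structure(list(lineages = lineages, pseudotime = pt, weights = w,
                 reduced_space = reduced, clusters = clusters, root = root,
                 centroids = cents,
                 mst_edges = igraph::as_data_frame(mst, what = "edges")),
            class = "trajectory_set")
}

# Orthogonal projection of points onto a piecewise-linear path through
# ordered vertices; returns arc-length position and squared distance.
project_polyline <- function(x, verts) {
  nseg <- nrow(verts) - 1
  seg_vec <- verts[-1, , drop = FALSE] - verts[-nrow(verts), , drop = FALSE]
  seg_len <- sqrt(rowSums(seg_vec^2))
  cum <- c(0, cumsum(seg_len))
  best_arc <- rep(NA_real_, nrow(x))
  best_d2 <- rep(Inf, nrow(x))
  for (s in seq_len(nseg)) {
    a <- verts[s, ]
    v <- seg_vec[s, ]
    L2 <- sum(v^2)
    t <- pmin(1, pmax(0, as.vector(sweep(x, 2, a) %*% v) / L2))
    px <- outer(rep(1, nrow(x)), a) + outer(t, v)
    d2 <- rowSums((x - px)^2)
    better <- d2 < best_d2
    best_d2[better] <- d2[better]
    best_arc[better] <- cum[s] + t[better] * seg_len[s]
  }
  list(arc = best_arc, dist2 = best_d2)
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("<trajectory_set> root=%s, %d lineage(s):\n", x$root,
              length(x$lineages)))
  for (l in names(x$lineages))
    cat(sprintf("  %s: %s\n", l, paste(x$lineages[[l]], collapse = " -> ")))
  invisible(x)
}

#' Pseudotime cell-type boundaries
#'
#' For each (cluster, lineage) with enough lineage-assigned cells, the
#' cluster's pseudotimes are sorted and `floor(n (1 - coverage) / 2)` cells
#' are dropped from each tail; the boundary interval is the min/max of the
#' retained cells, so it covers about `coverage` of the cluster's cells. The
#' boundary label is `<cluster>_to_<next cluster on the lineage>`
#' (`<cluster>_to_end` for the terminal cluster).
#'
#' @param traj a [infer_lineages()] result.
#' @param coverage target fraction of cells inside each boundary.
#' @param min_cells minimum lineage-assigned cells for a row.
#' @return a `boundary_table` data.frame with columns `lineage`, `cluster`,
#'   `boundary`, `t_start`, `t_end`, `n_cells`, `coverage_realized`.
#' @export
define_boundaries <- function(traj, coverage = 0.78, min_cells = 10) {
  stopifnot(inherits(traj, "trajectory_set"))
  rows <- list()
  for (li in names(traj$lineages)) {
    path <- traj$lineages[[li]]
    for (ci in seq_along(path)) {
      cl <- path[ci]
      idx <- which(traj$clusters == cl & !is.na(traj$pseudotime[, li]))
      if (length(idx) < min_cells) {
        warnf("cluster '%s' has < %d cells on %s; boundary omitted", cl,
              min_cells, li)
        next
      }
      ts <- sort(traj$pseudotime[idx, li])
      n <- length(ts)
      k <- floor(n * (1 - coverage) / 2 + 1e-9)
      kept <- ts[(k + 1):(n - k)]
      nxt <- if (ci < length(path)) path[ci + 1] else "end"
      rows[[paste(li, cl)]] <- data.frame(
        lineage = li, cluster = cl,
        boundary = paste0(cl, "_to_", nxt),
        t_start = min(kept), t_end = max(kept), n_cells = n,
        coverage_realized = length(kept) / n
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "coverage") <- coverage
  class(out) <- c("boundary_table", "data.frame")
  out
}
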