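# Hybrid Bayesian-network structure learning per co-expression module:
# constraint-based skeleton (max-min parent-child with Fisher-z partial
# correlation tests) followed by greedy hill climbing over Gaussian BIC,
# with edge additions restricted to the skeleton.

# Fisher-z test of partial correlation x _||_ y | S. Returns p-value; a
# singular conditioning set is treated as dependence (p = 0) and logged by
# the caller.
fisher_z_test <- function(C, n, x, y, S = integer(0)) {
  idx <- c(x, y, S)
  r <- tryCatch({
    if (length(S) == 0) C[x, y] else {
      P <- solve(C[idx, idx])
      -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
    }
  }, error = function(e) NA_real_)
  if (is.na(r)) return(list(p = 0, r = 1))
  r <- max(-1 + 1e-12, min(1 - 1e-12, r))
  df <- n - length(S) - 3
  if (df <= 0) return(list(p = 1, r = r))
  z <- 0.5 * log((1 + r) / (1 - r)) * sqrt(df)
  list(p = 2 * pnorm(-abs(z)), r = r)
}

subsets_upto <- function(set, kmax) {
  out <- list(integer(0))
  for (k in seq_len(min(kmax, length(set))))
    out <- c(out, utils::combn(set, k, simplify = FALSE))
  out
}

# Max association of x with target given the weakest conditioning subset of
# cpc: returns the MAXIMUM p-value over subsets (the min-association).
min_assoc <- function(C, n, x, target, cpc, max_cond) {
  pmax_ <- 0
  for (S in subsets_upto(cpc, max_cond)) {
    p <- fisher_z_test(C, n, x, target, S)$p
    if (p > pmax_) pmax_ <- p
    if (pmax_ >= 1) break
  }
  pmax_
}

#' Constraint-based candidate skeleton (max-min parent-child)
#'
#' For each target, grows a candidate parent-child (CPC) set by the max-min
#' heuristic -- repeatedly adding the variable whose weakest association with
#' the target over conditioning subsets of the current CPC (up to
#' `max_cond_set`) is strongest -- then shrinks it by removing variables
#' rendered independent given some subset. Fisher-z partial-correlation tests
#' at level `alpha`. The skeleton keeps edge X - T only if each endpoint is
#' in the other's CPC.
#'
#' @param expr samples x genes matrix.
#' @param alpha test level.
#' @param max_cond_set maximum conditioning-set size.
#' @return data.frame of undirected candidate edges (`from`, `to`),
#'   lexicographically ordered.
#' @export
mmpc_skeleton <- function(expr, alpha = 0.05, max_cond_set = 3) {
  p <- ncol(expr)
  genes <- colnames(expr)
  if (nrow(expr) < 15) stopf("need >= 15 samples for skeleton discovery")
  if (p < 2) return(data.frame(from = character(0), to = character(0)))
  C <- cor(expr)
  n <- nrow(expr)
  cpcs <- vector("list", p)
  for (t in seq_len(p)) {
    cpc <- integer(0)
    cand <- setdiff(seq_len(p), t)
    repeat {
      if (!length(cand)) break
      assoc <- vapply(cand, function(x) min_assoc(C, n, x, t, cpc, max_cond_set),
                      numeric(1))
      best <- which.min(assoc)
      if (assoc[best] >= alpha) break
      cpc <- c(cpc, cand[best])
      cand <- cand[-best]
    }
    # backward: drop members independent given some subset of the rest
    repeat {
      dropped <- FALSE
      for (x in cpc) {
        if (min_assoc(C, n, x, t, setdiff(cpc, x), max_cond_set) >= alpha) {
          cpc <- setdiff(cpc, x)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
    cpcs[[t]] <- cpc
  }
  edges <- list()
  for (t in seq_len(p)) for (x in cpcs[[t]]) {
    if (x > t && t %in% cpcs[[x]])
      edges[[length(edges) + 1]] <- data.frame(from = genes[t], to = genes[x])
  }
  if (!length(edges)) return(data.frame(from = character(0), to = character(0)))
  out <- do.call(rbind, edges)
  out[order(out$from, out$to), , drop = FALSE]
}

# Gaussian BIC score of one node given its parents (to be maximized).
node_bic <- function(expr, node, parents) {
  y <- expr[, node]
  n <- length(y)
  X <- cbind(1, expr[, parents, drop = FALSE])
  fit <- lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  sigma2 <- max(rss / n, 1e-300)
  ll <- -n / 2 * (log(2 * pi * sigma2) + 1)
  k <- length(parents) + 2
  -(-2 * ll + k * log(n)) / 2  # = ll - k/2 log n
}

#' Score-based hill climbing over a skeleton
#'
#' Greedy search over single-edge moves (add, delete, reverse) maximizing the
#' decomposable Gaussian BIC; additions are restricted to skeleton pairs,
#' deletions and reversals are unrestricted (hybrid convention). Acyclicity
#' is enforced per move, the best strictly improving move is accepted, and
#' ties break deterministically by lexicographic (parent, child).
#'
#' @param expr samples x genes matrix.
#' @param skeleton data.frame (`from`, `to`) of allowed adjacencies, e.g.
#'   from [mmpc_skeleton()].
#' @param max_iter iteration cap.
#' @return object of class `gene_dag`: list with `nodes`, `edges`
#'   (parent, child), `score`, `score_trace`.
#' @export
hill_climb <- function(expr, skeleton, max_iter = 500) {
  genes <- colnames(expr)
  p <- length(genes)
  allowed <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  if (nrow(skeleton)) {
    allowed[cbind(skeleton$from, skeleton$to)] <- TRUE
    allowed[cbind(skeleton$to, skeleton$from)] <- TRUE
  }
  amat <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  scores <- vapply(genes, function(g) node_bic(expr, g, character(0)), numeric(1))
  trace <- sum(scores)
  creates_cycle <- function(amat, from, to) {
    # would adding from->to create a cycle? (path to -> ... -> from)
    stack <- to
    seen <- character(0)
    while (length(stack)) {
      v <- stack[1]; stack <- stack[-1]
      if (v == from) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      stack <- c(stack, genes[amat[v, ]])
    }
    FALSE
  }
  for (it in seq_len(max_iter)) {
    best <- NULL
    consider <- function(kind, from, to, delta, new_scores) {
      if (delta <= 1e-9) return()
      if (!is.null(best)) {
        if (delta < best$delta - 1e-12) return()
        if (abs(delta - best$delta) <= 1e-12 &&
            paste(from, to, kind) >= paste(best$from, best$to, best$kind)) return()
      }
      best <<- list(kind = kind, from = from, to = to, delta = delta,
                    new_scores = new_scores)
    }
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j) next
      from <- genes[i]; to <- genes[j]
      pa_to <- genes[amat[, j]]
      if (!amat[i, j] && allowed[i, j]) {
        if (!creates_cycle(amat, from, to)) {
          s_new <- node_bic(expr, to, c(pa_to, from))
          consider("add", from, to, s_new - scores[to], setNames(s_new, to))
        }
      } else if (amat[i, j]) {
        s_del <- node_bic(expr, to, setdiff(pa_to, from))
        consider("delete", from, to, s_del - scores[to], setNames(s_del, to))
        # reversal: delete from->to, add to->from
        amat2 <- amat; amat2[i, j] <- FALSE
        if (!creates_cycle(amat2, to, from)) {
          pa_from <- genes[amat[, i]]
          s_to <- node_bic(expr, to, setdiff(pa_to, from))
          s_from <- node_bic(expr, from, c(pa_from, to))
          delta <- (s_to - scores[to]) + (s_from - scores[from])
          consider("reverse", from, to, delta,
                   setNames(c(s_to, s_from), c(to, from)))
        }
      }
    }
    if (is.null(best)) break
    if (best$kind == "add") {
      amat[best$from, best$to] <- TRUE
    } else if (best$kind == "delete") {
      amat[best$from, best$to] <- FALSE
    } else {
      amat[best$from, best$to] <- FALSE
      amat[best$to, best$from] <- TRUE
    }
    scores[names(best$new_scores)] <- best$new_scores
    trace <- c(trace, sum(scores))
  }
  edges <- which(amat, arr.ind = TRUE)
  edge_df <- data.frame(parent = genes[edges[, 1]], child = genes[edges[, 2]])
  edge_df <- edge_df[order(edge_df$parent, edge_df$child), , drop = FALSE]
  rownames(edge_df) <- NULL
  structure(list(nodes = genes, edges = edge_df, score = sum(scores),
                 score_trace = trace),
            class = "gene_dag")
}

#' @export
print.gene_dag <- function(x, ...) {
  cat(sprintf("<gene_dag> %d nodes, %d directed edges, BIC score %.2f\n",
              length(x$nodes), nrow(x$edges), x$score))
  invisible(x)
}

dag_igraph <- function(dag) {
  igraph::graph_from_data_frame(dag$edges, directed = TRUE,
                                vertices = dag$nodes)
}

#' Learn one Bayesian network per co-expression module (MMHC)
#'
#' @param partition a `module_partition`.
#' @param expr samples x genes expression matrix matching the partition.
#' @param alpha CI-test level for the skeleton phase.
#' @param max_cond_set maximum conditioning-set size.
#' @param min_genes modules smaller than this are skipped with a warning.
#' @param min_samples minimum samples required for skeleton discovery; with
#'   fewer, all modules are skipped with a warning.
#' @param max_genes_factor modules with more than `max_genes_factor` times
#'   the sample count are skipped with a warning: structure learning over
#'   many more variables than samples is both uninformative and costly.
#' @return named list of `gene_dag` objects (one per module).
#' @export
learn_module_networks <- function(partition, expr, alpha = 0.05,
                                  max_cond_set = 3, min_genes = 5,
                                  min_samples = 15, max_genes_factor = 3) {
  stopifnot(inherits(partition, "module_partition"))
  if (nrow(expr) < min_samples) {
    warnf("only %d samples (< %d); network learning skipped", nrow(expr),
          min_samples)
    return(list())
  }
  mods <- setdiff(unique(partition$assignments), "unassigned")
  out <- list()
  for (m in sort(mods)) {
    g <- sort(names(partition$assignments)[partition$assignments == m])
    if (length(g) < min_genes) {
      warnf("module %s has < %d genes; skipped", m, min_genes)
      next
    }
    if (length(g) > max_genes_factor * nrow(expr)) {
      warnf("module %s has %d genes for %d samples; network skipped",
            m, length(g), nrow(expr))
      next
    }
    em <- expr[, g, drop = FALSE]
    sk <- mmpc_skeleton(em, alpha = alpha, max_cond_set = max_cond_set)
    dag <- hill_climb(em, sk)
    dag$module <- m
    out[[m]] <- dag
  }
  out
}
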