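# Signed weighted co-expression modules: soft-thresholded adjacency,
# topological overlap, average-linkage tree cut, and iterative kME-based
# refinement (drop weak members, disband incoherent modules, re-detect on
# the residual pool).

#' Scale-free topology fit index for candidate soft powers
#'
#' For each power, computes the signed R^2 of the log10(frequency) vs
#' log10(connectivity) regression over connectivity bins (sign-flipped when
#' the slope is positive) and returns the smallest power reaching
#' `r2_target`, or `default_power` when none does.
#'
#' @param expr samples x genes matrix (or genes x samples with
#'   `genes_in_rows = TRUE`).
#' @param powers candidate powers.
#' @param r2_target fit-index target.
#' @param default_power returned when no power reaches the target.
#' @param nbins connectivity histogram bins.
#' @param genes_in_rows set when `expr` is genes x samples.
#' @return list with `power` and a data.frame `fit` (power, r2, mean_k).
#' @export
pick_soft_threshold <- function(expr, powers = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.85, default_power = 14,
                                nbins = 10, genes_in_rows = FALSE) {
  if (genes_in_rows) expr <- t(expr)
  if (nrow(expr) < 3) stopf("need >= 3 samples")
  sds <- apply(expr, 2, sd)
  if (any(sds == 0)) stopf("constant expression for gene(s): %s",
                           paste(head(colnames(expr)[sds == 0]), collapse = ", "))
  r <- cor(expr)
  rows <- lapply(powers, function(beta) {
    a <- ((1 + r) / 2)^beta
    k <- colSums(a) - 1
    data.frame(power = beta, r2 = sft_fit_index(k, nbins), mean_k = mean(k))
  })
  fit <- do.call(rbind, rows)
  ok <- which(!is.na(fit$r2) & fit$r2 >= r2_target)
  if (length(ok)) {
    list(power = fit$power[min(ok)], fit = fit)
  } else {
    warnf("no power reached fit index %.2f; using default %d", r2_target,
          default_power)
    list(power = default_power, fit = fit)
  }
}

sft_fit_index <- function(k, nbins = 10) {
  if (max(k) - min(k) < 1e-10) return(NA_real_)
  br <- seq(min(k), max(k), length.out = nbins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  freq <- tapply(k, bin, length)
  kmid <- tapply(k, bin, mean)
  use <- !is.na(freq) & freq > 0 & kmid > 0
  if (sum(use) < 3) return(NA_real_)
  x <- log10(kmid[use]); y <- log10(freq[use] / sum(freq[use]))
  f <- lm(y ~ x)
  r2 <- summary(f)$r.squared
  -sign(coef(f)[2]) * r2
}

#' Signed soft-thresholded adjacency
#'
#' `a_ij = ((1 + cor(x_i, x_j)) / 2)^beta` (Pearson), diagonal 1.
#'
#' @param expr samples x genes matrix.
#' @param beta soft power.
#' @param genes_in_rows set when `expr` is genes x samples.
#' @return gene x gene adjacency in \[0, 1\].
#' @export
signed_adjacency <- function(expr, beta = 14, genes_in_rows = FALSE) {
  if (beta <= 0) stopf("beta must be positive")
  if (genes_in_rows) expr <- t(expr)
  sds <- apply(expr, 2, sd)
  if (any(sds == 0)) stopf("zero-variance gene(s): %s",
                           paste(head(colnames(expr)[sds == 0]), collapse = ", "))
  a <- ((1 + cor(expr)) / 2)^beta
  diag(a) <- 1
  a
}

#' Topological overlap similarity
#'
#' `w_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for
#' `i != j`, with connectivity `k_i = sum_{u != i} a_iu`; diagonal 1.
#'
#' @param adjacency symmetric adjacency with unit diagonal.
#' @return gene x gene TOM in \[0, 1\].
#' @export
tom_similarity <- function(adjacency) {
  a <- adjacency
  diag(a) <- 0
  k <- colSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  w <- num / den
  diag(w) <- 1
  w
}

module_eigengene <- function(expr_members) {
  # expr_members: samples x member genes; first PC of standardized expression,
  # unit variance, sign-oriented to positive mean member correlation
  z <- scale(expr_members)
  z[!is.finite(z)] <- 0
  sv <- svd(z, nu = 1, nv = 0)
  e <- sv$u[, 1]
  e <- e / sd(e)
  if (mean(cor(expr_members, e)) < 0) e <- -e
  e
}

#' Detect co-expression modules from a TOM
#'
#' Average-linkage hierarchical clustering of `1 - TOM`. Candidate cut
#' heights spanning the dendrogram are scanned and the cut retained is the
#' one yielding the most coherent modules: clusters of at least
#' `min_module_size` genes whose mean within-cluster topological overlap
#' exceeds `coherence_ratio` times their mean overlap with the rest of the
#' network (ties broken toward the lower cut). Remaining genes are
#' unassigned; modules whose eigengenes correlate above `merge_cor` are
#' merged.
#'
#' @param tom TOM similarity matrix.
#' @param expr samples x genes expression (for eigengenes/kME).
#' @param min_module_size minimum module size.
#' @param coherence_ratio required ratio of within-module to module-vs-rest
#'   mean topological overlap.
#' @param max_cuts number of candidate cut heights scanned.
#' @param merge_cor eigengene correlation above which modules merge.
#' @return object of class `module_partition` with `assignments` (gene ->
#'   module id or "unassigned"), `eigengenes`, `kme`, `params`.
#' @export
detect_modules <- function(tom, expr, min_module_size = 20,
                           coherence_ratio = 2, max_cuts = 100,
                           merge_cor = 0.85) {
  genes <- colnames(tom)
  assignments <- setNames(rep("unassigned", length(genes)), genes)
  if (length(genes) < min_module_size)
    return(finish_partition(assignments, expr, min_module_size, merge_cor))
  diss <- 1 - tom
  hc <- hclust(stats::as.dist(diss), method = "average")
  hs <- sort(unique(hc$height))
  cuts <- if (length(hs) > 1) (hs[-1] + hs[-length(hs)]) / 2 else hs
  if (length(cuts) > max_cuts)
    cuts <- cuts[unique(round(seq(1, length(cuts), length.out = max_cuts)))]
  coherent_clusters <- function(groups) {
    keep <- list()
    for (gid in unique(groups)) {
      memb <- which(groups == gid)
      if (length(memb) < min_module_size || length(memb) == length(genes)) next
      within <- mean(tom[memb, memb][upper.tri(diag(length(memb)))])
      cross <- mean(tom[memb, -memb, drop = FALSE])
      if (is.finite(within) && within > coherence_ratio * cross)
        keep[[length(keep) + 1]] <- genes[memb]
    }
    keep
  }
  best <- list()
  for (h in cuts) {
    cand <- coherent_clusters(cutree(hc, h = h))
    # prefer more modules, then more genes assigned (ties keep the lower cut)
    if (length(cand) > length(best) ||
        (length(cand) == length(best) &&
         sum(lengths(cand)) > sum(lengths(best)))) best <- cand
  }
  for (i in seq_along(best)) assignments[best[[i]]] <- paste0("ME", i)
  finish_partition(assignments, expr, min_module_size, merge_cor)
}

finish_partition <- function(assignments, expr, min_module_size, merge_cor) {
  repeat {
    mods <- setdiff(unique(assignments), "unassigned")
    if (length(mods) < 2) break
    eg <- sapply(mods, function(m)
      module_eigengene(expr[, names(assignments)[assignments == m], drop = FALSE]))
    ec <- cor(eg)
    diag(ec) <- 0
    mx <- which(ec == max(ec), arr.ind = TRUE)[1, ]
    if (max(ec) <= merge_cor) break
    assignments[assignments == mods[mx[2]]] <- mods[mx[1]]
  }
  mods <- setdiff(unique(assignments), "unassigned")
  # stable ids by size
  sizes <- sort(table(assignments[assignments != "unassigned"]), decreasing = TRUE)
  relabel <- setNames(paste0("ME", seq_along(sizes)), names(sizes))
  assignments[assignments != "unassigned"] <- relabel[assignments[assignments != "unassigned"]]
  mods <- setdiff(unique(assignments), "unassigned")
  eigengenes <- if (length(mods))
    sapply(sort(mods), function(m)
      module_eigengene(expr[, names(assignments)[assignments == m], drop = FALSE]))
  else matrix(numeric(0), nrow(expr), 0)
  kme <- setNames(rep(NA_real_, length(assignments)), names(assignments))
  for (m in mods) {
    g <- names(assignments)[assignments == m]
    kme[g] <- as.vector(cor(expr[, g, drop = FALSE], eigengenes[, m]))
  }
  structure(list(assignments = assignments, eigengenes = eigengenes, kme = kme,
                 params = list(min_module_size = min_module_size,
                               merge_cor = merge_cor)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  mods <- setdiff(unique(x$assignments), "unassigned")
  cat(sprintf("<module_partition> %d modules over %d genes (%d unassigned)\n",
              length(mods), length(x$assignments),
              sum(x$assignments == "unassigned")))
  invisible(x)
}

#' Iterative kME refinement of a module partition
#'
#' Repeats until stable (or `max_iter`): recompute eigengenes and kME; drop
#' members with `kME < min_kme_to_stay` to the residual pool; disband modules
#' whose mean member kME falls below `min_core_kme`; re-run module detection
#' on the residual pool (with the same adjacency power) and add any new
#' modules.
#'
#' @param partition a [detect_modules()] result.
#' @param expr samples x genes expression matrix.
#' @param beta soft power used for re-detection on the residual pool.
#' @param min_kme_to_stay minimum kME to keep a member.
#' @param min_core_kme minimum mean member kME for a module to survive.
#' @param max_iter iteration cap.
#' @return refined `module_partition`.
#' @export
iterative_refine <- function(partition, expr, beta = 14, min_kme_to_stay = 0.5,
                             min_core_kme = 0.7, max_iter = 10) {
  stopifnot(inherits(partition, "module_partition"))
  assignments <- partition$assignments
  min_size <- partition$params$min_module_size
  for (it in seq_len(max_iter)) {
    prev <- assignments
    mods <- setdiff(unique(assignments), "unassigned")
    for (m in mods) {
      g <- names(assignments)[assignments == m]
      e <- module_eigengene(expr[, g, drop = FALSE])
      km <- as.vector(cor(expr[, g, drop = FALSE], e))
      drop <- g[km < min_kme_to_stay]
      assignments[drop] <- "unassigned"
      g <- setdiff(g, drop)
      if (length(g) < min_size) {
        assignments[g] <- "unassigned"
        next
      }
      e <- module_eigengene(expr[, g, drop = FALSE])
      km2 <- as.vector(cor(expr[, g, drop = FALSE], e))
      if (mean(km2) < min_core_kme) assignments[g] <- "unassigned"
    }
    # attempt re-detection on the residual pool
    pool <- names(assignments)[assignments == "unassigned"]
    if (length(pool) >= min_size) {
      pa <- signed_adjacency(expr[, pool, drop = FALSE], beta)
      pw <- tom_similarity(pa)
      sub <- detect_modules(pw, expr[, pool, drop = FALSE],
                            min_module_size = min_size,
                            merge_cor = partition$params$merge_cor)
      new_mods <- setdiff(unique(sub$assignments), "unassigned")
      for (nm in new_mods) {
        gg <- names(sub$assignments)[sub$assignments == nm]
        e <- module_eigengene(expr[, gg, drop = FALSE])
        if (mean(cor(expr[, gg, drop = FALSE], e)) >= min_core_kme)
          assignments[gg] <- paste0("new", it, "_", nm)
      }
    }
    if (identical(prev, assignments)) break
  }
  # final sweep: merging can leave members below the kME floor; drop them
  repeat {
    out <- finish_partition(assignments, expr, min_size,
                            partition$params$merge_cor)
    weak <- names(out$assignments)[out$assignments != "unassigned" &
                                     !is.na(out$kme) &
                                     out$kme < min_kme_to_stay]
    small <- names(table(out$assignments[out$assignments != "unassigned"]))
    if (!length(weak)) break
    assignments <- out$assignments
    assignments[weak] <- "unassigned"
    # dropping members can shrink a module below the floor; finish handles it
    sizes <- table(assignments[assignments != "unassigned"])
    for (mm in names(sizes)[sizes < min_size])
      assignments[assignments == mm] <- "unassigned"
  }
  out$params$min_kme_to_stay <- min_kme_to_stay
  out$params$min_core_kme <- min_core_kme
  out
}

#' Detect and refine modules for one cluster's pseudobulk matrix
#'
#' Convenience wrapper: soft threshold (configured or picked), signed
#' adjacency, TOM, detection, iterative refinement.
#'
#' @param expr_cluster genes x samples pseudobulk matrix (quantile stage).
#' @param beta soft power (NULL to pick by scale-free fit).
#' @param min_module_size,min_kme_to_stay,min_core_kme see
#'   [detect_modules()] / [iterative_refine()].
#' @return a `module_partition`.
#' @export
find_modules <- function(expr_cluster, beta = 14, min_module_size = 20,
                         min_kme_to_stay = 0.5, min_core_kme = 0.7) {
  expr <- t(expr_cluster)
  keep <- apply(expr, 2, sd) > 0
  expr <- expr[, keep, drop = FALSE]
  if (is.null(beta)) beta <- pick_soft_threshold(expr)$power
  a <- signed_adjacency(expr, beta)
  w <- tom_similarity(a)
  p0 <- detect_modules(w, expr, min_module_size = min_module_size)
  iterative_refine(p0, expr, beta = beta, min_kme_to_stay = min_kme_to_stay,
                   min_core_kme = min_core_kme)
}
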