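# Boundary-dynamic gene detection: per-lineage negative-binomial regression
# of counts on a cubic B-spline basis in pseudotime (log link, log-size-factor
# offset, lineage weights as cell weights), followed by threshold Wald tests
# contrasting the spline at the boundary start and end.

#' Cubic B-spline basis with knots at pseudotime quantiles
#'
#' The basis (including its knot placement) is shared by all genes of a run.
#'
#' @param pseudotime numeric vector of pseudotimes defining knot placement.
#' @param nknots total number of knots (boundary + interior).
#' @return object of class `spline_basis`; evaluate with [basis_eval()].
#' @export
spline_basis <- function(pseudotime, nknots = 10) {
  pt <- pseudotime[is.finite(pseudotime)]
  if (!length(pt)) stopf("no finite pseudotimes")
  bounds <- range(pt)
  if (nknots > 2) {
    probs <- seq(0, 1, length.out = nknots)[-c(1, nknots)]
    interior <- unique(quantile(pt, probs, names = FALSE, type = 7))
    interior <- interior[interior > bounds[1] & interior < bounds[2]]
  } else interior <- numeric(0)
  structure(list(knots = interior, bounds = bounds), class = "spline_basis")
}

#' Evaluate a spline basis
#'
#' @param basis a [spline_basis()].
#' @param t pseudotimes (clamped to the basis range).
#' @return design matrix with intercept column.
#' @export
basis_eval <- function(basis, t) {
  t <- pmin(pmax(t, basis$bounds[1]), basis$bounds[2])
  b <- splines::bs(t, knots = basis$knots, degree = 3, intercept = FALSE,
                   Boundary.knots = basis$bounds)
  cbind(`(Intercept)` = 1, unclass(b))
}

# One NB IRLS fit: counts ~ basis with offset and prior weights. Dispersion
# (1/theta) by method of moments on Pearson residuals, refit once.
fit_nb_one <- function(y, X, offset, w, max_iter = 50) {
  ok <- w > 1e-8
  y <- y[ok]; X <- X[ok, , drop = FALSE]; offset <- offset[ok]; w <- w[ok]
  theta <- 20
  fit <- NULL
  for (pass in 1:2) {
    fit <- tryCatch(suppressWarnings(
      stats::glm.fit(X, y, weights = w, offset = offset,
                     family = MASS::negative.binomial(theta = theta),
                     control = list(maxit = max_iter))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) return(NULL)
    mu <- fit$fitted.values
    df_res <- max(1, sum(ok) - ncol(X))
    # method of moments: E[(y-mu)^2] = mu + mu^2/theta
    num <- sum(w * ((y - mu)^2 - mu))
    den <- sum(w * mu^2)
    alpha <- max(num / den * length(y) / df_res, 1e-4)
    theta_new <- 1 / min(alpha, 100)
    if (abs(log(theta_new / theta)) < 0.05) { theta <- theta_new; break }
    theta <- theta_new
  }
  # coefficient covariance from the weighted Fisher information
  eta <- fit$linear.predictors
  mu <- fit$fitted.values
  wt <- w * mu / (1 + mu / theta)    # var(y) = mu + mu^2/theta, log link
  XtWX <- crossprod(X * sqrt(wt))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(NULL)
  list(beta = fit$coefficients, cov = cov, theta = theta,
       converged = fit$converged)
}

#' Fit the per-lineage NB spline smoother for one gene
#'
#' @param gene_counts integer vector of raw counts, one per cell.
#' @param traj a [infer_lineages()] result (pseudotime + lineage weights).
#' @param basis a shared named list of per-lineage [spline_basis()] objects
#'   (one basis per lineage, knots at that lineage's pseudotime quantiles);
#'   built from `traj` when NULL.
#' @param nknots knots used when `basis` is NULL.
#' @param size_factors per-cell size factors for the log offset; defaults to
#'   total counts of the matrix the gene came from are unknown here, so
#'   callers should pass library-size factors (see [fit_dynamic_genes()]).
#' @param min_cells minimum weighted cells per lineage to attempt a fit.
#' @return object of class `smoother_fit`: per-lineage list of coefficients,
#'   covariance and dispersion, plus the basis. Lineages that fail to
#'   converge are flagged and excluded from testing.
#' @export
fit_nb_spline <- function(gene_counts, traj, basis = NULL, nknots = 10,
                          size_factors = NULL, min_cells = 50) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (is.null(basis)) basis <- smoother_bases(traj, nknots)
  if (is.null(size_factors)) size_factors <- rep(1, length(gene_counts))
  fits <- list()
  for (li in colnames(traj$pseudotime)) {
    pt <- traj$pseudotime[, li]
    w <- traj$weights[, li]
    idx <- which(!is.na(pt) & !is.na(w))
    if (sum(w[idx]) < min_cells) { fits[[li]] <- NULL; next }
    X <- basis_eval(basis[[li]], pt[idx])
    f <- fit_nb_one(gene_counts[idx], X, log(size_factors[idx]), w[idx])
    fits[[li]] <- f
  }
  structure(list(lineages = fits, basis = basis), class = "smoother_fit")
}

#' Per-lineage spline bases for a trajectory
#'
#' One cubic B-spline basis per lineage with knots at that lineage's
#' pseudotime quantiles, shared by every gene of a run.
#'
#' @param traj a [infer_lineages()] result.
#' @param nknots knots per lineage.
#' @return named list of [spline_basis()] objects.
#' @export
smoother_bases <- function(traj, nknots = 10) {
  out <- lapply(colnames(traj$pseudotime), function(li)
    spline_basis(traj$pseudotime[, li], nknots))
  names(out) <- colnames(traj$pseudotime)
  out
}

wald_threshold <- function(delta, var_delta, df1 = 1, l2fc = 0.5) {
  thr <- l2fc * log(2)
  shrunk <- pmax(0, abs(delta) - thr)
  stat <- sum(shrunk^2 / var_delta)
  list(stat = stat, p = pchisq(stat, df = df1, lower.tail = FALSE))
}

#' Start-vs-end threshold Wald test for one boundary
#'
#' Contrasts the fitted spline at the boundary end versus start on the
#' natural-log scale: `Delta = (basis(t_end) - basis(t_start)) . beta`. The
#' statistic `max(0, |Delta| - l2fc*ln 2)^2 / Var(Delta)` is referred to a
#' chi-square with 1 df, so changes below the fold-change threshold are not
#' called.
#'
#' @param fit a [fit_nb_spline()] result.
#' @param boundary one row of a [define_boundaries()] table.
#' @param l2fc log2 fold-change threshold.
#' @return data.frame row with `boundary`, `lineage`, `wald_stat`, `df`, `p`,
#'   `delta_log2`; NA statistics when the lineage fit is missing or the
#'   contrast variance is not positive.
#' @export
start_vs_end_test <- function(fit, boundary, l2fc = 0.5) {
  stopifnot(inherits(fit, "smoother_fit"))
  li <- boundary$lineage
  f <- fit$lineages[[li]]
  out <- data.frame(boundary = boundary$boundary, lineage = li,
                    wald_stat = NA_real_, df = 1L, p = NA_real_,
                    delta_log2 = NA_real_, l2fc_threshold = l2fc)
  if (is.null(f)) return(out)
  ctr <- basis_eval(fit$basis[[li]], boundary$t_end) -
    basis_eval(fit$basis[[li]], boundary$t_start)
  delta <- as.numeric(ctr %*% f$beta)
  v <- as.numeric(ctr %*% f$cov %*% t(ctr))
  out$delta_log2 <- delta / log(2)
  if (!is.finite(v) || v <= 0) return(out)
  wt <- wald_threshold(delta, v, 1, l2fc)
  out$wald_stat <- wt$stat
  out$p <- wt$p
  out
}

#' Global start-vs-end test across lineages sharing a cluster
#'
#' Joint Wald test stacking the per-lineage start-vs-end contrasts (each
#' thresholded as in [start_vs_end_test()]), referred to a chi-square with
#' one degree of freedom per lineage. With a single boundary row this
#' reduces to the trajectory-specific test.
#'
#' @param fit a [fit_nb_spline()] result.
#' @param boundaries boundary rows (same cluster, different lineages).
#' @param l2fc log2 fold-change threshold.
#' @return one data.frame row with `boundary = "global"` plus the cluster.
#' @export
global_start_vs_end_test <- function(fit, boundaries, l2fc = 0.5) {
  stopifnot(inherits(fit, "smoother_fit"))
  deltas <- c(); vars <- c()
  for (r in seq_len(nrow(boundaries))) {
    b <- boundaries[r, ]
    f <- fit$lineages[[b$lineage]]
    if (is.null(f)) next
    ctr <- basis_eval(fit$basis[[b$lineage]], b$t_end) -
      basis_eval(fit$basis[[b$lineage]], b$t_start)
    v <- as.numeric(ctr %*% f$cov %*% t(ctr))
    if (!is.finite(v) || v <= 0) next
    deltas <- c(deltas, as.numeric(ctr %*% f$beta))
    vars <- c(vars, v)
  }
  cl <- unique(boundaries$cluster)
  if (!length(deltas))
    return(data.frame(boundary = "global", cluster = cl[1], wald_stat = NA_real_,
                      df = 0L, p = NA_real_, delta_log2 = NA_real_,
                      l2fc_threshold = l2fc))
  wt <- wald_threshold(deltas, vars, length(deltas), l2fc)
  data.frame(boundary = "global", cluster = cl[1], wald_stat = wt$stat,
             df = length(deltas), p = wt$p,
             delta_log2 = deltas[which.max(abs(deltas))] / log(2),
             l2fc_threshold = l2fc)
}

#' Benjamini-Hochberg adjustment and significance calls
#'
#' Adjusts p-values within each (boundary, lineage) family and flags
#' `significant = p_adj < alpha`.
#'
#' @param results data.frame of test rows with columns `boundary`, `p` (and
#'   optionally `lineage`).
#' @param alpha FDR level.
#' @return `results` with `p_adj` and `significant` columns.
#' @export
adjust_and_call <- function(results, alpha = 0.05) {
  fam <- if ("lineage" %in% names(results))
    paste(results$boundary, results$lineage) else results$boundary
  results$p_adj <- NA_real_
  for (f in unique(fam)) {
    idx <- which(fam == f & !is.na(results$p))
    results$p_adj[idx] <- bh_adjust(results$p[idx])
  }
  results$significant <- !is.na(results$p_adj) & results$p_adj < alpha
  results
}

#' Run the boundary-dynamic gene tests for a whole count matrix
#'
#' Fits the shared-basis NB spline per gene and applies the trajectory-
#' specific start-vs-end test at every boundary plus the global test per
#' cluster, then BH-adjusts within each (boundary, lineage) family.
#'
#' @param counts a (typically downsampled) [cell_counts()] object.
#' @param traj matching [infer_lineages()] result.
#' @param boundaries a [define_boundaries()] table.
#' @param nknots spline knots.
#' @param l2fc log2 fold-change threshold.
#' @param alpha FDR level.
#' @param genes optional subset of genes to test.
#' @return list with data.frames `trajectory` (per gene x boundary) and
#'   `global` (per gene x cluster), each with `p_adj` and `significant`.
#' @export
fit_dynamic_genes <- function(counts, traj, boundaries, nknots = 10,
                              l2fc = 0.5, alpha = 0.05, genes = NULL) {
  stopifnot(inherits(counts, "cell_counts"))
  genes <- genes %||% rownames(counts$counts)
  lib <- Matrix::colSums(counts$counts)
  sf <- lib / mean(lib)
  sf[sf <= 0] <- min(sf[sf > 0])
  basis <- smoother_bases(traj, nknots)
  traj_rows <- list(); glob_rows <- list(); n_failed <- 0L
  for (g in genes) {
    y <- as.numeric(counts$counts[g, ])
    fit <- fit_nb_spline(y, traj, basis = basis, size_factors = sf)
    if (all(vapply(fit$lineages, is.null, logical(1)))) { n_failed <- n_failed + 1L; next }
    for (r in seq_len(nrow(boundaries))) {
      row <- start_vs_end_test(fit, boundaries[r, ], l2fc)
      row$gene <- g
      row$cluster <- boundaries$cluster[r]
      traj_rows[[length(traj_rows) + 1L]] <- row
    }
    for (cl in unique(boundaries$cluster)) {
      bcl <- boundaries[boundaries$cluster == cl, , drop = FALSE]
      row <- global_start_vs_end_test(fit, bcl, l2fc)
      row$gene <- g
      glob_rows[[length(glob_rows) + 1L]] <- row
    }
  }
  if (n_failed) message(sprintf("%d gene fits failed to converge and were excluded", n_failed))
  traj_df <- do.call(rbind, traj_rows)
  glob_df <- do.call(rbind, glob_rows)
  traj_df <- adjust_and_call(traj_df, alpha)
  glob_df <- adjust_and_call(glob_df, alpha)
  list(trajectory = traj_df, global = glob_df)
}
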