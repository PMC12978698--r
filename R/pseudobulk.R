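# Per-cluster, per-sample mean-expression pseudobulk and its normalization
# chain: raw_mean -> cpm -> vst -> quantile. Stage tags enforce the order.

pb_stages <- c("raw_mean", "cpm", "vst", "quantile")

new_pseudobulk <- function(matrices, stage, contributing_cells) {
  structure(list(matrices = matrices, stage = stage,
                 contributing_cells = contributing_cells),
            class = "pseudobulk_set")
}

#' @export
print.pseudobulk_set <- function(x, ...) {
  cat(sprintf("<pseudobulk_set> stage=%s, %d cluster(s)\n", x$stage,
              length(x$matrices)))
  for (cl in names(x$matrices))
    cat(sprintf("  %s: %d genes x %d samples\n", cl, nrow(x$matrices[[cl]]),
                ncol(x$matrices[[cl]])))
  invisible(x)
}

check_stage <- function(pb, expected, op) {
  if (!inherits(pb, "pseudobulk_set")) stopf("%s expects a pseudobulk_set", op)
  if (!pb$stage %in% expected)
    stopf("%s requires stage %s, got '%s' (chain is raw_mean -> cpm -> vst -> quantile)",
          op, paste(sQuote(expected), collapse = " or "), pb$stage)
}

#' Mean-expression pseudobulk per cluster
#'
#' For each sample contributing at least `min_cells` cells to a cluster,
#' unnormalized UMI counts are averaged over those cells and rounded to two
#' decimal places (round-half-to-even). Samples below the cell threshold are
#' omitted from that cluster's matrix.
#'
#' @param counts a QC'd [cell_counts()] object.
#' @param min_cells minimum cells a sample must contribute to a cluster.
#' @return a `pseudobulk_set` at stage `raw_mean`.
#' @export
mean_expression <- function(counts, min_cells = 5) {
  stopifnot(inherits(counts, "cell_counts"))
  cm <- counts$cell_meta
  mats <- list()
  contrib <- list()
  for (cl in sort(unique(cm$cluster))) {
    in_cl <- cm$cluster == cl
    tab <- table(cm$sample_id[in_cl])
    ok_samples <- names(tab)[tab >= min_cells]
    if (!length(ok_samples)) {
      warnf("cluster '%s' has no sample with >= %d cells; empty matrix", cl, min_cells)
      mats[[cl]] <- matrix(numeric(0), nrow(counts$counts), 0,
                           dimnames = list(rownames(counts$counts), NULL))
      next
    }
    m <- vapply(ok_samples, function(s) {
      idx <- which(in_cl & cm$sample_id == s)
      round(Matrix::rowSums(counts$counts[, idx, drop = FALSE]) / length(idx), 2)
    }, numeric(nrow(counts$counts)))
    m <- matrix(m, nrow = nrow(counts$counts),
                dimnames = list(rownames(counts$counts), ok_samples))
    mats[[cl]] <- m
    contrib[[cl]] <- data.frame(cluster = cl, sample_id = ok_samples,
                                n_cells = as.integer(tab[ok_samples]))
  }
  new_pseudobulk(mats, "raw_mean",
                 if (length(contrib)) do.call(rbind, contrib) else
                   data.frame(cluster = character(), sample_id = character(),
                              n_cells = integer()))
}

#' Drop genes expressed in too few samples
#'
#' Per cluster independently, genes with non-zero pseudobulk values in fewer
#' than `min_nonzero` samples are removed.
#'
#' @param pb a `pseudobulk_set` at stage `raw_mean`.
#' @param min_nonzero minimum number of samples with non-zero expression.
#' @return the filtered `pseudobulk_set`.
#' @export
filter_low_expressed <- function(pb, min_nonzero = 15) {
  check_stage(pb, "raw_mean", "filter_low_expressed")
  pb$matrices <- lapply(pb$matrices, function(m)
    m[rowSums(m > 0) >= min_nonzero, , drop = FALSE])
  pb
}

#' Counts-per-million normalization (no log)
#'
#' Each column is scaled to sum to one million.
#'
#' @param pb a `pseudobulk_set` at stage `raw_mean`.
#' @return a `pseudobulk_set` at stage `cpm`.
#' @export
normalize_cpm <- function(pb) {
  check_stage(pb, "raw_mean", "normalize_cpm")
  cls <- names(pb$matrices)
  pb$matrices <- lapply(cls, function(cl) {
    m <- pb$matrices[[cl]]
    cs <- colSums(m)
    if (any(cs == 0))
      stopf("cluster '%s': zero column sum for sample(s) %s", cl,
            paste(colnames(m)[cs == 0], collapse = ", "))
    sweep(m, 2, cs, `/`) * 1e6
  })
  names(pb$matrices) <- cls
  pb$stage <- "cpm"
  pb
}

# Median-of-ratios size factors over genes with all-positive rows.
size_factors_mor <- function(m) {
  pos <- rowSums(m <= 0) == 0
  if (!any(pos)) return(rep(1, ncol(m)))
  lg <- log(m[pos, , drop = FALSE])
  geo <- rowMeans(lg)
  apply(exp(sweep(lg, 1, geo)), 2, median)
}

# Dispersion trend alpha(mu) = a1/mu + a0, fitted by two passes of reweighted
# gamma regression on method-of-moments gene dispersions; least squares on
# log dispersions is the fallback when the GLM diverges.
fit_dispersion_trend <- function(mu, alpha) {
  use <- is.finite(alpha) & alpha > 1e-8 & mu > 0
  if (sum(use) < 10) return(NULL)
  df <- data.frame(a = alpha[use], im = 1 / mu[use])
  fit <- tryCatch({
    g <- stats::glm(a ~ im, data = df, family = stats::Gamma(link = "identity"),
                    start = c(max(mean(df$a) / 2, 1e-3), 1e-3))
    # second pass: drop gross outliers relative to the first fit
    r <- df$a / pmax(stats::fitted(g), 1e-8)
    keep <- r > 1e-4 & r < 15
    stats::glm(a ~ im, data = df[keep, ], family = stats::Gamma(link = "identity"),
               start = pmax(coef(g), 1e-4))
  }, error = function(e) NULL, warning = function(w) NULL)
  co <- if (!is.null(fit)) coef(fit) else NULL
  if (is.null(co) || !all(is.finite(co))) {
    ls <- stats::lm(log(a) ~ log(im), data = df)
    # crude log-linear fallback mapped onto the a0 + a1/mu form
    a0 <- exp(coef(ls)[1]) * median(df$im)^coef(ls)[2]
    co <- c(a0, max(0, a0 * 0.5))
  }
  c(a0 = unname(co[1]), a1 = max(0, unname(co[2])))
}

vst_closed_form <- function(q, a0, a1) {
  log2((1 + a1 + 2 * a0 * q + 2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
}

#' Variance-stabilizing transform
#'
#' Per cluster: (1) median-of-ratios size factors; (2) per-gene
#' method-of-moments dispersions with a parametric trend
#' `alpha(mu) = a1/mu + a0` fitted by reweighted gamma regression; (3) the
#' closed-form transform
#' `f(q) = log2((1 + a1 + 2 a0 q + 2 sqrt(a0 q (1 + a1 + a0 q))) / (4 a0))`
#' applied to size-factor-normalized values, monotone increasing in `q`. If
#' the fitted `a0` is not positive the cluster falls back to `log2(q + 1)`
#' with a warning.
#'
#' @param pb a `pseudobulk_set` at stage `cpm` with at least two samples per
#'   cluster.
#' @return a `pseudobulk_set` at stage `vst`.
#' @export
vst_transform <- function(pb) {
  check_stage(pb, "cpm", "vst_transform")
  cls <- names(pb$matrices)
  pb$matrices <- lapply(cls, function(cl) {
    m <- pb$matrices[[cl]]
    if (ncol(m) < 2) stopf("cluster '%s': VST needs >= 2 samples", cl)
    sf <- size_factors_mor(m)
    q <- sweep(m, 2, sf, `/`)
    mu <- rowMeans(q)
    v <- apply(q, 1, var)
    alpha <- (v - mu) / mu^2
    tr <- fit_dispersion_trend(mu, alpha)
    if (is.null(tr) || tr["a0"] <= 0) {
      warnf("cluster '%s': dispersion trend fit degenerate; using log2(q+1)", cl)
      return(log2(q + 1))
    }
    vst_closed_form(q, tr["a0"], tr["a1"])
  })
  names(pb$matrices) <- cls
  pb$stage <- "vst"
  pb
}

#' Quantile normalization
#'
#' Each column's values are replaced by the mean of the order statistics
#' across columns at the same rank, so all columns share an identical sorted
#' value vector. With `ties = "first"` (the default) tied values are assigned
#' consecutive reference values in order of occurrence, which keeps the
#' column distributions exactly identical; with `ties = "average"` tied
#' values receive the mean of the reference values they span (the behavior of
#' [limma::normalizeQuantiles()] with `ties = TRUE`), which preserves
#' within-column equality of ties at the cost of exact distribution matching.
#'
#' @param pb a `pseudobulk_set` at stage `vst`.
#' @param ties `"first"` or `"average"`, see Details.
#' @return a `pseudobulk_set` at stage `quantile`.
#' @export
quantile_normalize <- function(pb, ties = c("first", "average")) {
  ties <- match.arg(ties)
  check_stage(pb, "vst", "quantile_normalize")
  pb$matrices <- lapply(pb$matrices, function(m) {
    if (ncol(m) == 0 || nrow(m) == 0) return(m)
    ref <- rowMeans(apply(m, 2, sort))
    out <- m
    for (j in seq_len(ncol(m))) {
      if (ties == "first") {
        out[order(m[, j]), j] <- ref
      } else {
        r <- rank(m[, j], ties.method = "average")
        out[, j] <- approx(seq_along(ref), ref, xout = r)$y
      }
    }
    out
  })
  pb$stage <- "quantile"
  pb
}

#' Write per-cluster pseudobulk matrices as CSV
#'
#' @param pb a `pseudobulk_set`.
#' @param dir output directory; one `pseudobulk_<cluster>_<stage>.csv` per
#'   cluster (genes x samples).
#' @return `dir`, invisibly.
#' @export
write_pseudobulk <- function(pb, dir) {
  stopifnot(inherits(pb, "pseudobulk_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(pb$matrices)) {
    f <- file.path(dir, sprintf("pseudobulk_%s_%s.csv", cl, pb$stage))
    write.csv(data.frame(gene = rownames(pb$matrices[[cl]]), pb$matrices[[cl]],
                         check.names = FALSE), f, row.names = FALSE)
  }
  invisible(dir)
}
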