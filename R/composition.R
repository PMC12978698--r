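# Cell-type composition analysis on arcsine-square-root transformed
# per-sample proportions, with covariate-adjusted group tests and trait
# correlations.

#' Per-sample cell-type proportions
#'
#' @param cell_meta data.frame with `sample_id` and `cluster`.
#' @return samples x clusters matrix of proportions (rows sum to 1).
#' @export
cell_type_proportions <- function(cell_meta) {
  tab <- table(cell_meta$sample_id, cell_meta$cluster)
  sweep(unclass(tab), 1, rowSums(tab), `/`)
}

#' Arcsine square root transform of proportions
#'
#' `y = asin(sqrt(p))`, mapping \[0, 1\] to \[0, pi/2\].
#'
#' @param proportions numeric vector/matrix of proportions in \[0, 1\].
#' @return transformed values.
#' @export
asin_sqrt_transform <- function(proportions) {
  if (any(proportions < 0 | proportions > 1, na.rm = TRUE))
    stopf("proportions must lie in [0, 1]")
  asin(sqrt(proportions))
}

#' Covariate-adjusted test of composition differences between groups
#'
#' Linear model of the transformed proportion on the group factor plus
#' covariates; two-sided t-test on the group coefficient for two groups, the
#' ANOVA F-test on the group factor for more.
#'
#' @param transformed named numeric vector (per sample) of arcsine-sqrt
#'   proportions for one cluster.
#' @param grouping factor/character per sample.
#' @param covariates optional data.frame of per-sample covariates (e.g. sex,
#'   batch), rownames or order matching `transformed`.
#' @return one-row data.frame with `statistic`, `df`, `p`, `estimate` (group
#'   effect for the two-group case).
#' @export
composition_test <- function(transformed, grouping, covariates = NULL) {
  grouping <- factor(grouping)
  if (nlevels(grouping) < 2) stopf("need >= 2 groups")
  if (min(table(grouping)) < 3) stopf("need >= 3 samples per group")
  dat <- data.frame(y = as.numeric(transformed), grp = grouping)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- vapply(covariates, function(cc) length(unique(cc)) > 1, logical(1))
    dat <- cbind(dat, covariates[, keep, drop = FALSE])
  }
  # confounding check: the group indicators must not lie in the span of the
  # covariate design
  if (!is.null(covariates) && ncol(dat) > 2) {
    C <- stats::model.matrix(~ ., data = dat[, -(1:2), drop = FALSE])
    G <- stats::model.matrix(~ grp, data = dat)[, -1, drop = FALSE]
    resid_g <- G - C %*% qr.coef(qr(C), G)
    resid_g[is.na(resid_g)] <- 0
    if (max(abs(resid_g)) < 1e-8) stopf("grouping is confounded with covariates")
  }
  fit <- lm(y ~ ., data = dat)
  if (anyNA(coef(fit)[grep("^grp", names(coef(fit)))]))
    stopf("grouping is confounded with covariates")
  if (nlevels(grouping) == 2) {
    sm <- summary(fit)$coefficients
    row <- grep("^grp", rownames(sm))[1]
    data.frame(statistic = sm[row, "t value"], df = fit$df.residual,
               p = sm[row, "Pr(>|t|)"], estimate = sm[row, "Estimate"])
  } else {
    an <- anova(fit)
    data.frame(statistic = an["grp", "F value"], df = an["grp", "Df"],
               p = an["grp", "Pr(>F)"], estimate = NA_real_)
  }
}

#' Correlate transformed cell-type proportions with sample traits
#'
#' Pearson correlation per (cluster, trait) with BH adjustment within each
#' trait family.
#'
#' @param transformed samples x clusters matrix of arcsine-sqrt proportions.
#' @param traits samples x traits data.frame (numeric), rows matching.
#' @return data.frame (`cluster`, `trait`, `r`, `p`, `p_adj`).
#' @export
trait_correlation <- function(transformed, traits) {
  traits <- as.data.frame(traits)
  rows <- list()
  for (tr in names(traits)) {
    v <- traits[[tr]]
    if (length(unique(v[!is.na(v)])) < 2) {
      message(sprintf("trait %s is constant; skipped", tr))
      next
    }
    for (cl in colnames(transformed)) {
      x <- transformed[, cl]
      ok <- is.finite(x) & is.finite(v)
      if (sum(ok) < 3) next
      ct <- cor.test(x[ok], v[ok])
      rows[[paste(tr, cl)]] <- data.frame(cluster = cl, trait = tr,
                                          r = unname(ct$estimate), p = ct$p.value)
    }
  }
  if (!length(rows))
    return(data.frame(cluster = character(0), trait = character(0),
                      r = numeric(0), p = numeric(0), p_adj = numeric(0)))
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  for (tr in unique(out$trait))
    out$p_adj[out$trait == tr] <- bh_adjust(out$p[out$trait == tr])
  rownames(out) <- NULL
  out
}
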