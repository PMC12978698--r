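# Founder-haplotype eQTL scan: at each marker, LOD compares the linear model
# expression ~ covariates + founder dosages against covariates alone,
# LOD = (n/2) log10(RSS0/RSS1). Founder effects are reported sum-to-zero.

build_covariate_matrix <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(matrix(1, 1, 1))  # placeholder, handled by caller
  mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[setdiff(seq_len(ncol(mm)), qr_$pivot[seq_len(qr_$rank)])]
    stopf("rank-deficient covariates; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }
  mm
}

#' Haplotype-regression LOD scan for one gene
#'
#' At each marker fits H1: expression ~ covariates + founder dosages (one
#' founder dropped for identifiability; effects reported sum-to-zero) and
#' H0: covariates only, by least squares; `LOD = (n/2) log10(RSS0/RSS1)`.
#'
#' @param expr_vector named expression vector (names are sample ids).
#' @param genotypes a `founder_genotypes` object.
#' @param covariates data.frame of per-sample covariates (rows matching
#'   `expr_vector`), or NULL for intercept-only.
#' @param min_samples minimum complete samples.
#' @return data.frame per marker: `marker`, `chrom`, `pos`, `lod`, plus an
#'   attached `founder_effects` attribute (markers x founders, sum-to-zero)
#'   for the peak marker via [scan_peak()].
#' @export
scan_gene <- function(expr_vector, genotypes, covariates = NULL,
                      min_samples = 20) {
  samples <- names(expr_vector)
  if (is.null(samples)) stopf("expr_vector must be named by sample id")
  samples <- intersect(samples, dimnames(genotypes$dosage)[[1]])
  y <- expr_vector[samples]
  if (length(y) < min_samples) stopf("need >= %d samples, have %d", min_samples,
                                     length(y))
  X0 <- if (is.null(covariates)) matrix(1, length(y), 1) else
    build_covariate_matrix(covariates[match(samples, rownames(covariates)), ,
                                      drop = FALSE])
  scan_core(y, X0, genotypes, samples)
}

scan_core <- function(y, X0, genotypes, samples) {
  n <- length(y)
  fit0 <- lm.fit(X0, y)
  rss0 <- sum(fit0$residuals^2)
  nf <- dim(genotypes$dosage)[3]
  map <- genotypes$marker_map
  lod <- numeric(nrow(map))
  eff <- matrix(NA_real_, nrow(map), nf,
                dimnames = list(map$marker, dimnames(genotypes$dosage)[[3]]))
  for (j in seq_len(nrow(map))) {
    D <- genotypes$dosage[samples, j, , drop = TRUE]
    X1 <- cbind(X0, D[, -nf, drop = FALSE])
    f1 <- lm.fit(X1, y)
    rss1 <- sum(f1$residuals^2)
    lod[j] <- (n / 2) * log10(max(rss0, 1e-300) / max(rss1, 1e-300))
    b <- f1$coefficients[(ncol(X0) + 1):ncol(X1)]
    b[is.na(b)] <- 0
    b8 <- c(b, 0)
    eff[j, ] <- b8 - mean(b8)
  }
  out <- data.frame(marker = map$marker, chrom = map$chrom, pos = map$pos,
                    lod = lod)
  attr(out, "founder_effects") <- eff
  out
}

#' Peak of a LOD curve
#'
#' @param scan output of [scan_gene()].
#' @return one-row data.frame: peak marker, chrom, pos, lod, and the
#'   sum-to-zero founder-effect vector as columns `effect_<founder>`.
#' @export
scan_peak <- function(scan) {
  i <- which.max(scan$lod)
  eff <- attr(scan, "founder_effects")[i, ]
  out <- scan[i, c("marker", "chrom", "pos", "lod")]
  for (f in names(eff)) out[[paste0("effect_", f)]] <- unname(eff[f])
  rownames(out) <- NULL
  out
}

#' Permutation LOD significance threshold
#'
#' Per cluster, `n_genes` random genes are scanned under `n_perm`
#' permutations of the expression vector (covariates refit each time); each
#' gene's threshold is the `quantile` of its genome-wide max-LOD permutation
#' distribution; the cluster value is the median over genes and the final
#' threshold the mean over clusters.
#'
#' @param pb a `pseudobulk_set` (any normalized stage).
#' @param genotypes a `founder_genotypes`.
#' @param covariates per-sample covariate data.frame (rownames = sample id).
#' @param n_genes genes sampled per cluster.
#' @param n_perm permutations per gene.
#' @param quantile_level quantile of the max-LOD null distribution.
#' @param seed integer seed.
#' @return list with `threshold`, `per_cluster` (named medians), and
#'   `per_gene` thresholds.
#' @export
permutation_threshold <- function(pb, genotypes, covariates = NULL,
                                  n_genes = 50, n_perm = 1000,
                                  quantile_level = 0.95, seed = 1) {
  stopifnot(inherits(pb, "pseudobulk_set"))
  with_seed(child_seed(seed, "permthr"), {
    per_cluster <- c()
    per_gene <- list()
    for (cl in names(pb$matrices)) {
      m <- pb$matrices[[cl]]
      if (!ncol(m)) next
      gs <- rownames(m)
      if (length(gs) < n_genes) {
        warnf("cluster '%s' has %d < %d genes; using all", cl, length(gs), n_genes)
        pick <- gs
      } else pick <- sample(gs, n_genes)
      samples <- intersect(colnames(m), dimnames(genotypes$dosage)[[1]])
      X0 <- if (is.null(covariates)) matrix(1, length(samples), 1) else
        build_covariate_matrix(covariates[match(samples, rownames(covariates)), ,
                                          drop = FALSE])
      # precompute per-marker QR for the permutation batch
      thr <- vapply(pick, function(g) {
        y <- m[g, samples]
        perms <- replicate(n_perm, sample(y))
        maxlod <- perm_max_lod(perms, X0, genotypes, samples)
        unname(quantile(maxlod, quantile_level))
      }, numeric(1))
      per_gene[[cl]] <- thr
      per_cluster[cl] <- median(thr)
    }
    list(threshold = mean(per_cluster), per_cluster = per_cluster,
         per_gene = per_gene)
  })
}

# Vectorized genome-wide max LOD for a matrix of (permuted) response vectors.
perm_max_lod <- function(Y, X0, genotypes, samples) {
  n <- nrow(Y)
  q0 <- qr.Q(qr(X0))
  rss0 <- colSums(Y^2) - colSums(crossprod(q0, Y)^2)
  nmark <- nrow(genotypes$marker_map)
  nf <- dim(genotypes$dosage)[3]
  maxlod <- rep(-Inf, ncol(Y))
  for (j in seq_len(nmark)) {
    X1 <- cbind(X0, genotypes$dosage[samples, j, -nf, drop = TRUE])
    q1 <- qr.Q(qr(X1))
    rss1 <- colSums(Y^2) - colSums(crossprod(q1, Y)^2)
    lod <- (n / 2) * log10(pmax(rss0, 1e-300) / pmax(rss1, 1e-300))
    maxlod <- pmax(maxlod, lod)
  }
  maxlod
}

#' Genome-wide eQTL scan of a pseudobulk cluster and cis calling
#'
#' Scans every gene of each cluster matrix, takes the genome-wide peak and
#' retains genes whose peak LOD reaches the threshold and whose peak marker
#' lies on the gene's chromosome within `cis_window` of its TSS.
#'
#' @param pb a `pseudobulk_set`.
#' @param genotypes a `founder_genotypes`.
#' @param gene_annot data.frame with `symbol`, `chrom`, `tss_pos`.
#' @param covariates per-sample covariates (rownames = sample ids).
#' @param threshold LOD significance threshold (e.g. from
#'   [permutation_threshold()]).
#' @param cis_window maximum TSS distance in bp (inclusive).
#' @param genes optional gene subset.
#' @param min_samples clusters with fewer genotyped samples are skipped with
#'   a warning.
#' @return data.frame of cis-eQTL peaks (`gene`, `cluster`, `marker`, `lod`,
#'   founder effects, `cis`, `threshold_used`); attribute `all_peaks` keeps
#'   every scanned peak.
#' @export
call_cis_eqtl <- function(pb, genotypes, gene_annot, covariates = NULL,
                          threshold, cis_window = 1e6, genes = NULL,
                          min_samples = 20) {
  stopifnot(inherits(pb, "pseudobulk_set"))
  peaks <- list()
  for (cl in names(pb$matrices)) {
    m <- pb$matrices[[cl]]
    if (!ncol(m)) next
    n_geno <- length(intersect(colnames(m), dimnames(genotypes$dosage)[[1]]))
    if (n_geno < min_samples) {
      warnf("cluster '%s' has %d genotyped samples (< %d); eQTL scan skipped",
            cl, n_geno, min_samples)
      next
    }
    gs <- intersect(genes %||% rownames(m), rownames(m))
    for (g in gs) {
      ann <- gene_annot[gene_annot$symbol == g, , drop = FALSE]
      if (!nrow(ann) || is.na(ann$tss_pos[1])) {
        message(sprintf("gene %s has no TSS annotation; skipped", g))
        next
      }
      y <- m[g, ]
      names(y) <- colnames(m)
      sc <- scan_gene(y, genotypes, covariates, min_samples = min_samples)
      pk <- scan_peak(sc)
      pk$gene <- g
      pk$cluster <- cl
      pk$cis <- pk$chrom == ann$chrom[1] & abs(pk$pos - ann$tss_pos[1]) <= cis_window
      pk$threshold_used <- threshold
      peaks[[length(peaks) + 1]] <- pk
    }
  }
  allp <- if (length(peaks)) do.call(rbind, peaks) else
    data.frame(gene = character(0), cluster = character(0), lod = numeric(0),
               cis = logical(0))
  out <- allp[!is.na(allp$lod) & allp$lod >= threshold & allp$cis, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_peaks") <- allp
  out
}

#' Founder-carrier sample partition at a marker
#'
#' Carriers are samples whose dosage of the founder at the marker is at least
#' `dosage_min` (0.5 approximates "at least one allele").
#'
#' @param genotypes a `founder_genotypes`.
#' @param marker marker name.
#' @param founder founder label.
#' @param dosage_min carrier dosage threshold (inclusive).
#' @return list with `carriers` and `rest` sample id vectors.
#' @export
carrier_groups <- function(genotypes, marker, founder, dosage_min = 0.5) {
  if (!marker %in% dimnames(genotypes$dosage)[[2]]) stopf("unknown marker '%s'", marker)
  if (!founder %in% dimnames(genotypes$dosage)[[3]]) stopf("unknown founder '%s'", founder)
  d <- genotypes$dosage[, marker, founder]
  carriers <- names(d)[d >= dosage_min]
  if (!length(carriers)) warnf("no carriers of founder %s at %s", founder, marker)
  list(carriers = carriers, rest = setdiff(names(d), carriers))
}
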