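# Synthetic-population generator. Counts are negative binomial with
# mean mu_gc = s_c * exp(eta_gc); eta stacks a gene baseline, cluster-marker
# boosts, a sigmoid in pseudotime for dynamic genes, a sample-level
# linear-Gaussian SEM latent for module genes, and a founder-dosage eQTL term.

#' Simulate founder haplotype genotypes
#'
#' Each sample carries two founder haplotypes per chromosome, drawn as a
#' Markov chain along markers (uniform start, switch to a uniformly chosen
#' other founder with probability `switch_prob` per interval). The dosage at a
#' marker is the count of each founder among the two haplotypes, an 8-vector
#' summing to 2 (diploid).
#'
#' @param config a [sim_config()].
#' @return object of class `founder_genotypes`: list with `dosage`
#'   (samples x markers x founders array), `marker_map` (marker, chrom, pos)
#'   and `founder_labels`.
#' @export
simulate_genotypes <- function(config) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, "genotypes"), simulate_genotypes_impl(config))
}

simulate_genotypes_impl <- function(config) {
  nf <- config$founders
  nm <- config$n_mice
  nmark <- config$n_markers_per_chrom
  samples <- sprintf("DO%03d", seq_len(nm))
  maps <- lapply(seq_len(config$n_chromosomes), function(ch) {
    data.frame(
      marker = sprintf("chr%d_m%02d", ch, seq_len(nmark)),
      chrom = paste0("chr", ch),
      pos = round(seq(2e6, config$chrom_length - 2e6, length.out = nmark))
    )
  })
  marker_map <- do.call(rbind, maps)
  dosage <- array(0, dim = c(nm, nrow(marker_map), nf),
                  dimnames = list(samples, marker_map$marker, LETTERS[seq_len(nf)]))
  draw_hap <- function() {
    h <- integer(nmark)
    h[1] <- sample.int(nf, 1)
    for (j in 2:nmark) {
      h[j] <- if (runif(1) < config$switch_prob) {
        sample(setdiff(seq_len(nf), h[j - 1]), 1)
      } else h[j - 1]
    }
    h
  }
  for (s in seq_len(nm)) {
    off <- 0L
    for (ch in seq_len(config$n_chromosomes)) {
      h1 <- draw_hap(); h2 <- draw_hap()
      for (j in seq_len(nmark)) {
        dosage[s, off + j, h1[j]] <- dosage[s, off + j, h1[j]] + 1
        dosage[s, off + j, h2[j]] <- dosage[s, off + j, h2[j]] + 1
      }
      off <- off + nmark
    }
  }
  structure(list(dosage = dosage, marker_map = marker_map,
                 founder_labels = LETTERS[seq_len(nf)]),
            class = "founder_genotypes")
}

#' @export
print.founder_genotypes <- function(x, ...) {
  cat(sprintf("<founder_genotypes> %d samples x %d markers x %d founders\n",
              dim(x$dosage)[1], dim(x$dosage)[2], dim(x$dosage)[3]))
  invisible(x)
}

#' Random banded module DAG
#'
#' Nodes in topological order, each non-root drawing 1-2 parents from the
#' `window` immediately preceding nodes. Local attachment keeps the graph
#' deep, so radius-3 neighborhoods are proper subgraphs of the module.
#'
#' @param genes node names in topological order.
#' @param weight_range magnitude range of edge weights.
#' @param neg_prob probability an edge weight is negative.
#' @param window how many preceding nodes are candidate parents.
#' @return data.frame with columns `parent`, `child`, `weight`.
#' @export
make_module_dag <- function(genes, weight_range = c(0.5, 1), neg_prob = 0,
                            window = 4) {
  p <- length(genes)
  edges <- list()
  for (j in 2:p) {
    lo <- max(1, j - window)
    cand <- lo:(j - 1)
    npar <- min(length(cand), sample(1:2, 1))
    pars <- if (length(cand) == 1) cand else sample(cand, npar)
    edges[[j - 1]] <- data.frame(parent = genes[pars], child = genes[j])
  }
  dag <- do.call(rbind, edges)
  sgn <- ifelse(runif(nrow(dag)) < neg_prob, -1, 1)
  dag$weight <- sgn * runif(nrow(dag), weight_range[1], weight_range[2])
  dag
}

#' Sample a linear-Gaussian structural equation model
#'
#' Root nodes are N(0, 1); each child is the weighted sum of its parents plus
#' N(0, `noise_sd`^2) noise. Used both to drive the sample-level module signal
#' of the synthetic population and as a stand-alone generator for Bayesian
#' network recovery tests.
#'
#' @param dag data.frame with columns `parent`, `child` and optionally
#'   `weight` (defaults drawn from +/-\[0.5, 1\]).
#' @param n number of independent samples.
#' @param noise_sd child noise standard deviation.
#' @param standardize rescale every node to unit sample variance as it is
#'   generated, so correlations do not saturate along deep descent chains
#'   (the conditional-independence structure is unchanged).
#' @return numeric matrix, `n` rows by one column per node.
#' @export
sem_sample <- function(dag, n, noise_sd = 0.5, standardize = TRUE) {
  nodes <- unique(c(dag$parent, dag$child))
  if (is.null(dag$weight)) dag$weight <- runif(nrow(dag), 0.5, 1)
  g <- igraph::graph_from_data_frame(dag[c("parent", "child")], directed = TRUE,
                                     vertices = nodes)
  if (!igraph::is_dag(g)) stopf("module DAG contains a cycle")
  ord <- nodes[igraph::topo_sort(g)]
  x <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  for (nd in ord) {
    inc <- dag[dag$child == nd, , drop = FALSE]
    if (nrow(inc) == 0) {
      x[, nd] <- rnorm(n)
    } else {
      v <- x[, inc$parent, drop = FALSE] %*% inc$weight + rnorm(n, sd = noise_sd)
      if (standardize && sd(v) > 0) v <- v / sd(v)
      x[, nd] <- v
    }
  }
  x
}

#' Plant a driver hub in a module DAG
#'
#' Chooses the node with the largest undirected radius-3 neighborhood and
#' augments it with a few extra local edges on both flanks (extra direct
#' targets four and six positions away), making the driver a structurally
#' distinctive hub whose neighborhood robustly exceeds the size filter of
#' downstream neighborhood analysis.
#'
#' @param dag module DAG (data.frame parent/child/weight).
#' @param genes module gene vector in topological order.
#' @param weight_range magnitude range of the added edge weights.
#' @return list with `dag` (augmented) and `driver`.
#' @export
plant_module_driver <- function(dag, genes, weight_range = c(0.6, 1)) {
  sizes <- vapply(genes, function(g) length(radius_neighborhood(dag, g)),
                  integer(1))
  drv <- names(which.max(sizes))
  j <- match(drv, genes)
  p <- length(genes)
  fw <- genes[intersect(c(j + 4, j + 6), seq_len(p))]
  bw <- genes[intersect(c(j - 4, j - 6), seq_len(p))]
  extra <- rbind(
    if (length(fw)) data.frame(parent = drv, child = fw,
                               weight = runif(length(fw), weight_range[1],
                                              weight_range[2])),
    if (length(bw)) data.frame(parent = bw, child = drv,
                               weight = runif(length(bw), weight_range[1],
                                              weight_range[2])))
  if (!is.null(extra)) {
    extra <- extra[!paste(extra$parent, extra$child) %in%
                     paste(dag$parent, dag$child), , drop = FALSE]
    dag <- rbind(dag, extra)
  }
  rownames(dag) <- NULL
  list(dag = dag, driver = drv)
}

radius_neighborhood <- function(dag, focal, order = 3) {
  nodes <- unique(c(dag$parent, dag$child))
  g <- igraph::graph_from_data_frame(dag[c("parent", "child")], directed = TRUE,
                                     vertices = nodes)
  nb <- igraph::ego(g, order = order, nodes = focal, mode = "all")[[1]]
  names(nb)
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Simulate a single-cell population with planted ground truth
#'
#' Generates UMI counts, sample covariates, founder genotypes and the full
#' ground truth (clusters, pseudotime, module DAGs, planted drivers, dynamic
#' genes, eQTL effects, a synthetic colocalization gene list) under the
#' configured study design. The returned latent space holds each cell's
#' position on its trajectory segment plus isotropic noise, padded with noise
#' dimensions; trajectory inference on it should recover the planted paths.
#'
#' @param config a [sim_config()].
#' @return list with elements `counts` ([cell_counts()]), `samples`
#'   (covariate data.frame), `genotypes` ([simulate_genotypes()] output),
#'   `truth` (class `ground_truth`) and `latent_space` (cells x
#'   `n_latent_dims` matrix).
#' @export
simulate_population <- function(config) {
  validate_sim_config(config)
  genotypes <- simulate_genotypes(config)
  with_seed(child_seed(config$seed, "population"),
            simulate_population_impl(config, genotypes))
}

simulate_population_impl <- function(cfg, genotypes) {
  lineages <- topology_lineages(cfg)
  layout <- topology_layout(cfg)
  clusters <- names(layout$segments)
  n_clusters <- length(clusters)
  nm <- cfg$n_mice
  samples <- sprintf("DO%03d", seq_len(nm))

  ## ---- gene catalogue -------------------------------------------------
  module_ids <- paste0("M", seq_len(cfg$n_modules))
  module_genes <- lapply(module_ids, function(m)
    sprintf("%s.g%02d", m, seq_len(cfg$module_size)))
  names(module_genes) <- module_ids
  # module DAGs with a planted hub driver; the driver's radius-3 ball is the
  # module's seeded dynamic-gene program
  module_dag <- list()
  planted_drivers <- character(0)
  driver_balls <- list()
  for (m in module_ids) {
    pd <- plant_module_driver(
      make_module_dag(module_genes[[m]], cfg$sem_weight_range,
                      cfg$sem_neg_weight_prob),
      module_genes[[m]])
    module_dag[[m]] <- pd$dag
    planted_drivers[m] <- pd$driver
    driver_balls[[m]] <- radius_neighborhood(pd$dag, pd$driver)
  }
  n_seeded <- if (cfg$n_dynamic_genes > 0) sum(lengths(driver_balls)) else 0
  n_free_dyn <- max(0, cfg$n_dynamic_genes - n_seeded)
  free_dyn <- if (n_free_dyn) sprintf("Dyn%03d", seq_len(n_free_dyn)) else character()
  marker_genes <- unlist(lapply(clusters, function(cl)
    sprintf("Mk.%s.%d", cl, seq_len(cfg$n_marker_genes_per_cluster))))
  eqtl_genes <- if (cfg$n_eqtl_genes) sprintf("Eq%03d", seq_len(cfg$n_eqtl_genes)) else character()
  n_mito <- round(cfg$frac_mito * cfg$n_noise_genes)
  n_rpl <- round(cfg$frac_rpl * cfg$n_noise_genes)
  n_rps <- round(cfg$frac_rps * cfg$n_noise_genes)
  n_plain <- cfg$n_noise_genes - n_mito - n_rpl - n_rps
  noise_genes <- c(if (n_mito) sprintf("mt-Sim%02d", seq_len(n_mito)),
                   if (n_rpl) sprintf("Rpl%02d", seq_len(n_rpl)),
                   if (n_rps) sprintf("Rps%02d", seq_len(n_rps)),
                   if (n_plain) sprintf("Ns%03d", seq_len(n_plain)))
  genes <- c(unname(unlist(module_genes)), free_dyn, marker_genes, eqtl_genes,
             noise_genes)
  ngene <- length(genes)

  ## ---- gene annotation (synthetic genome) -----------------------------
  marker_map <- genotypes$marker_map
  gene_meta <- data.frame(
    symbol = genes,
    chrom = sample(paste0("chr", seq_len(cfg$n_chromosomes)), ngene, replace = TRUE),
    tss_pos = round(runif(ngene, 1e6, cfg$chrom_length - 1e6))
  )
  # cis-eQTL genes sit within 0.5 Mbp of their causal marker's position
  eqtl_marker_idx <- if (cfg$n_eqtl_genes)
    sample(nrow(marker_map), cfg$n_eqtl_genes, replace = FALSE) else integer()
  eqtl_truth <- NULL
  if (cfg$n_eqtl_genes) {
    gi <- match(eqtl_genes, gene_meta$symbol)
    gene_meta$chrom[gi] <- marker_map$chrom[eqtl_marker_idx]
    gene_meta$tss_pos[gi] <- pmax(1, round(
      marker_map$pos[eqtl_marker_idx] +
        sample(c(-1, 1), cfg$n_eqtl_genes, TRUE) * runif(cfg$n_eqtl_genes, 0, 5e5)))
    eqtl_truth <- data.frame(
      gene = eqtl_genes,
      marker = marker_map$marker[eqtl_marker_idx],
      chrom = marker_map$chrom[eqtl_marker_idx],
      founder = sample(genotypes$founder_labels, cfg$n_eqtl_genes, replace = TRUE),
      effect = sample(c(-1, 1), cfg$n_eqtl_genes, TRUE) * cfg$eqtl_effect_sd
    )
  } else {
    eqtl_truth <- data.frame(gene = character(), marker = character(),
                             chrom = character(), founder = character(),
                             effect = numeric())
  }

  ## ---- dynamic genes ---------------------------------------------------
  dyn_rows <- list()
  if (cfg$n_dynamic_genes > 0) {
    # each module's seeded dynamic genes (the driver's radius-3 ball) share
    # one (lineage, boundary cluster)
    mod_lineage <- sample(names(lineages), cfg$n_modules, replace = TRUE)
    for (i in seq_along(module_ids)) {
      m <- module_ids[i]
      picked <- driver_balls[[m]]
      lin <- mod_lineage[i]
      bcl <- sample(lineages[[lin]], 1)
      dyn_rows[[m]] <- data.frame(gene = picked, lineage = lin, boundary = bcl)
    }
    if (n_free_dyn) {
      lin <- sample(names(lineages), n_free_dyn, replace = TRUE)
      bcl <- vapply(lin, function(l) sample(lineages[[l]], 1), character(1))
      dyn_rows[["free"]] <- data.frame(gene = free_dyn, lineage = lin, boundary = bcl)
    }
  }
  dynamic_genes <- if (length(dyn_rows)) do.call(rbind, dyn_rows) else
    data.frame(gene = character(), lineage = character(), boundary = character())
  rownames(dynamic_genes) <- NULL
  if (nrow(dynamic_genes)) {
    dynamic_genes$l2fc <- sample(c(-1, 1), nrow(dynamic_genes), TRUE) *
      runif(nrow(dynamic_genes), cfg$dynamic_l2fc_range[1], cfg$dynamic_l2fc_range[2])
    len <- layout$seg_len
    dynamic_genes$t0 <- layout$t_start[dynamic_genes$boundary] +
      len * runif(nrow(dynamic_genes), 0.35, 0.65)
    dynamic_genes$tau <- len / 7
  }

  ## ---- sample covariates ----------------------------------------------
  sample_tab <- data.frame(
    sample_id = samples,
    sex = sample(c("F", "M"), nm, replace = TRUE),
    age_days = sample(80:120, nm, replace = TRUE),
    weight = round(rnorm(nm, 25, 3), 1),
    length = round(rnorm(nm, 9.5, 0.5), 1),
    generation = sample(c("G33", "G34", "G35"), nm, replace = TRUE),
    batch = rep(c("batch1", "batch2"), length.out = nm),
    trait_BMD = round(rnorm(nm, 50, 5), 2),
    trait_strength = round(rnorm(nm, 20, 3), 2)
  )

  ## ---- cells: cluster, pseudotime, latent space -----------------------
  base_props <- c(MPC = 0.18, LMP = 0.22, OBP = 0.16, OB1 = 0.13, OB2 = 0.10,
                  Ocy = 0.08, MALP = 0.13)
  props <- if (all(clusters %in% names(base_props))) base_props[clusters] else
    setNames(rep(1 / n_clusters, n_clusters), clusters)
  cell_rows <- list()
  for (s in seq_len(nm)) {
    alpha <- 60 * props / sum(props)
    pr <- rgamma(n_clusters, shape = alpha); pr <- pr / sum(pr)
    cl <- sample(clusters, cfg$n_cells_per_mouse, replace = TRUE, prob = pr)
    cell_rows[[s]] <- data.frame(sample_id = samples[s], cluster = cl)
  }
  cells <- do.call(rbind, cell_rows)
  ncell <- nrow(cells)
  cells$cell_id <- sprintf("cell%05d", seq_len(ncell))
  cells$batch <- sample_tab$batch[match(cells$sample_id, sample_tab$sample_id)]
  u <- runif(ncell)
  cells$pseudotime <- layout$t_start[cells$cluster] + u * layout$seg_len
  latent <- matrix(rnorm(ncell * cfg$n_latent_dims, sd = cfg$latent_noise_sd),
                   ncell, cfg$n_latent_dims)
  for (cl in clusters) {
    idx <- which(cells$cluster == cl)
    seg <- layout$segments[[cl]]
    pos <- outer(rep(1, length(idx)), seg$start) +
      outer(u[idx], seg$end - seg$start)
    latent[idx, seq_len(layout$ndim)] <- latent[idx, seq_len(layout$ndim)] + pos
  }
  rownames(latent) <- cells$cell_id

  # which lineages contain each cluster; divergence time of a cluster from a
  # lineage = pseudotime at which its own path leaves the lineage's path
  lineage_of <- lapply(lineages, function(p) clusters %in% p)

  ## ---- eta assembly ----------------------------------------------------
  base <- rnorm(ngene, log(2), 0.8)
  names(base) <- genes
  base[grepl("^mt-", genes)] <- base[grepl("^mt-", genes)] + 1.2
  base[grepl("^Rpl", genes)] <- base[grepl("^Rpl", genes)] + 1.6
  base[grepl("^Rps", genes)] <- base[grepl("^Rps", genes)] + 1.4

  eta <- matrix(rep(base, ncell), ngene, ncell,
                dimnames = list(genes, cells$cell_id))
  # cluster markers
  for (cl in clusters) {
    mk <- sprintf("Mk.%s.%d", cl, seq_len(cfg$n_marker_genes_per_cluster))
    eta[mk, cells$cluster == cl] <- eta[mk, cells$cluster == cl] + 1.5
  }
  # dynamic genes: sigmoid along the assigned lineage; off-lineage cells are
  # evaluated at the pseudotime where their path diverges from that lineage
  if (nrow(dynamic_genes)) {
    for (r in seq_len(nrow(dynamic_genes))) {
      lin_path <- lineages[[dynamic_genes$lineage[r]]]
      on_lin <- cells$cluster %in% lin_path
      t_eff <- cells$pseudotime
      if (any(!on_lin)) {
        # divergence pseudotime: end of the deepest shared ancestor segment
        div_t <- vapply(clusters, function(cl) {
          anc <- ancestors_on_path(cfg, cl)
          shared <- intersect(anc, lin_path)
          if (!length(shared)) 0 else max(layout$t_start[shared]) + layout$seg_len
        }, numeric(1))
        t_eff[!on_lin] <- pmin(t_eff[!on_lin], div_t[cells$cluster[!on_lin]])
      }
      eta[dynamic_genes$gene[r], ] <- eta[dynamic_genes$gene[r], ] +
        dynamic_genes$l2fc[r] * log(2) *
          logistic((t_eff - dynamic_genes$t0[r]) / dynamic_genes$tau[r])
    }
  }
  # module signal: one SEM draw per mouse, standardized across mice, shared by
  # all cells of the mouse so pseudobulk correlations reflect the DAG
  for (m in module_ids) {
    z <- sem_sample(module_dag[[m]], nm, cfg$sem_noise_sd)
    z <- scale(z)[, module_genes[[m]], drop = FALSE]
    rho <- cfg$module_factor_rho
    z <- sqrt(rho) * rnorm(nm) + sqrt(1 - rho) * z
    rownames(z) <- samples
    eta[module_genes[[m]], ] <- eta[module_genes[[m]], ] +
      cfg$module_amp * t(z[cells$sample_id, , drop = FALSE])
  }
  # eQTL: founder-dosage dot product, constant within mouse
  if (nrow(eqtl_truth)) {
    for (r in seq_len(nrow(eqtl_truth))) {
      dos <- genotypes$dosage[, eqtl_truth$marker[r], eqtl_truth$founder[r]]
      eta[eqtl_truth$gene[r], ] <- eta[eqtl_truth$gene[r], ] +
        eqtl_truth$effect[r] * dos[cells$sample_id]
    }
  }

  ## ---- size factors and QC outliers -----------------------------------
  sf <- rlnorm(ncell, -0.03, 0.25)
  sf[cells$batch == "batch2"] <- sf[cells$batch == "batch2"] * 1.15
  n_out <- round(cfg$qc_outlier_frac * ncell)
  outlier_kind <- character(0)
  if (n_out > 0) {
    out_idx <- sample.int(ncell, n_out)
    kind <- rep(c("low_lib", "high_lib", "high_mito"), length.out = n_out)
    sf[out_idx[kind == "low_lib"]] <- 0.06
    sf[out_idx[kind == "high_lib"]] <- 5
    mito_rows <- grepl("^mt-", genes)
    hi <- out_idx[kind == "high_mito"]
    if (length(hi) && any(mito_rows)) eta[mito_rows, hi] <- eta[mito_rows, hi] + 2.5
    outlier_kind <- setNames(kind, cells$cell_id[out_idx])
  }

  ## ---- draw counts -----------------------------------------------------
  mu <- sweep(exp(eta), 2, sf, `*`)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$nb_dispersion),
                   ngene, ncell, dimnames = dimnames(mu))
  cc <- cell_counts(counts, gene_meta = gene_meta,
                    cell_meta = cells[c("cell_id", "sample_id", "cluster", "batch")])

  ## ---- pseudotime per lineage + coloc list ----------------------------
  pt <- matrix(NA_real_, ncell, length(lineages),
               dimnames = list(cells$cell_id, names(lineages)))
  for (l in names(lineages))
    pt[cells$cluster %in% lineages[[l]], l] <-
      cells$pseudotime[cells$cluster %in% lineages[[l]]]

  tissues <- c("Adipose (visceral)", "Testis", "Liver", "Pituitary",
               "Nerve (tibial)", "Spleen", "Pancreas")
  coloc_pool <- c(unname(planted_drivers),
                  sample(setdiff(genes, planted_drivers), min(10, ngene)))
  coloc_genes <- data.frame(
    gene = coloc_pool,
    modality = sample(c("eQTL", "sQTL"), length(coloc_pool), replace = TRUE),
    tissue = sample(tissues, length(coloc_pool), replace = TRUE),
    score = round(runif(length(coloc_pool), 0.1, 1), 4)
  )

  truth <- structure(list(
    cell_cluster = setNames(cells$cluster, cells$cell_id),
    cell_pseudotime = pt,
    lineages = lineages,
    module_membership = setNames(rep(module_ids, each = cfg$module_size),
                                 unlist(module_genes)),
    module_dag = module_dag,
    planted_drivers = planted_drivers,
    dynamic_genes = dynamic_genes,
    eqtl_truth = eqtl_truth,
    coloc_genes = coloc_genes,
    qc_outliers = outlier_kind,
    t_start = layout$t_start,
    seg_len = layout$seg_len
  ), class = "ground_truth")

  list(counts = cc, samples = sample_tab, genotypes = genotypes, truth = truth,
       latent_space = latent)
}

# clusters on the path from root to (and including) `cl`
ancestors_on_path <- function(cfg, cl) {
  topo <- cfg$cluster_topology
  path <- cl
  while (cl %in% topo$child) {
    cl <- topo$parent[match(cl, topo$child)]
    path <- c(cl, path)
  }
  path
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(paste0("<ground_truth> %d cells, %d lineages, %d modules, ",
                     "%d dynamic genes, %d eQTL genes\n"),
              length(x$cell_cluster), length(x$lineages),
              length(x$module_dag), nrow(x$dynamic_genes), nrow(x$eqtl_truth)))
  invisible(x)
}
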