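#' Default cluster topology
#'
#' The seven mesenchymal clusters arranged as a rooted tree with three
#' root-to-leaf differentiation paths: an osteogenic path ending in
#' osteocyte-like cells (MPC-LMP-OBP-OB1-Ocy), a second osteogenic path
#' (MPC-LMP-OBP-OB2) and an adipogenic path (MPC-LMP-MALP).
#'
#' @return data.frame with columns `parent`, `child`.
#' @export
default_topology <- function() {
  data.frame(
    parent = c("MPC", "LMP", "LMP", "OBP", "OBP", "OB1"),
    child  = c("LMP", "OBP", "MALP", "OB1", "OB2", "Ocy")
  )
}

#' Simulation configuration
#'
#' Parameters of the synthetic single-cell population used for recovery and
#' calibration testing. Defaults describe a desk-scale cohort (24 mice, 400
#' cells each) with the same structural features as a large outbred
#' single-cell study: a 7-cluster mesenchymal topology with three bifurcating
#' trajectories, negative-binomial UMI counts, co-expression modules generated
#' from linear-Gaussian DAGs at the sample level, sigmoidal
#' trajectory-dynamic genes, and cis-acting founder-haplotype eQTL.
#'
#' @param n_mice number of samples (mice).
#' @param n_cells_per_mouse cells simulated per mouse (before QC outliers).
#' @param founders number of founder haplotypes (8 for Diversity Outbred).
#' @param n_chromosomes,n_markers_per_chrom,chrom_length synthetic genome:
#'   `n_chromosomes` chromosomes of `chrom_length` bp with uniformly spaced
#'   markers (1-based positions).
#' @param switch_prob per-interval founder switch probability of the haplotype
#'   Markov chain.
#' @param cluster_topology rooted tree of cluster labels as a
#'   (parent, child) data.frame; must have exactly three leaves by default
#'   convention, any tree is accepted.
#' @param root root cluster label.
#' @param n_modules,module_size planted co-expression modules (one DAG each).
#' @param n_dynamic_genes target total of trajectory-dynamic genes. Every
#'   gene of a planted driver's radius-3 neighborhood is seeded as dynamic
#'   (the driver's differentiation program); free-standing dynamic genes fill
#'   the remainder of the target.
#' @param n_dynamic_per_driver minimum dynamic genes guaranteed inside each
#'   planted driver's radius-3 neighborhood (ground-truth invariant).
#' @param n_marker_genes_per_cluster cluster marker genes (elevated baseline in
#'   their own cluster).
#' @param n_noise_genes unstructured background genes; a fraction is flagged
#'   mitochondrial (`frac_mito`) or ribosomal (`frac_rpl`, `frac_rps`) with
#'   elevated baselines.
#' @param n_eqtl_genes genes given a cis founder-haplotype effect.
#' @param nb_dispersion negative-binomial dispersion (variance `mu + a*mu^2`).
#' @param eqtl_effect_sd log-scale allele-substitution effect of the planted
#'   eQTL founder allele.
#' @param module_amp log-scale amplitude of the sample-level module latent.
#' @param module_factor_rho variance share of a module-wide common factor
#'   mixed with the structural-equation values (keeps modules globally
#'   coherent while DAG-adjacent genes stay the most correlated pairs).
#' @param sem_noise_sd child-node noise SD of the linear-Gaussian structural
#'   equation model.
#' @param sem_weight_range absolute range of SEM edge weights.
#' @param sem_neg_weight_prob probability an SEM edge weight is negative.
#' @param dynamic_l2fc_range absolute range of planted log2 fold changes
#'   (lower bound >= 1 so planted genes clear the test's effect threshold).
#' @param frac_mito,frac_rpl,frac_rps fraction of noise genes flagged.
#' @param qc_outlier_frac fraction of cells generated outside the QC envelope
#'   (library size below 400 or above 6200, or mitochondrial fraction above
#'   10%) to exercise the cell filters.
#' @param latent_noise_sd SD of per-cell noise around the trajectory segment in
#'   the latent space.
#' @param n_latent_dims dimensionality of the returned latent space (noise
#'   dimensions pad the tree layout).
#' @param seed integer seed; a fixed seed gives byte-identical output.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_mice = 24, n_cells_per_mouse = 400, founders = 8,
                       n_chromosomes = 2, n_markers_per_chrom = 30,
                       chrom_length = 1e8, switch_prob = 0.05,
                       cluster_topology = default_topology(), root = "MPC",
                       n_modules = 4, module_size = 60,
                       n_dynamic_genes = 110, n_dynamic_per_driver = 6,
                       n_marker_genes_per_cluster = 5, n_noise_genes = 225,
                       n_eqtl_genes = 20, nb_dispersion = 0.1,
                       eqtl_effect_sd = 0.5, module_amp = 0.4,
                       module_factor_rho = 0.6,
                       sem_noise_sd = 0.5, sem_weight_range = c(0.5, 1),
                       sem_neg_weight_prob = 0,
                       dynamic_l2fc_range = c(1, 2.5),
                       frac_mito = 0.03, frac_rpl = 0.04, frac_rps = 0.03,
                       qc_outlier_frac = 0.03, latent_noise_sd = 0.15,
                       n_latent_dims = 15, seed = 1) {
  cfg <- structure(as.list(environment()), class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_mice", "n_cells_per_mouse", "founders", "n_chromosomes",
              "n_markers_per_chrom", "n_modules", "module_size", "n_latent_dims")
  for (f in counts) if (cfg[[f]] < 1) stopf("'%s' must be a positive count", f)
  if (cfg$n_markers_per_chrom < 2) stopf("need at least 2 markers per chromosome")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be positive")
  if (cfg$n_dynamic_genes < 0) stopf("n_dynamic_genes must be non-negative")
  topo <- cfg$cluster_topology
  if (!is.data.frame(topo) || nrow(topo) == 0)
    stopf("cluster_topology must be a non-empty (parent, child) data.frame")
  labs <- unique(c(topo$parent, topo$child))
  if (!cfg$root %in% labs) stopf("root '%s' not in topology", cfg$root)
  g <- igraph::graph_from_data_frame(topo, directed = TRUE)
  if (!igraph::is_dag(g) || any(igraph::degree(g, mode = "in") > 1) ||
      igraph::components(g)$no != 1)
    stopf("cluster_topology must be a tree rooted at '%s'", cfg$root)
  if (igraph::degree(g, v = cfg$root, mode = "in") != 0)
    stopf("root '%s' has an incoming edge", cfg$root)
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("<sim_config> %d mice x %d cells, %d clusters, ",
                     "%d modules x %d genes, %d dynamic, %d eQTL genes, seed %d\n"),
              x$n_mice, x$n_cells_per_mouse,
              length(unique(unlist(x$cluster_topology))), x$n_modules,
              x$module_size, x$n_dynamic_genes, x$n_eqtl_genes, x$seed))
  invisible(x)
}

# Lineages (root-to-leaf cluster paths) of the configured topology.
topology_lineages <- function(cfg) {
  g <- igraph::graph_from_data_frame(cfg$cluster_topology, directed = TRUE)
  leaves <- names(which(igraph::degree(g, mode = "out") == 0))
  paths <- lapply(leaves, function(lf) {
    p <- igraph::shortest_paths(g, from = cfg$root, to = lf, mode = "out")$vpath[[1]]
    names(p)
  })
  names(paths) <- paste0("lineage_", seq_along(paths))
  paths
}

# Geometric layout of the topology: each cluster is a straight segment of
# length 2 in a low-dimensional space. A single child continues its parent's
# direction; the children of a branch point leave along +/- a fresh orthogonal
# axis, so cluster centroids reconstruct the tree as a Euclidean MST.
topology_layout <- function(cfg, seg_len = 2) {
  topo <- cfg$cluster_topology
  labs <- unique(c(topo$parent, topo$child))
  kid_counts <- table(topo$parent)
  ndim <- max(3, 1 + sum(ceiling(kid_counts[kid_counts >= 2] / 2)))
  segs <- list()
  axis_counter <- new.env()
  axis_counter$i <- 1L
  lay <- function(node, origin, dir) {
    segs[[node]] <<- list(start = origin, end = origin + seg_len * dir)
    kids <- topo$child[topo$parent == node]
    if (length(kids) == 1) {
      lay(kids, segs[[node]]$end, dir)
    } else if (length(kids) >= 2) {
      dirs <- lapply(seq_along(kids), function(i) {
        axis_id <- axis_counter$i + (i - 1) %/% 2
        ax <- numeric(ndim); ax[1 + axis_id] <- 1
        if (i %% 2 == 1) ax else -ax
      })
      axis_counter$i <- axis_counter$i + (length(kids) + 1) %/% 2
      for (i in seq_along(kids)) lay(kids[i], segs[[node]]$end, dirs[[i]])
    }
  }
  e1 <- numeric(ndim); e1[1] <- 1
  lay(cfg$root, numeric(ndim), e1)
  depth <- igraph::distances(
    igraph::graph_from_data_frame(topo, directed = TRUE),
    v = cfg$root, mode = "out")[1, labs]
  list(segments = segs, seg_len = seg_len,
       t_start = setNames(depth * seg_len, labs), ndim = ndim)
}
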