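# Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixtures)) assign(key, builder(), envir = .fixtures)
  get(key, envir = .fixtures)
}

# Desk-scale simulated population used across modules.
sim_default <- function() memo("sim_default", function()
  simulate_population(sim_config(seed = 101)))

# QC'd counts and the full pseudobulk chain for the default population.
qc_default <- function() memo("qc_default", function()
  filter_genes_min_cells(filter_cells(sim_default()$counts)))

pb_quantile_default <- function() memo("pb_quantile", function()
  quantile_normalize(vst_transform(normalize_cpm(
    filter_low_expressed(mean_expression(qc_default()))))))

traj_default <- function() memo("traj_default", function() {
  sim <- sim_default()
  cc <- qc_default()
  infer_lineages(sim$latent_space[cc$cell_meta$cell_id, , drop = FALSE],
                 cc$cell_meta$cluster, "MPC")
})

# Map planted lineage names to inferred lineage names via their leaf cluster.
lineage_map <- function(traj, truth) {
  inferred_leaf <- vapply(traj$lineages, function(p) p[length(p)], character(1))
  truth_leaf <- vapply(truth$lineages, function(p) p[length(p)], character(1))
  setNames(names(inferred_leaf)[match(truth_leaf, inferred_leaf)],
           names(truth_leaf))
}

# Tiny single-lineage trajectory over synthetic pseudotime for test fits.
toy_trajectory <- function(n = 300, tmax = 5, seed = 1) {
  set.seed(seed)
  pt <- matrix(runif(n, 0, tmax), ncol = 1,
               dimnames = list(sprintf("c%04d", seq_len(n)), "lineage_1"))
  w <- matrix(1, n, 1, dimnames = dimnames(pt))
  structure(list(lineages = list(lineage_1 = c("A", "B")), pseudotime = pt,
                 weights = w, clusters = rep(c("A", "B"), length.out = n),
                 root = "A"),
            class = "trajectory_set")
}

toy_boundary <- function(t_start = 0.5, t_end = 4.5) {
  data.frame(lineage = "lineage_1", cluster = "A", boundary = "A_to_B",
             t_start = t_start, t_end = t_end)
}

# Correlated gene blocks: n samples x p genes with common-factor share r.
block_matrix <- function(p, r, n, prefix = "G") {
  z <- rnorm(n)
  m <- sapply(seq_len(p), function(i) sqrt(r) * z + sqrt(1 - r) * rnorm(n))
  colnames(m) <- paste0(prefix, seq_len(p))
  m
}

# A gene_dag object from an edge list.
toy_dag <- function(parent, child, nodes = NULL) {
  nodes <- nodes %||% unique(c(parent, child))
  structure(list(nodes = nodes,
                 edges = data.frame(parent = parent, child = child),
                 score = NA_real_, module = "M"),
            class = "gene_dag")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
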