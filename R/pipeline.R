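# End-to-end orchestration: simulate (or load) -> QC -> pseudobulk ->
# trajectories -> dynamic genes -> modules -> Bayesian networks -> DDG
# enrichment -> eQTL + composition -> prioritization, with a JSON manifest.

#' Run the full differentiation-driver-gene pipeline
#'
#' Executes every stage on a simulated (or supplied) dataset and writes
#' stage outputs plus a manifest to `out_dir`. Deterministic under a fixed
#' seed.
#'
#' @param config a [sim_config()] describing the synthetic dataset; ignored
#'   when `sim` is supplied.
#' @param out_dir output directory (created).
#' @param sim optional pre-built [simulate_population()] result.
#' @param coloc optional colocalization table ([read_coloc_table()] input);
#'   defaults to the simulation's synthetic coloc gene list.
#' @param impc_genes optional knockout-phenotype gene list.
#' @param beta,min_module_size co-expression parameters.
#' @param nknots,l2fc,alpha dynamic-gene test parameters.
#' @param coverage boundary coverage target.
#' @param downsample_target cell cap for the spline tests.
#' @param n_perm,perm_genes permutation-threshold effort.
#' @param population_mode hypergeometric population mode, see
#'   [hypergeom_enrichment()].
#' @param use_latent_space use the simulation's latent space for trajectory
#'   inference (default) instead of expression PCA.
#' @return (invisibly) a list with every stage result.
#' @export
run_all <- function(config = sim_config(), out_dir, sim = NULL, coloc = NULL,
                    impc_genes = NULL, beta = 14, min_module_size = 20,
                    nknots = 10, l2fc = 0.5, alpha = 0.05, coverage = 0.78,
                    downsample_target = 10000, n_perm = 200, perm_genes = 25,
                    population_mode = "union", use_latent_space = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t_start <- Sys.time()
  stage <- function(name, code) {
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(force(code), error = function(e)
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (is.null(sim)) sim <- stage("simulate", simulate_population(config))
  write_simulation(sim, file.path(out_dir, "simulation"))

  cc <- stage("qc", filter_genes_min_cells(filter_cells(sim$counts)))
  pb_raw <- stage("pseudobulk", filter_low_expressed(mean_expression(cc),
                                                     min_nonzero = min(15, config$n_mice - 2)))
  # samples whose retained genes are all zero in a cluster cannot be scaled
  pb_raw$matrices <- lapply(pb_raw$matrices, function(m) {
    drop <- colSums(m) == 0
    if (any(drop))
      warnf("dropping %d all-zero pseudobulk column(s)", sum(drop))
    m[, !drop, drop = FALSE]
  })
  usable <- vapply(pb_raw$matrices, ncol, integer(1)) >= 2
  if (any(!usable))
    warnf("dropping cluster(s) with < 2 usable samples: %s",
          paste(names(pb_raw$matrices)[!usable], collapse = ", "))
  pb_raw$matrices <- pb_raw$matrices[usable]
  pb <- stage("normalize",
              quantile_normalize(vst_transform(normalize_cpm(pb_raw))))
  write_pseudobulk(pb, file.path(out_dir, "pseudobulk"))

  reduced <- if (use_latent_space && !is.null(sim$latent_space)) {
    sim$latent_space[cc$cell_meta$cell_id, , drop = FALSE]
  } else stage("pca", reduce_pca(cc))
  traj <- stage("trajectories",
                infer_lineages(reduced, cc$cell_meta$cluster, config$root))
  boundaries <- stage("boundaries", define_boundaries(traj, coverage))
  write.csv(boundaries, file.path(out_dir, "boundaries.csv"), row.names = FALSE)
  write.csv(data.frame(cell_id = rownames(traj$pseudotime), traj$pseudotime),
            file.path(out_dir, "pseudotime.csv"), row.names = FALSE)

  cc_ds <- downsample_cells(cc, min(downsample_target, ncol(cc$counts)),
                            seed = child_seed(config$seed, "downsample"))
  traj_ds <- subset_trajectory(traj, cc_ds$cell_meta$cell_id)
  dyn <- stage("dynamic_genes",
               fit_dynamic_genes(cc_ds, traj_ds, boundaries, nknots = nknots,
                                 l2fc = l2fc, alpha = alpha))
  write.csv(dyn$trajectory, file.path(out_dir, "dynamic_trajectory.csv"),
            row.names = FALSE)
  write.csv(dyn$global, file.path(out_dir, "dynamic_global.csv"),
            row.names = FALSE)

  partitions <- stage("modules", lapply(pb$matrices, function(m)
    find_modules(m, beta = beta, min_module_size = min_module_size)))
  networks <- stage("bayes_nets", {
    out <- list()
    for (cl in names(partitions)) {
      expr <- t(pb$matrices[[cl]])
      out[[cl]] <- suppressWarnings(
        learn_module_networks(partitions[[cl]], expr))
    }
    out
  })

  ddg_tab <- stage("ddg", {
    rows <- list()
    sig <- dyn$trajectory[dyn$trajectory$significant, , drop = FALSE]
    for (cl in names(networks)) {
      bcl <- boundaries[boundaries$cluster == cl, , drop = FALSE]
      if (!nrow(bcl)) next
      dynamic_sets <- lapply(seq_len(nrow(bcl)), function(r)
        unique(sig$gene[sig$boundary == bcl$boundary[r] &
                          sig$lineage == bcl$lineage[r]]))
      names(dynamic_sets) <- bcl$boundary
      dynamic_sets <- dynamic_sets[!duplicated(names(dynamic_sets))]
      for (m in names(networks[[cl]])) {
        pruned <- prune_network(networks[[cl]][[m]])
        if (length(pruned$nodes) < 2) next
        en <- suppressWarnings(
          neighborhood_enrichment(pruned, dynamic_sets,
                                  population_mode = population_mode))
        if (nrow(en)) {
          en$cluster <- cl
          rows[[paste(cl, m)]] <- en
        }
      }
    }
    calls <- if (length(rows)) call_ddgs(do.call(rbind, rows), alpha) else
      call_ddgs(empty_enrichment(), alpha)
    calls
  })
  write.csv(ddg_tab, file.path(out_dir, "ddg_calls.csv"), row.names = FALSE)

  covars <- sim$samples[c("sex", "age_days", "weight", "length", "generation")]
  rownames(covars) <- sim$samples$sample_id
  thr <- stage("eqtl_threshold",
               suppressWarnings(permutation_threshold(
                 pb, sim$genotypes, covars, n_genes = perm_genes,
                 n_perm = n_perm, seed = child_seed(config$seed, "perm"))))
  eqtl <- stage("eqtl_scan",
                call_cis_eqtl(pb, sim$genotypes, cc$gene_meta, covars,
                              threshold = thr$threshold))
  write.csv(eqtl, file.path(out_dir, "cis_eqtl.csv"), row.names = FALSE)

  comp <- stage("composition", {
    props <- cell_type_proportions(cc$cell_meta)
    trans <- asin_sqrt_transform(props)
    cov2 <- sim$samples[match(rownames(trans), sim$samples$sample_id),
                        c("sex", "batch")]
    rows <- list()
    if (nrow(eqtl)) {
      top <- eqtl[which.max(eqtl$lod), ]
      effcols <- grep("^effect_", names(top), value = TRUE)
      founder <- sub("effect_", "", effcols[which.max(abs(unlist(top[effcols])))])
      grp <- carrier_groups(sim$genotypes, top$marker, founder)
      g <- ifelse(rownames(trans) %in% grp$carriers, "carrier", "rest")
      if (min(table(g)) >= 3) {
        for (cl in colnames(trans)) {
          r <- composition_test(trans[, cl], g, cov2)
          r$cluster <- cl; r$marker <- top$marker; r$founder <- founder
          rows[[cl]] <- r
        }
      }
    }
    tc <- trait_correlation(trans, sim$samples[match(rownames(trans),
                                                     sim$samples$sample_id),
                                               grep("^trait_", names(sim$samples))])
    list(carrier_tests = if (length(rows)) do.call(rbind, rows) else NULL,
         trait_correlation = tc, transformed = trans)
  })
  if (!is.null(comp$carrier_tests))
    write.csv(comp$carrier_tests, file.path(out_dir, "composition_tests.csv"),
              row.names = FALSE)
  write.csv(comp$trait_correlation, file.path(out_dir, "trait_correlation.csv"),
            row.names = FALSE)

  pri <- stage("prioritize", {
    ct <- read_coloc_table(coloc %||% sim$truth$coloc_genes)
    dd <- ddg_tab[ddg_tab$is_ddg %in% TRUE, , drop = FALSE]
    if (nrow(dd)) {
      # trajectory id from the boundary's lineage
      dd$trajectory <- boundaries$lineage[match(dd$boundary, boundaries$boundary)]
    }
    rows <- intersect_coloc(dd, ct)
    if (!is.null(impc_genes)) rows <- flag_impc(rows, impc_genes)
    rows
  })
  write.csv(pri, file.path(out_dir, "prioritized_ddgs.csv"), row.names = FALSE)
  summ <- summarize_prioritized(pri)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ddgnet")),
    seed = config$seed,
    parameters = list(beta = beta, min_module_size = min_module_size,
                      nknots = nknots, l2fc = l2fc, alpha = alpha,
                      coverage = coverage, n_perm = n_perm,
                      perm_genes = perm_genes,
                      population_mode = population_mode,
                      downsample_target = downsample_target),
    n_cells_raw = ncol(sim$counts$counts),
    n_cells_qc = ncol(cc$counts),
    n_genes_qc = nrow(cc$counts),
    lod_threshold = thr$threshold,
    n_cis_eqtl = nrow(eqtl),
    n_ddg_rows = sum(ddg_tab$is_ddg %in% TRUE),
    prioritized = summ,
    elapsed_sec = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(sim = sim, counts_qc = cc, pseudobulk = pb, trajectories = traj,
                 boundaries = boundaries, dynamic = dyn, partitions = partitions,
                 networks = networks, ddg = ddg_tab, eqtl_threshold = thr,
                 eqtl = eqtl, composition = comp, prioritized = pri,
                 summary = summ, manifest = manifest))
}

# Restrict a trajectory_set to a subset of cells (by cell id).
subset_trajectory <- function(traj, cell_ids) {
  keep <- match(cell_ids, rownames(traj$pseudotime))
  traj$pseudotime <- traj$pseudotime[keep, , drop = FALSE]
  traj$weights <- traj$weights[keep, , drop = FALSE]
  traj$reduced_space <- traj$reduced_space[keep, , drop = FALSE]
  traj$clusters <- traj$clusters[keep]
  traj
}
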