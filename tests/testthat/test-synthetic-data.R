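test_that("simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_mice = 6, n_cells_per_mouse = 60, n_modules = 1,
                    module_size = 20, n_dynamic_genes = 25, n_noise_genes = 40,
                    n_eqtl_genes = 4, seed = 7)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(as.matrix(s1$counts$counts), as.matrix(s2$counts$counts))
  expect_identical(s1$genotypes$dosage, s2$genotypes$dosage)
  expect_identical(s1$truth$dynamic_genes, s2$truth$dynamic_genes)
})

test_that("genotype dosages are diploid and founder-uniform in the long run", {
  cfg <- sim_config(n_mice = 500, seed = 11)
  gen <- simulate_genotypes(cfg)
  sums <- apply(gen$dosage, 1:2, sum)
  expect_true(all(abs(sums - 2) < 1e-9))
  # with 8 founders and uniform starts, mean dosage per founder ~ 2/8
  founder_means <- apply(gen$dosage, 3, mean)
  expect_true(all(abs(founder_means - 0.25) < 0.04))
})

test_that("zero switch probability yields constant single-founder pairs", {
  cfg <- sim_config(n_mice = 5, switch_prob = 0, seed = 3)
  gen <- simulate_genotypes(cfg)
  nmark <- cfg$n_markers_per_chrom
  for (s in 1:5) for (ch in 1:cfg$n_chromosomes) {
    idx <- (ch - 1) * nmark + seq_len(nmark)
    block <- gen$dosage[s, idx, ]
    expect_true(all(apply(block, 2, function(col) length(unique(col)) == 1)))
  }
})

test_that("counts follow negative-binomial moments", {
  # constant-eta genes: check mean/variance against NB(mu, phi) at many cells
  cfg <- sim_config(n_mice = 25, n_cells_per_mouse = 400, n_modules = 1,
                    module_size = 20, n_dynamic_genes = 0, n_eqtl_genes = 0,
                    n_noise_genes = 150, qc_outlier_frac = 0, seed = 21)
  sim <- simulate_population(cfg)
  counts <- as.matrix(sim$counts$counts)
  plain <- grep("^Ns", rownames(counts), value = TRUE)
  phi <- cfg$nb_dispersion
  # size factors vary per cell; compare pooled variance to the NB prediction
  # E[var] = mean(mu_c) + (phi + cv_s^2 (1 + phi)) mean(mu_c)^2 approximately;
  # use a generous band and require the dispersion signal to be present
  ratios <- vapply(plain, function(g) {
    x <- counts[g, ]
    mu <- mean(x)
    if (mu < 0.5) return(NA_real_)
    (var(x) - mu) / mu^2
  }, numeric(1))
  ratios <- ratios[!is.na(ratios)]
  # excess dispersion includes the lognormal size-factor CV^2 (~0.07)
  expect_gt(median(ratios), phi * 0.5)
  expect_lt(median(ratios), phi + 0.35)
})

test_that("no planted signal means empty dynamic truth", {
  cfg <- sim_config(n_mice = 6, n_cells_per_mouse = 50, n_dynamic_genes = 0,
                    n_modules = 1, module_size = 20, n_noise_genes = 30,
                    n_eqtl_genes = 2, seed = 5)
  sim <- simulate_population(cfg)
  expect_equal(nrow(sim$truth$dynamic_genes), 0)
})

test_that("driver radius-3 neighborhoods contain the configured dynamic genes", {
  sim <- sim_default()
  cfg_min <- 6
  for (m in names(sim$truth$module_dag)) {
    drv <- sim$truth$planted_drivers[[m]]
    ball <- ddgnet:::radius_neighborhood(sim$truth$module_dag[[m]], drv)
    expect_gte(sum(sim$truth$dynamic_genes$gene %in% ball), cfg_min)
  }
  # planted fold changes clear the magnitude floor
  expect_true(all(abs(sim$truth$dynamic_genes$l2fc) >= 1))
})

test_that("eQTL markers lie within 1 Mbp of their gene's TSS", {
  sim <- sim_default()
  et <- sim$truth$eqtl_truth
  gm <- sim$counts$gene_meta
  map <- sim$genotypes$marker_map
  for (r in seq_len(nrow(et))) {
    gi <- match(et$gene[r], gm$symbol)
    mi <- match(et$marker[r], map$marker)
    expect_identical(gm$chrom[gi], map$chrom[mi])
    expect_lte(abs(gm$tss_pos[gi] - map$pos[mi]), 1e6)
  }
})

test_that("sample-level pseudobulk correlation reflects the module DAG", {
  sim <- sim_default()
  pb <- pb_quantile_default()
  m <- pb$matrices[["LMP"]]
  mm <- sim$truth$module_membership
  dag <- sim$truth$module_dag[[1]]
  adj <- mapply(function(p, c)
    if (p %in% rownames(m) && c %in% rownames(m)) cor(m[p, ], m[c, ]) else NA,
    dag$parent, dag$child)
  g1 <- intersect(names(mm)[mm == names(sim$truth$module_dag)[1]], rownames(m))
  g2 <- intersect(names(mm)[mm == names(sim$truth$module_dag)[2]], rownames(m))
  between <- cor(t(m[g1, ]), t(m[g2, ]))
  gap <- median(abs(adj), na.rm = TRUE) - median(abs(between))
  expect_gt(gap, 0.3)
})

test_that("ground truth serializes losslessly through JSON", {
  sim <- sim_default()
  f <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(sim$truth, f)
  gt2 <- read_ground_truth(f)
  for (nm in names(sim$truth))
    expect_equal(gt2[[nm]], sim$truth[[nm]], tolerance = 1e-12, info = nm)
})

test_that("simulation round-trips through the on-disk layout", {
  cfg <- sim_config(n_mice = 5, n_cells_per_mouse = 40, n_modules = 1,
                    module_size = 20, n_dynamic_genes = 0, n_noise_genes = 20,
                    n_eqtl_genes = 2, seed = 13)
  sim <- simulate_population(cfg)
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  cc <- read_cell_counts(file.path(d, "counts"))
  expect_identical(as.matrix(cc$counts), as.matrix(sim$counts$counts))
  gen <- read_genotypes(d)
  expect_equal(gen$dosage, sim$genotypes$dosage)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(nb_dispersion = 0), "dispersion")
  expect_error(sim_config(n_mice = 0), "positive count")
  bad_topo <- data.frame(parent = c("A", "B"), child = c("B", "A"))
  expect_error(sim_config(cluster_topology = bad_topo, root = "A"), "tree")
  expect_error(sim_config(root = "missing"), "not in topology")
})

test_that("a zero eQTL effect is indistinguishable from background genes", {
  cfg <- sim_config(n_mice = 20, n_cells_per_mouse = 150, n_modules = 1,
                    module_size = 20, n_dynamic_genes = 0, n_noise_genes = 300,
                    n_eqtl_genes = 6, eqtl_effect_sd = 0, seed = 31)
  sim <- simulate_population(cfg)
  cc <- filter_genes_min_cells(filter_cells(sim$counts))
  pb <- normalize_cpm(filter_low_expressed(mean_expression(cc), min_nonzero = 10))
  m <- pb$matrices[["LMP"]]
  lod_of <- function(g) {
    y <- m[g, ]; names(y) <- colnames(m)
    max(scan_gene(y, sim$genotypes, min_samples = 15)$lod)
  }
  eqtl_lods <- vapply(intersect(sim$truth$eqtl_truth$gene, rownames(m)),
                      lod_of, numeric(1))
  bg <- intersect(grep("^Ns", rownames(m), value = TRUE), rownames(m))[1:12]
  bg_lods <- vapply(bg, lod_of, numeric(1))
  expect_lt(abs(median(eqtl_lods) - median(bg_lods)), 2)
})
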