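# Pseudobulk construction and the raw_mean -> cpm -> vst -> quantile chain.

pb_counts <- function(mat, samples, clusters) {
  rownames(mat) <- sprintf("g%02d", seq_len(nrow(mat)))
  colnames(mat) <- sprintf("cell%03d", seq_len(ncol(mat)))
  cm <- data.frame(cell_id = colnames(mat), sample_id = samples,
                   cluster = clusters)
  cell_counts(mat, cell_meta = cm)
}

test_that("mean expression averages raw UMI and rounds to 2 decimals", {
  # sample s1: 5 cells with counts 1,2,2,2,2 for gene 1 -> mean 1.8
  # gene 2 constant 7 -> 7.00; gene 3 values 1,2,0,0,0 -> 0.6
  mat <- rbind(c(1, 2, 2, 2, 2), rep(7, 5), c(1, 2, 0, 0, 0))
  cc <- pb_counts(mat, rep("s1", 5), rep("A", 5))
  pb <- mean_expression(cc, min_cells = 5)
  expect_equal(unname(pb$matrices$A[, "s1"]), c(1.8, 7, 0.6))
  expect_equal(pb$stage, "raw_mean")
})

test_that("two-cell average with permissive threshold gives 1.50", {
  mat <- rbind(c(1, 2))
  cc <- pb_counts(mat, rep("s1", 2), rep("A", 2))
  pb <- mean_expression(cc, min_cells = 2)
  expect_equal(unname(pb$matrices$A[1, "s1"]), 1.5)
})

test_that("samples contributing fewer than min_cells are omitted", {
  mat <- matrix(1, 3, 9)
  cc <- pb_counts(mat, c(rep("s1", 5), rep("s2", 4)), rep("A", 9))
  pb <- mean_expression(cc, min_cells = 5)
  expect_equal(colnames(pb$matrices$A), "s1")
  expect_equal(pb$contributing_cells$n_cells, 5L)
})

test_that("mean expression commutes with cell permutation within samples", {
  sim <- sim_default()
  cc <- qc_default()
  set.seed(2)
  perm <- sample(ncol(cc$counts))
  ccp <- cc
  ccp$counts <- ccp$counts[, perm]
  ccp$cell_meta <- ccp$cell_meta[perm, ]
  pb1 <- mean_expression(cc)
  pb2 <- mean_expression(ccp)
  expect_equal(pb1$matrices, pb2$matrices)
})

test_that("low-expression gene filter uses the nonzero-sample count", {
  m <- rbind(c(rep(1, 10), rep(0, 10)),
             c(rep(1, 14), rep(0, 6)),
             c(rep(1, 15), rep(0, 5)),
             rep(1, 20))
  rownames(m) <- paste0("g", 1:4)
  colnames(m) <- paste0("s", 1:20)
  pb <- ddgnet:::new_pseudobulk(list(A = m), "raw_mean",
                                data.frame(cluster = "A", sample_id = colnames(m),
                                           n_cells = 5))
  out <- filter_low_expressed(pb, 15)
  expect_equal(rownames(out$matrices$A), c("g3", "g4"))
  expect_equal(filter_low_expressed(pb, 0)$matrices, pb$matrices)
})

test_that("CPM scales columns to one million", {
  m <- cbind(s1 = c(1, 1, 1, 1), s2 = c(1, 3, 0, 0))
  rownames(m) <- paste0("g", 1:4)
  pb <- ddgnet:::new_pseudobulk(list(A = m), "raw_mean",
                                data.frame(cluster = "A",
                                           sample_id = c("s1", "s2"),
                                           n_cells = 5))
  out <- normalize_cpm(pb)
  expect_equal(unname(out$matrices$A[, "s1"]), rep(250000, 4))
  expect_equal(unname(out$matrices$A[1:2, "s2"]), c(250000, 750000))
  expect_true(all(abs(colSums(out$matrices$A) - 1e6) < 1e-6 * 1e6))
  bad <- pb; bad$matrices$A[, 2] <- 0
  expect_error(normalize_cpm(bad), "s2")
})

test_that("stage tags enforce the normalization order", {
  m <- matrix(rpois(40, 10) + 1, 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  pb <- ddgnet:::new_pseudobulk(list(A = m), "raw_mean",
                                data.frame(cluster = "A", sample_id = colnames(m),
                                           n_cells = 5))
  expect_error(vst_transform(pb), "stage")
  expect_error(quantile_normalize(pb), "stage")
  cpm <- normalize_cpm(pb)
  expect_error(normalize_cpm(cpm), "stage")
  expect_error(filter_low_expressed(cpm), "stage")
})

test_that("the VST closed form matches hand substitution and is monotone", {
  f <- ddgnet:::vst_closed_form
  expect_equal(f(0, a0 = 0.5, a1 = 1), 0)
  for (a0 in c(0.05, 0.5, 2)) for (a1 in c(0, 1, 5)) {
    q <- sort(runif(50, 0, 1000))
    expect_true(all(diff(f(q, a0, a1)) > 0))
  }
})

test_that("VST flattens the mean-variance relation of NB pseudobulk", {
  set.seed(4)
  a0 <- 0.05; a1 <- 2
  mu <- exp(seq(log(1), log(1000), length.out = 300))
  n <- 40
  m <- t(sapply(mu, function(m_) rnbinom(n, mu = m_,
                                         size = 1 / (a0 + a1 / m_))))
  rownames(m) <- paste0("g", seq_along(mu)); colnames(m) <- paste0("s", 1:n)
  pb <- ddgnet:::new_pseudobulk(list(A = m), "raw_mean",
                                data.frame(cluster = "A", sample_id = colnames(m),
                                           n_cells = 5))
  cpm <- normalize_cpm(pb)
  v <- vst_transform(cpm)
  bin <- cut(rank(mu), 6)
  ratio <- function(x) {
    bv <- tapply(seq_along(mu), bin, function(i) median(apply(x[i, ], 1, var)))
    max(bv) / min(bv)
  }
  expect_gt(ratio(cpm$matrices$A), 10)
  expect_lt(ratio(v$matrices$A), 3)
})

test_that("quantile normalization equalizes column distributions", {
  m <- cbind(s1 = c(1, 3), s2 = c(2, 4))
  rownames(m) <- c("g1", "g2")
  pb <- ddgnet:::new_pseudobulk(list(A = m), "vst",
                                data.frame(cluster = "A",
                                           sample_id = c("s1", "s2"),
                                           n_cells = 5))
  out <- quantile_normalize(pb)
  expect_equal(unname(out$matrices$A[, "s1"]), c(1.5, 3.5))
  expect_equal(unname(out$matrices$A[, "s2"]), c(1.5, 3.5))
  # identical columns are unchanged
  m2 <- cbind(s1 = c(5, 1, 3), s2 = c(5, 1, 3))
  pb2 <- ddgnet:::new_pseudobulk(list(A = m2), "vst",
                                 data.frame(cluster = "A",
                                            sample_id = c("s1", "s2"),
                                            n_cells = 5))
  expect_equal(quantile_normalize(pb2)$matrices$A, m2)
})

test_that("post-quantile columns share identical sorted values (Kolmogorov 0)", {
  pb <- pb_quantile_default()
  for (cl in names(pb$matrices)[1:3]) {
    m <- pb$matrices[[cl]]
    ref <- unname(sort(m[, 1]))
    for (j in 2:ncol(m)) expect_equal(unname(sort(m[, j])), ref)
  }
})

test_that("tie-averaging mode reproduces the reference implementation", {
  set.seed(8)
  m <- matrix(round(rnorm(60), 1), 12, 5,
              dimnames = list(paste0("g", 1:12), paste0("s", 1:5)))
  pb <- ddgnet:::new_pseudobulk(list(A = m), "vst",
                                data.frame(cluster = "A", sample_id = colnames(m),
                                           n_cells = 5))
  ours <- quantile_normalize(pb, ties = "average")$matrices$A
  ref <- limma::normalizeQuantiles(m, ties = TRUE)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})
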