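# Signed adjacency, TOM, module detection and iterative kME refinement.

test_that("signed adjacency hits its range endpoints and worked value", {
  n <- 16
  x <- rnorm(n)
  m <- cbind(a = x, b = x, c = -x)
  a <- signed_adjacency(m, beta = 14)
  expect_equal(a["a", "b"], 1)
  expect_equal(a["a", "c"], 0)
  # exactly orthogonal pair: r = 0 -> 0.5^14
  m2 <- cbind(u = rep(c(1, -1), 8), v = rep(c(1, 1, -1, -1), 4))
  a2 <- signed_adjacency(m2, beta = 14)
  expect_equal(a2["u", "v"], 0.5^14, tolerance = 1e-12)
  expect_equal(a2["u", "v"], 6.1035e-5, tolerance = 1e-4)
  # symmetry and range on random data
  set.seed(1)
  a3 <- signed_adjacency(matrix(rnorm(200), 20), beta = 6)
  expect_true(isSymmetric(a3))
  expect_true(all(a3 >= 0 & a3 <= 1))
  expect_error(signed_adjacency(cbind(a = rep(1, 5), b = rnorm(5))), "zero-variance")
  expect_error(signed_adjacency(m, beta = 0), "positive")
})

test_that("TOM matches hand computation and brute force", {
  a <- matrix(0.5, 3, 3); diag(a) <- 1
  dimnames(a) <- list(letters[1:3], letters[1:3])
  w <- tom_similarity(a)
  expect_equal(w["a", "b"], 0.5)       # (0.25 + 0.5) / (1 + 1 - 0.5)
  expect_true(all(diag(w) == 1))
  # zero off-diagonal adjacency -> zero TOM
  a0 <- diag(3); dimnames(a0) <- dimnames(a)
  expect_true(all(tom_similarity(a0)[upper.tri(a0)] == 0))
  # brute-force triple loop on a random 20-gene adjacency
  set.seed(2)
  r <- cor(matrix(rnorm(20 * 30), 30))
  aa <- ((1 + r) / 2)^6; diag(aa) <- 1
  dimnames(aa) <- list(paste0("g", 1:20), paste0("g", 1:20))
  w1 <- tom_similarity(aa)
  w2 <- aa
  k <- colSums(aa) - diag(aa)
  for (i in 1:20) for (j in 1:20) {
    if (i == j) { w2[i, j] <- 1; next }
    num <- sum(aa[i, -c(i, j)] * aa[-c(i, j), j]) + aa[i, j]
    w2[i, j] <- num / (min(k[i], k[j]) + 1 - aa[i, j])
  }
  expect_equal(w1, w2, tolerance = 1e-12)
  expect_true(all(w1 >= -1e-12 & w1 <= 1 + 1e-12))
})

test_that("soft-threshold selection reaches the fit target on modular data", {
  # scale-free fit on the generator's pseudobulk (planted modules + noise)
  x <- t(pb_quantile_default()$matrices[["LMP"]])
  x <- x[, apply(x, 2, sd) > 0]
  res <- suppressWarnings(pick_soft_threshold(x))
  expect_gte(res$fit$r2[res$fit$power == res$power], 0.85)
  # degenerate identical genes: no finite fit index -> default with warning
  xx <- matrix(rep(rnorm(20), 25), 20)
  colnames(xx) <- paste0("g", 1:25)
  expect_warning(res2 <- pick_soft_threshold(xx), "default")
  expect_equal(res2$power, 14)
  expect_error(pick_soft_threshold(cbind(a = rep(1, 20), b = rnorm(20))),
               "constant")
})

test_that("planted blocks are detected and refined block-pure", {
  set.seed(7)
  x <- cbind(block_matrix(30, 0.8, 24, "A"), block_matrix(30, 0.8, 24, "B"),
             matrix(rnorm(24 * 20), 24, dimnames = list(NULL, paste0("N", 1:20))))
  a <- signed_adjacency(x, 14)
  p0 <- detect_modules(tom_similarity(a), x, min_module_size = 20)
  mods0 <- setdiff(unique(p0$assignments), "unassigned")
  expect_equal(length(mods0), 2)
  pr <- iterative_refine(p0, x, beta = 14)
  mods <- setdiff(unique(pr$assignments), "unassigned")
  expect_equal(length(mods), 2)
  for (m in mods) {
    members <- names(pr$assignments)[pr$assignments == m]
    blocks <- unique(substr(members, 1, 1))
    expect_length(setdiff(blocks, "N"), 1)   # one block per module
  }
  # every block gene assigned to its block's module
  for (b in c("A", "B")) {
    lab <- pr$assignments[paste0(b, 1:30)]
    expect_equal(length(unique(lab)), 1)
    expect_false(unique(lab) == "unassigned")
  }
  # no module below the size floor
  expect_true(all(table(pr$assignments[pr$assignments != "unassigned"]) >= 20))
})

test_that("pure noise yields no refined modules", {
  set.seed(11)
  x <- matrix(rnorm(24 * 80), 24, dimnames = list(NULL, paste0("G", 1:80)))
  p0 <- detect_modules(tom_similarity(signed_adjacency(x, 14)), x, 20)
  pr <- iterative_refine(p0, x, beta = 14)
  expect_equal(unique(pr$assignments), "unassigned")
})

test_that("kME refinement ejects weak members and keeps strong modules fixed", {
  set.seed(13)
  strong <- block_matrix(30, 0.9, 40, "S")
  noise <- matrix(rnorm(40 * 10), 40, dimnames = list(NULL, paste0("N", 1:10)))
  x <- cbind(strong, noise)
  seeded <- structure(list(
    assignments = setNames(rep("ME1", 40), colnames(x)),
    params = list(min_module_size = 20, merge_cor = 0.85)),
    class = "module_partition")
  pr <- iterative_refine(seeded, x, beta = 14)
  expect_gte(sum(pr$assignments[paste0("N", 1:10)] == "unassigned"), 8)
  expect_true(all(pr$assignments[paste0("S", 1:30)] != "unassigned"))
  # an already-coherent module is a fixed point
  clean <- structure(list(
    assignments = setNames(c(rep("ME1", 30), rep("unassigned", 10)),
                           colnames(x)),
    params = list(min_module_size = 20, merge_cor = 0.85)),
    class = "module_partition")
  pr2 <- iterative_refine(clean, x, beta = 14)
  expect_true(all(pr2$assignments[paste0("S", 1:30)] ==
                    pr2$assignments["S1"]))
  # anti-correlated gene is dropped in the first iteration
  x2 <- cbind(strong, flip = -strong[, 1] + rnorm(40, sd = 0.1))
  seeded2 <- structure(list(
    assignments = setNames(rep("ME1", 31), colnames(x2)),
    params = list(min_module_size = 20, merge_cor = 0.85)),
    class = "module_partition")
  pr3 <- iterative_refine(seeded2, x2, beta = 14, max_iter = 1)
  expect_equal(unname(pr3$assignments["flip"]), "unassigned")
})

test_that("eigengenes are sign-oriented and unit variance", {
  pb <- pb_quantile_default()
  part <- find_modules(pb$matrices[["MPC"]])
  for (m in colnames(part$eigengenes)) {
    members <- names(part$assignments)[part$assignments == m]
    kme <- part$kme[members]
    expect_gte(mean(kme), 0)
    expect_equal(sd(part$eigengenes[, m]), 1, tolerance = 1e-8)
    expect_true(all(kme >= 0.5 - 1e-8))
  }
})
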