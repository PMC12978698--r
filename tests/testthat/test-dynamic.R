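# NB spline smoothers and threshold Wald tests for boundary-dynamic genes.

# A smoother_fit whose start->end contrast has a chosen delta and SE.
crafted_fit <- function(delta, se, t_start = 0, t_end = 1) {
  basis <- spline_basis(seq(t_start, t_end, length.out = 50), nknots = 2)
  ctr <- basis_eval(basis, t_end) - basis_eval(basis, t_start)
  beta <- as.numeric(delta * t(ctr) / sum(ctr^2))
  cov <- diag(length(beta)) * se^2 / sum(ctr^2)
  structure(list(lineages = list(lineage_1 = list(beta = beta, cov = cov,
                                                  theta = 10)),
                 basis = list(lineage_1 = basis)),
            class = "smoother_fit")
}

test_that("the threshold Wald statistic matches the closed form", {
  b <- data.frame(lineage = "lineage_1", cluster = "A", boundary = "A_to_B",
                  t_start = 0, t_end = 1)
  # delta/ln2 = 1.5, SE = 0.2 ln2, l2fc 0.5 -> stat ((1.5-0.5)/0.2)^2 = 25
  fit <- crafted_fit(1.5 * log(2), 0.2 * log(2))
  r <- start_vs_end_test(fit, b, l2fc = 0.5)
  expect_equal(r$wald_stat, 25, tolerance = 1e-8)
  expect_equal(r$p, pchisq(25, 1, lower.tail = FALSE), tolerance = 1e-10)
  expect_equal(r$p, 5.733e-7, tolerance = 1e-3)
  expect_equal(r$delta_log2, 1.5, tolerance = 1e-8)
  # zero contrast -> stat 0, p 1
  r0 <- start_vs_end_test(crafted_fit(0, 0.2), b)
  expect_equal(r0$wald_stat, 0)
  expect_equal(r0$p, 1)
  # contrasts below the fold-change threshold are not called
  rsub <- start_vs_end_test(crafted_fit(0.4 * log(2), 0.01), b, l2fc = 0.5)
  expect_equal(rsub$wald_stat, 0)
  expect_equal(rsub$p, 1)
})

test_that("raising the fold-change threshold never raises the statistic", {
  b <- data.frame(lineage = "lineage_1", cluster = "A", boundary = "A_to_B",
                  t_start = 0, t_end = 1)
  for (d in c(0.3, 0.8, 1.7, 3)) {
    fit <- crafted_fit(d, 0.15)
    stats <- vapply(c(0, 0.25, 0.5, 1, 2), function(l2fc)
      start_vs_end_test(fit, b, l2fc = l2fc)$wald_stat, numeric(1))
    expect_true(all(diff(stats) <= 1e-12))
  }
})

test_that("interior knots sit at pseudotime quantiles", {
  basis <- spline_basis(seq(0, 1, length.out = 10001), nknots = 10)
  expect_equal(basis$knots, seq(1 / 9, 8 / 9, by = 1 / 9), tolerance = 1e-3)
  expect_equal(basis$bounds, c(0, 1))
})

test_that("a constant-mean gene fits flat within 2 SE", {
  tr <- toy_trajectory(n = 400, seed = 5)
  set.seed(5)
  y <- rnbinom(400, mu = 6, size = 10)
  fit <- fit_nb_spline(y, tr)
  f <- fit$lineages$lineage_1
  grid <- basis_eval(fit$basis$lineage_1, seq(0.2, 4.8, length.out = 20))
  pred <- as.numeric(grid %*% f$beta)
  se <- sqrt(diag(grid %*% f$cov %*% t(grid)))
  expect_true(all(abs(pred - mean(pred)) < 2.5 * (se + 1e-6) + 0.15))
})

test_that("a planted sigmoid is recovered within the stated band", {
  tr <- toy_trajectory(n = 500, seed = 6)
  set.seed(6)
  eta <- log(4) + 2 * log(2) * plogis((tr$pseudotime[, 1] - 2.5) / 0.3)
  y <- rnbinom(500, mu = exp(eta), size = 10)
  fit <- fit_nb_spline(y, tr)
  r <- start_vs_end_test(fit, toy_boundary(), l2fc = 0.5)
  expect_gte(r$delta_log2, 1)
  expect_lte(r$delta_log2, 3)
  expect_lt(r$p, 1e-4)
})

test_that("the global test stacks per-lineage contrasts", {
  b <- data.frame(lineage = "lineage_1", cluster = "A", boundary = "A_to_B",
                  t_start = 0, t_end = 1)
  fit1 <- crafted_fit(1.5 * log(2), 0.2 * log(2))
  # single lineage: global equals the trajectory-specific test with df 1
  g1 <- global_start_vs_end_test(fit1, b)
  expect_equal(g1$wald_stat, 25, tolerance = 1e-8)
  expect_equal(g1$df, 1L)
  # two lineages, one flat: statistic unchanged, df 2
  fit2 <- fit1
  flat <- crafted_fit(0, 0.2 * log(2))
  fit2$lineages$lineage_2 <- flat$lineages$lineage_1
  fit2$basis$lineage_2 <- flat$basis$lineage_1
  b2 <- rbind(b, data.frame(lineage = "lineage_2", cluster = "A",
                            boundary = "A_to_B", t_start = 0, t_end = 1))
  g2 <- global_start_vs_end_test(fit2, b2)
  expect_equal(g2$wald_stat, 25, tolerance = 1e-8)
  expect_equal(g2$df, 2L)
  expect_gt(g2$p, g1$p)   # same signal spread over more df
  # all lineages flat -> p 1
  fit3 <- fit2
  fit3$lineages$lineage_1 <- flat$lineages$lineage_1
  expect_equal(global_start_vs_end_test(fit3, b2)$p, 1)
})

test_that("BH adjustment matches the step-up rule and a brute-force oracle", {
  # worked example by hand
  r <- adjust_and_call(data.frame(boundary = "b", lineage = "l",
                                  p = c(0.01, 0.02, 0.03)))
  expect_equal(r$p_adj, c(0.03, 0.03, 0.03))
  # single p is unchanged; all-ones yield no calls
  expect_equal(adjust_and_call(data.frame(boundary = "b", p = 0.2))$p_adj, 0.2)
  expect_false(any(adjust_and_call(data.frame(boundary = "b",
                                              p = rep(1, 5)))$significant))
  # brute-force step-up oracle on random vectors
  bh_oracle <- function(p) {
    n <- length(p)
    o <- order(p)
    adj <- p[o] * n / seq_len(n)
    adj <- rev(cummin(rev(adj)))
    pmin(1, adj)[order(o)]
  }
  set.seed(9)
  for (i in 1:1000) {
    p <- runif(sample(1:30, 1))^sample(c(1, 2, 4), 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-13)
  }
})

test_that("p-values are adjusted within (boundary, lineage) families", {
  df <- data.frame(boundary = rep(c("b1", "b2"), each = 2),
                   lineage = "l", p = c(0.05, 0.01, 0.04, 0.5))
  out <- adjust_and_call(df)
  expect_equal(out$p_adj[1:2], c(0.05, 0.02))
  expect_equal(out$p_adj[3:4], c(0.08, 0.5))
})
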