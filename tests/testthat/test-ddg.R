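# Network pruning, ego neighborhoods, size filtering and hypergeometric
# enrichment for driver calling.

test_that("pruning removes weakly connected nodes", {
  # isolated node removed
  dag <- toy_dag("A", "B", nodes = c("A", "B", "C"))
  expect_setequal(prune_network(dag)$nodes, character(0))
  # path A->B->C: single pass removes the endpoints, keeps isolated B
  path <- toy_dag(c("A", "B"), c("B", "C"))
  pr1 <- prune_network(path)
  expect_equal(pr1$nodes, "B")
  expect_equal(nrow(pr1$edges), 0)
  # iterate mode empties the path
  expect_length(prune_network(path, iterate = TRUE)$nodes, 0)
  # diamond: all degrees >= 2, unchanged
  dia <- toy_dag(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  expect_setequal(prune_network(dia)$nodes, c("A", "B", "C", "D"))
  expect_equal(nrow(prune_network(dia)$edges), 4)
})

test_that("three-step neighborhoods follow BFS depth and mode", {
  chain <- toy_dag(c("A", "B", "C", "D"), c("B", "C", "D", "E"))
  expect_setequal(three_step_neighborhood(chain, "A"), c("A", "B", "C", "D"))
  # focal with no edges
  lone <- toy_dag("A", "B", nodes = c("A", "B", "Z"))
  expect_equal(three_step_neighborhood(lone, "Z"), "Z")
  # collider, outgoing mode from the sink
  coll <- toy_dag(c("X", "Y"), c("Z", "Z"))
  expect_equal(three_step_neighborhood(coll, "Z", mode = "out"), "Z")
  expect_setequal(three_step_neighborhood(coll, "Z", mode = "in"),
                  c("X", "Y", "Z"))
  expect_error(three_step_neighborhood(chain, "missing"), "not in network")
})

test_that("the size filter keeps neighborhoods above mean + 1 sd", {
  expect_equal(sizes_above_mean_sd(c(2, 2, 2, 10)), c(FALSE, FALSE, FALSE, TRUE))
  expect_warning(none <- sizes_above_mean_sd(c(4, 4, 4, 4)), "equal")
  expect_false(any(none))
  expect_error(sizes_above_mean_sd(7), "at least 2")
})

test_that("hypergeometric upper tail matches brute-force enumeration", {
  brute <- function(overlap, m, n, k) {
    xs <- max(0, k - n):min(m, k)
    xs <- xs[xs >= overlap]
    sum(choose(m, xs) * choose(n, k - xs)) / choose(m + n, k)
  }
  # worked example m=5, n=15, k=6, overlap=3
  r <- hypergeom_enrichment(c(paste0("d", 1:3), paste0("x", 1:3)),
                            paste0("d", 1:5), m = 5, population = 20)
  expect_equal(r$p, brute(3, 5, 15, 6), tolerance = 1e-12)
  expect_equal(r$k, 6); expect_equal(r$overlap, 3); expect_equal(r$n, 15)
  # zero overlap -> p = 1 (upper tail from below the support)
  r0 <- hypergeom_enrichment(paste0("x", 1:4), paste0("d", 1:5), m = 5,
                             population = 20)
  expect_equal(r0$p, 1)
  # q = overlap - 1 parameterization, verified against phyper directly
  expect_equal(r$p, phyper(2, 5, 15, 6, lower.tail = FALSE), tolerance = 1e-15)
})

test_that("upper tail equals enumeration for all (m, n, k) up to 25", {
  # scan the full small parameter box via vectorized enumeration
  for (m in seq(0, 25, by = 5)) for (n in seq(1, 25, by = 6)) {
    for (k in seq(1, min(m + n, 25), by = 3)) {
      for (ov in unique(c(0, 1, k %/% 2, min(m, k)))) {
        xs <- max(0, k - n):min(m, k)
        xs <- xs[xs >= ov]
        expected <- if (length(xs))
          sum(exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k)))
        else 0
        got <- phyper(ov - 1, m, n, k, lower.tail = FALSE)
        expect_equal(got, expected, tolerance = 1e-12)
      }
    }
  }
})

test_that("enrichment p is monotone decreasing in overlap", {
  for (ov in 0:5) {
    p_lo <- phyper(ov - 1, 6, 20, 8, lower.tail = FALSE)
    p_hi <- phyper(ov, 6, 20, 8, lower.tail = FALSE)
    expect_lte(p_hi, p_lo + 1e-15)
  }
})

test_that("infeasible populations are floored or rejected by mode", {
  # population smaller than the draw: n floored to k - overlap
  r <- hypergeom_enrichment(paste0("x", 1:6), character(0), m = 0,
                            population = 2, population_mode = "literal")
  expect_true(r$n_adjusted)
  expect_equal(r$p, 1)   # m = 0 -> no successes possible
})

test_that("driver calls are invariant to gene-order permutation", {
  set.seed(21)
  dagT <- make_module_dag(sprintf("g%02d", 1:40))
  pd <- plant_module_driver(dagT, sprintf("g%02d", 1:40))
  x <- sem_sample(pd$dag, 400, 0.5)
  net <- hill_climb(x, mmpc_skeleton(x)); net$module <- "M"
  pr <- prune_network(net)
  dyn <- ddgnet:::radius_neighborhood(pd$dag, pd$driver)
  en1 <- suppressWarnings(neighborhood_enrichment(pr, list(B = dyn)))
  en2 <- suppressWarnings(neighborhood_enrichment(pr, list(B = rev(dyn))))
  o1 <- en1[order(en1$focal_gene), ]
  o2 <- en2[order(en2$focal_gene), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
  c1 <- call_ddgs(en1)
  expect_identical(sort(c1$focal_gene[c1$is_ddg]),
                   sort(call_ddgs(en2)$focal_gene[call_ddgs(en2)$is_ddg]))
})

test_that("edge cases of DDG calling", {
  # single enrichment keeps its p and is called when below alpha
  one <- data.frame(k = 5, overlap = 4, m = 6, n = 20, p = 0.01,
                    n_adjusted = FALSE, population_mode = "union",
                    focal_gene = "g1", boundary = "b", module = "M")
  out <- call_ddgs(one)
  expect_equal(out$p_adj, 0.01)
  expect_true(out$is_ddg)
  # no dynamic genes -> all p 1, nothing called
  dag <- toy_dag(c("A", "A", "B", "C"), c("B", "C", "D", "D"))
  en <- suppressWarnings(neighborhood_enrichment(dag, list(b = character(0))))
  if (nrow(en)) expect_true(all(en$p == 1))
  expect_equal(nrow(call_ddgs(ddgnet:::empty_enrichment())), 0)
})
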