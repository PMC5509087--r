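test_that("hypergeometric enrichment matches combinatorial enumeration", {
  universe <- paste0("g", 1:20)
  targets <- universe[1:5]
  cluster <- c(universe[c(1, 2, 3)], universe[10])  # k = 3, n = 4
  r <- hypergeom_enrichment(targets, cluster, universe)
  manual <- (choose(5, 3) * choose(15, 1) + choose(5, 4) * choose(15, 0)) /
    choose(20, 4)
  expect_equal(r$p, manual)           # 155/4845
  expect_equal(r$p, oracle_hyper(20, 5, 4, 3))

  # zero overlap gives p = 1
  r0 <- hypergeom_enrichment(universe[1:5], universe[6:9], universe)
  expect_equal(r0$p, 1)

  # units below the minimum target count are skipped
  r2 <- hypergeom_enrichment(universe[1:2], cluster, universe)
  expect_true(r2$skipped)
  expect_true(is.na(r2$p))
  expect_error(hypergeom_enrichment(targets, cluster, character(0)),
               "empty universe")
})

test_that("hypergeometric p equals enumeration across random configurations", {
  set.seed(60)
  for (i in 1:25) {
    N <- sample(8:30, 1)
    K <- sample(3:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    universe <- paste0("g", seq_len(N))
    targets <- sample(universe, K)
    cluster <- sample(universe, n)
    r <- hypergeom_enrichment(targets, cluster, universe)
    expect_equal(r$p, oracle_hyper(N, K, n, r$k), tolerance = 1e-12)
  }
})

test_that("enrichment p-values are invariant under gene relabeling", {
  universe <- paste0("g", 1:30)
  targets <- universe[1:6]; cluster <- universe[4:12]
  relabel <- setNames(paste0("x", 30:1), universe)
  r1 <- hypergeom_enrichment(targets, cluster, universe)
  r2 <- hypergeom_enrichment(relabel[targets], relabel[cluster],
                             unname(relabel))
  expect_equal(r1$p, r2$p)
})

test_that("family-wise adjustment calls match hand-computed examples", {
  one <- adjust_and_call(data.frame(p = 0.04), alpha = 0.05)
  expect_equal(one$p_adj, 0.04)
  expect_true(one$significant)

  bon <- adjust_and_call(data.frame(p = c(0.004, 0.006, rep(0.5, 8))),
                         method = "bonferroni", alpha = 0.05)
  expect_equal(bon$p_adj[1:2], c(0.04, 0.06))
  expect_equal(bon$significant[1:2], c(TRUE, FALSE))

  bh <- adjust_and_call(data.frame(p = c(0.001, 0.01, 0.02, 0.8)),
                        alpha = 0.05, method = "BH")
  expect_equal(bh$significant, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh$p_adj, oracle_bh(c(0.001, 0.01, 0.02, 0.8)))
})

test_that("TF-cluster enrichment respects the minimum-target rule", {
  edges <- rbind(
    data.frame(tf = "tfA", target = paste0("g", 1:6)),
    data.frame(tf = "tfB", target = paste0("g", 7:8)))  # only 2 targets
  clusters <- list(cl1 = paste0("g", 1:5), cl2 = paste0("g", 6:20))
  res <- tf_cluster_enrichment(edges, clusters,
                               universe = paste0("g", 1:20))
  expect_setequal(unique(res$tf), "tfA")  # tfB skipped (K < 3)
  expect_equal(nrow(res), 2)
})

test_that("overlap test is symmetric and matches enumeration", {
  universe <- paste0("g", 1:100)
  a <- universe[1:30]; b <- universe[c(1:12, 40:47)]
  r1 <- overlap_test(a, b, universe)
  r2 <- overlap_test(b, a, universe)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$k, 12)
  expect_equal(r1$p, oracle_hyper(100, 30, 20, 12), tolerance = 1e-12)
  expect_setequal(attr(r1, "intersection"), universe[1:12])

  # disjoint sets: p = 1
  expect_equal(overlap_test(universe[1:5], universe[6:10], universe)$p, 1)

  # maximal overlap at small N is the single most extreme table
  u <- paste0("g", 1:8)
  r3 <- overlap_test(u[1:4], u[1:4], u)
  expect_equal(r3$p, 1 / choose(8, 4), tolerance = 1e-12)
})

test_that("discordant genes are found exactly in the planted scenario", {
  sc <- sim_discordant_scenario(seed = 71)
  calls_a <- call_degs(fit_nested_glm(sc$cm_a))
  calls_b <- call_degs(fit_nested_glm(sc$cm_b))
  res <- find_discordant(calls_a, calls_b, time_min = 120, alpha = 0.1)

  expect_setequal(res$discordant$gene, sc$discordant)
  expect_false(any(sc$concordant %in% res$discordant$gene))

  shared_conc <- res$shared[res$shared$gene %in% sc$concordant, ]
  expect_gt(nrow(shared_conc), 3)
  expect_gt(cor(shared_conc$lfc_a, shared_conc$lfc_b), 0.9)

  # a gene significant in one region only is excluded
  only_a <- setdiff(calls_a$degs$time_120, calls_b$degs$time_120)
  expect_false(any(only_a %in% res$shared$gene))
})

test_that("DAPDEGx joins expression and accessibility layers", {
  degx <- c("g1", "g2", "g3")
  dap_calls <- data.frame(peak_id = c("p1", "p2", "p3"),
                          call = c("DAP_up", "none", "DAP_down"))
  links <- data.frame(peak_id = c("p1", "p2", "p3", "p3"),
                      gene_id = c("g1", "g2", "g4", "g5"))
  expect_identical(dapdegx(degx, dap_calls, links), "g1")
})
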