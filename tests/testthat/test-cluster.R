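test_that("identical rows merge first at height zero", {
  x <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  h <- ward_cluster(x)
  expect_equal(h$height[1], 0)
  expect_setequal(abs(h$merge[1, ]), c(1, 2))
})

test_that("merge heights equal the naive Lance-Williams oracle", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(12, 30, 50)[seed]
    x <- matrix(rnorm(n * 3), n)
    h <- ward_cluster(x)
    expect_equal(sort(h$height), sort(oracle_ward_heights(x)),
                 tolerance = 1e-10)
    expect_true(all(diff(h$height) >= -1e-12))  # Ward monotone
  }
})

test_that("row permutation changes labels but not merge heights", {
  set.seed(3)
  x <- matrix(rnorm(25 * 3), 25)
  rownames(x) <- paste0("g", 1:25)
  h1 <- ward_cluster(x)
  o <- sample(25)
  h2 <- ward_cluster(x[o, ])
  expect_equal(sort(h1$height), sort(h2$height), tolerance = 1e-10)
})

test_that("NaN profiles are rejected", {
  x <- matrix(c(1, NaN, 3, 4, 5, 6), 2)
  expect_error(ward_cluster(x), "non-finite")
})

test_that("tree cutting honors k, height and label ordering", {
  set.seed(4)
  x <- rbind(matrix(rnorm(20 * 3, 0, .1), 20),
             matrix(rnorm(5 * 3, 8, .1), 5))
  rownames(x) <- paste0("g", 1:25)
  h <- ward_cluster(x)
  expect_error(cut_tree(h), "exactly one")
  expect_error(cut_tree(h, k = 3, height = 2), "exactly one")
  expect_error(cut_tree(h, k = 26), "exceeds")

  # above the root: one cluster; below the first merge: all singletons
  expect_equal(unname(cut_tree(h, height = max(h$height) + 1)),
               rep(1L, 25))
  expect_length(unique(cut_tree(h, height = min(h$height) - 1e-9)), 25)

  k2 <- cut_tree(h, k = 2)
  # labels ordered by size: cluster 1 is the 20-member group
  expect_equal(sum(k2 == 1), 20)
  expect_equal(sum(k2 == 2), 5)
})

test_that("planted three-profile clusters are recovered (ARI >= 0.9)", {
  set.seed(5)
  profiles <- list(c(1.5, -1.5, 1.5), c(-1.5, 1.5, -1.5), c(0, 0, 1.5))
  truth <- rep(1:3, each = 40)
  x <- t(vapply(truth, function(k) profiles[[k]] + rnorm(3, 0, 0.2),
                numeric(3)))
  rownames(x) <- paste0("g", seq_len(nrow(x)))
  cl <- cut_tree(ward_cluster(x), k = 3)
  expect_gte(adjusted_rand_index(cl, truth), 0.9)
})

test_that("cluster summaries code patterns from mean profiles", {
  x <- rbind(g1 = c(1, 1, 1), g2 = c(3, 3, 3),
             g3 = c(0.05, -0.5, 0.7), g4 = c(0.15, -0.5, 0.7))
  colnames(x) <- c("lfc_30", "lfc_60", "lfc_120")
  assign <- setNames(c(1L, 1L, 2L, 2L), rownames(x))
  s <- summarize_clusters(assign, x)
  expect_equal(unname(s$means[1, ]), c(2, 2, 2))
  expect_equal(unname(s$pattern[1]), "up, up, up")
  # mean (0.1, -0.5, 0.7) at the flat threshold boundary codes up;
  # a mean below 0.1 in magnitude codes "no change"
  s2 <- summarize_clusters(setNames(c(1L, 1L), c("g3", "g4")),
                           x[c("g3", "g4"), ])
  expect_equal(unname(s2$pattern[1]), "up, down, up")
  s3 <- summarize_clusters(setNames(1L, "g3"), x["g3", , drop = FALSE])
  expect_equal(unname(s3$pattern[1]), "no change, down, up")
})

test_that("dendrograms export to Newick", {
  set.seed(6)
  x <- matrix(rnorm(10 * 3), 10, dimnames = list(paste0("g", 1:10), NULL))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram_newick(ward_cluster(x), f)
  tree <- ape::read.tree(f)
  expect_setequal(tree$tip.label, rownames(x))
})
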