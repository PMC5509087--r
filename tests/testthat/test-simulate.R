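test_that("simulated genomes are deterministic, ordered and gap-controlled", {
  g1 <- simulate_genome(n_genes = 100, seed = 9)
  g2 <- simulate_genome(n_genes = 100, seed = 9)
  expect_identical(g1, g2)
  expect_false(identical(g1, simulate_genome(n_genes = 100, seed = 10)))

  # genes do not overlap within a chromosome
  for (ch in unique(g1$chrom)) {
    spans <- g1[!duplicated(g1$gene_id) & g1$chrom == ch, ]
    spans <- spans[order(spans$start), ]
    expect_true(all(diff(spans$start) > 0))
    expect_true(all(spans$start[-1] > spans$end[-nrow(spans)]))
  }

  # fixed 5 kb gap construction
  gfix <- simulate_genome(n_chrom = 1, n_genes = 2,
                          spacing = list(p_short = 1, short = c(5000, 5000),
                                         long = c(5000, 5000)),
                          gene_length = c(2000, 2000), seed = 1)
  spans <- gfix[!duplicated(gfix$gene_id), ]
  expect_equal(spans$start[2] - spans$end[1], 5000L)

  expect_error(simulate_genome(spacing = list(p_short = 0.5,
                                              short = c(-10, 5),
                                              long = c(100, 200))),
               "non-positive")

  # mixture fraction of short gaps recovered within binomial error
  p_short <- 0.4
  gg <- simulate_genome(n_chrom = 1, n_genes = 400,
                        spacing = list(p_short = p_short,
                                       short = c(5e3, 1.5e4),
                                       long = c(2.5e4, 1e5)), seed = 21)
  spans <- gg[!duplicated(gg$gene_id), ]
  gaps <- spans$start[-1] - spans$end[-nrow(spans)]
  phat <- mean(gaps < 2e4)
  se <- sqrt(p_short * (1 - p_short) / length(gaps))
  expect_lt(abs(phat - p_short), 3 * se)
})

test_that("planted treatment profiles produce the requested fold change", {
  # one gene with profile (0, 0, +2) under Poisson sampling: the 120-min
  # experimental/control mean ratio is 4
  genes <- sprintf("g%04d", 1:50)
  cl <- planted_clusters(list(a = c(0, 0, 2)), list(a = "g0001"),
                         jitter_sd = 0)
  cfg <- sim_config(n_genes = 50, n_per_cell = 200, phi = 0,
                    baseline_mean = 8, baseline_sd = 0,
                    lib_size_range = c(1e6, 1e6), seed = 3)
  sim <- simulate_expression(cfg, clusters = cl, gene_ids = genes)
  d <- sim$cm$design
  y <- sim$cm$counts["g0001", ]
  r120 <- mean(y[d$treatment == "experimental" & d$time_min == 120]) /
    mean(y[d$treatment == "control" & d$time_min == 120])
  expect_lt(abs(log2(r120) - 2), 0.15)
  r30 <- mean(y[d$treatment == "experimental" & d$time_min == 30]) /
    mean(y[d$treatment == "control" & d$time_min == 30])
  expect_lt(abs(log2(r30)), 0.15)
  expect_identical(sim$truth$degx, "g0001")
})

test_that("simulated counts obey the var = mu + phi mu^2 relation", {
  phi <- 0.15
  cfg <- sim_config(n_genes = 1500, n_per_cell = 30, phi = phi,
                    baseline_mean = 6, baseline_sd = 1.5,
                    lib_size_range = c(1e6, 1e6), seed = 8)
  sim <- simulate_expression(cfg)
  y <- sim$cm$counts
  m <- rowMeans(y); v <- apply(y, 1, var)
  keep <- m > 5
  # regression of (v - m) on m^2 through the origin recovers phi
  slope <- sum((v - m)[keep] * m[keep]^2) / sum(m[keep]^4)
  expect_lt(abs(slope - phi), 0.03)
})

test_that("expression generator is deterministic given the seed", {
  cfg <- sim_config(n_genes = 100, seed = 5)
  s1 <- simulate_expression(cfg)
  s2 <- simulate_expression(cfg)
  expect_identical(s1$cm$counts, s2$cm$counts)
})

test_that("regulatory program construction enforces its invariants", {
  expect_error(regulatory_program(
    data.frame(tf = "a", target = "a", weight = 1), 0.1), "self-edge")
  expect_error(regulatory_program(
    data.frame(tf = "a", target = "b", weight = Inf), 0.1), "finite")
  pr <- make_regulatory_program(paste0("tf", 1:5), paste0("g", 1:30),
                                seed = 2)
  expect_true(all(table(pr$edges$target) >= 1))
  expect_true(all(abs(pr$edges$weight) >= 0.5 &
                    abs(pr$edges$weight) <= 1))
})

test_that("simulated ChIP tables are deterministic and carry planted truth", {
  g <- simulate_genome(n_genes = 60, seed = 2)
  spec <- data.frame(gene = unique(g$gene_id)[1:6], time = 120,
                     direction = rep(c("up", "down"), 3), fold = 8)
  c1 <- simulate_chip(g, spec, seed = 7)
  c2 <- simulate_chip(g, spec, seed = 7)
  expect_identical(as.data.frame(c1$peaks), as.data.frame(c2$peaks))
  expect_length(c1$truth$dap_120, 6)
  expect_error(simulate_chip(g, data.frame(gene = unique(g$gene_id)[1],
                                           time = 120, direction = "up",
                                           fold = -2)), "fold")
  expect_error(simulate_chip(g, data.frame(gene = "nope", time = 120,
                                           direction = "up", fold = 2)),
               "not in genome")
})
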