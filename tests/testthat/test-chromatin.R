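toy_peaks <- function(...) {
  vals <- list(...)
  df <- data.frame(chrom = "chr1",
                   start = seq(1, by = 1000, length.out = length(vals[[1]])),
                   end = seq(500, by = 1000, length.out = length(vals[[1]])),
                   peak_id = paste0("p", seq_along(vals[[1]])))
  for (nm in names(vals)) df[[nm]] <- vals[[nm]]
  peak_table(df, tag_cols = names(vals))
}

test_that("baseline calls match exact binomial hand computations", {
  pt <- toy_peaks(sample = c(100, 80, 40), input = c(100, 10, 10))
  res <- call_baseline(pt, sample_lib = 1e6, input_lib = 1e6)
  expect_equal(res$fold, c(100.5 / 100.5, 80.5 / 10.5, 40.5 / 10.5))
  expect_equal(res$call[1], "none")
  # binomial(90, 0.5) upper tail at k = 80
  expect_equal(res$p[2], pbinom(79, 90, 0.5, lower.tail = FALSE))
  expect_lt(res$p[2], 1e-4)
  expect_equal(res$call[2], "baseline")
  expect_error(call_baseline(pt, sample_lib = 0, input_lib = 1),
               "zero total")
})

test_that("baseline boundary is inclusive at fold 4", {
  pt <- toy_peaks(sample = c(100), input = c(100))
  res4 <- call_baseline(pt, sample_lib = 1e6, input_lib = 1e6,
                        min_fold = 1.0)
  expect_equal(res4$call, "none")  # p not small even if fold passes
  # equal tags but a 4x larger input library puts the normalized fold
  # exactly on the boundary: fold >= 4 must call when p is small
  pt3 <- toy_peaks(sample = 100, input = 100)
  res <- call_baseline(pt3, sample_lib = 1e6, input_lib = 4e6)
  expect_equal(res$fold, 4)
  expect_equal(res$p, pbinom(99, 200, 0.2, lower.tail = FALSE))
  expect_lt(res$p, 1e-4)
  expect_equal(res$call, "baseline")
})

test_that("differential calls match exact binomials and are direction-symmetric", {
  pt <- toy_peaks(exp = c(120, 100, 12), ctrl = c(12, 100, 120))
  res <- call_differential(pt, exp_lib = 1e6, ctrl_lib = 1e6)
  expect_equal(res$call, c("DAP_up", "none", "DAP_down"))
  expect_equal(res$p_up[1], pbinom(119, 132, 0.5, lower.tail = FALSE))
  # swapping condition labels maps up <-> down with identical p-values
  swapped <- call_differential(
    toy_peaks(exp = c(12, 100, 120), ctrl = c(120, 100, 12)),
    exp_lib = 1e6, ctrl_lib = 1e6)
  expect_equal(swapped$call, c("DAP_down", "none", "DAP_up"))
  expect_equal(swapped$p_up, res$p_down)
  expect_equal(swapped$p_down, res$p_up)
})

test_that("the DAP fold boundary is strict at 2", {
  # equal tags with a 2x larger control library: normalized fold exactly
  # 2, binomial p far below 1e-4 -- still NOT called (strict >)
  pt <- toy_peaks(exp = 100, ctrl = 100)
  res <- call_differential(pt, exp_lib = 1e6, ctrl_lib = 2e6)
  expect_equal(res$fold, 2)
  expect_lt(res$p_up, 1e-4)
  expect_equal(res$call, "none")
  pt2 <- toy_peaks(exp = 101, ctrl = 100)
  expect_equal(call_differential(pt2, exp_lib = 1e6,
                                 ctrl_lib = 2e6)$call, "DAP_up")
})

test_that("null ChIP data produce calls at the nominal error level", {
  gm <- simulate_genome(n_genes = 400, seed = 50)
  chip <- simulate_chip(gm, NULL, seed = 50)
  res <- rbind(
    call_differential(chip$peaks, exp_col = "exp_30", ctrl_col = "ctrl_30"),
    call_differential(chip$peaks, exp_col = "exp_120", ctrl_col = "ctrl_120"))
  # two one-sided tests at p < 1e-4 with a fold gate: expect ~0 calls
  expect_lte(sum(res$call != "none"), 3)
})

test_that("planted DAPs are detected with the right direction", {
  gm <- simulate_genome(n_genes = 300, seed = 51)
  gene_ids <- unique(gm$gene_id)
  spec <- data.frame(gene = gene_ids[1:40], time = 120,
                     direction = rep(c("up", "down"), 20), fold = 8)
  chip <- simulate_chip(gm, spec, seed = 51)
  res <- call_differential(chip$peaks, exp_col = "exp_120",
                           ctrl_col = "ctrl_120")
  called <- res$peak_id[res$call != "none"]
  truth <- names(chip$truth$dap_120)
  expect_gte(sum(called %in% truth) / length(truth), 0.9)  # sensitivity
  m <- res[match(truth, res$peak_id), ]
  found <- m$call != "none"
  expect_true(all((m$call[found] == "DAP_up") ==
                    (chip$truth$dap_120[found] == "up")))
})

test_that("merged peak universes sum tags onto unified intervals", {
  a <- peak_table(data.frame(chrom = "chr1", start = c(101, 501),
                             end = c(200, 600), peak_id = c("a1", "a2"),
                             tag = c(10, 20)))
  b <- peak_table(data.frame(chrom = "chr1", start = c(151, 901),
                             end = c(250, 1000), peak_id = c("b1", "b2"),
                             tag = c(5, 7)))
  u <- merge_peak_universes(a, b, "ta", "tb")
  expect_equal(nrow(u), 3)           # a1+b1 merge; a2; b2
  expect_equal(u$ta, c(10, 20, 0))
  expect_equal(u$tb, c(5, 0, 7))
})

test_that("isolated-gene domains extend the transcript by the window", {
  gm <- gene_models(data.frame(
    gene_id = "gA", transcript_id = "tA", chrom = "chr1", strand = "+",
    start = 100001, end = 105000))
  dom <- build_domains(gm, window = 20000)$gA
  expect_equal(GenomicRanges::start(dom), 80001)
  expect_equal(GenomicRanges::end(dom), 125000)
})

test_that("neighbor transcripts truncate the window at their boundary", {
  gm <- gene_models(data.frame(
    gene_id = c("gA", "gB"), transcript_id = c("tA", "tB"),
    chrom = "chr1", strand = "+",
    start = c(100001, 110001), end = c(105000, 115000)))
  dom <- build_domains(gm)
  # gA: window reaches 125000 but is truncated at gB's start; the region
  # beyond gB is not part of the domain
  expect_equal(GenomicRanges::start(dom$gA), 80001)
  expect_equal(GenomicRanges::end(dom$gA), 110000)
  expect_length(dom$gA, 1)
  # gB symmetric: truncated on the left at gA's end
  expect_equal(GenomicRanges::start(dom$gB), 105001)
  expect_equal(GenomicRanges::end(dom$gB), 135000)
  # no domain intersects another gene's transcripts
  tx <- genomewaves:::models_granges(gm)
  for (g in names(dom))
    expect_length(GenomicRanges::findOverlaps(
      dom[[g]], tx[tx$gene_id != g]), 0)
})

test_that("a gene's own overlapping transcripts never truncate it", {
  gm <- gene_models(data.frame(
    gene_id = "gA", transcript_id = c("tA1", "tA2"),
    chrom = "chr1", strand = "+",
    start = c(100001, 102001), end = c(105000, 108000)))
  dom <- build_domains(gm)$gA
  expect_equal(GenomicRanges::start(dom), 80001)
  expect_equal(GenomicRanges::end(dom), 128000)
})

test_that("peak assignment uses closed-interval any-overlap semantics", {
  gm <- gene_models(data.frame(
    gene_id = "gA", transcript_id = "tA", chrom = "chr1", strand = "+",
    start = 100001, end = 105000))
  dom <- build_domains(gm)
  # 10 bp overlap at the domain start boundary (BED [79990, 80010))
  pt <- peak_table(data.frame(chrom = "chr1", start = 79991, end = 80010,
                              peak_id = "p1", tag = 1))
  links <- assign_peaks(pt, dom, gm)
  expect_equal(nrow(links), 1)
  expect_equal(links$overlap_bp, 10L)
  # a peak ending exactly where the domain begins (BED half-open
  # abutment) is not linked
  pt2 <- peak_table(data.frame(chrom = "chr1", start = 79901, end = 80000,
                               peak_id = "p2", tag = 1))
  expect_equal(nrow(assign_peaks(pt2, dom, gm)), 0)
})

test_that("assignment equals the quadratic overlap oracle", {
  gm <- simulate_genome(n_chrom = 3, n_genes = 100, seed = 52)
  domains <- build_domains(gm)
  set.seed(52)
  n <- 1000
  chrom_lens <- attr(gm, "chrom_lengths")
  chrom <- sample(names(chrom_lens), n, TRUE)
  start <- vapply(chrom, function(ch)
    sample.int(chrom_lens[[ch]] - 2000L, 1), integer(1))
  pt <- peak_table(data.frame(chrom = chrom, start = start,
                              end = start + sample(200:2000, n, TRUE),
                              peak_id = sprintf("p%04d", 1:n),
                              tag = 1))
  links <- assign_peaks(pt, domains)
  oracle <- oracle_overlap_scan(pt, domains)
  key <- function(d) sort(paste(d$peak_id, d$gene_id, d$overlap_bp))
  expect_identical(key(links), key(oracle))
})
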