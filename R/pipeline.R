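#' Pipeline configuration with study-default thresholds
#'
#' Assembles the threshold set used across the pipeline, every one at its
#' study default: DEG FDR 0.1, MI screen p 1e-6, normalized RMSD gate
#' 0.33, DAP fold > 2 at p < 1e-4, baseline fold >= 4 at p < 1e-4,
#' 20 kb domain window, >= 3 targets per TF for enrichment at FDR 0.05.
#' Unnamed entries of `...` are not allowed; any named entry overrides
#' the default of the same name.
#'
#' @param seed master seed; every stochastic stage derives its own
#'   sub-seed from it by stage-name hashing, so stage outputs do not
#'   depend on execution order.
#' @param outdir output directory.
#' @param ... overrides (e.g. `deg_fdr = 0.05`, `cluster_k = 6`).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L, outdir = tempfile("gw_run_"), ...) {
  cfg <- list(
    seed = as.integer(seed), outdir = outdir,
    deg_fdr = 0.1, mi_p = 1e-6, rmsd = 0.33,
    dap_fold = 2, dap_p = 1e-4, baseline_fold = 4,
    domain_bp = 20000, min_targets = 3, enrich_fdr = 0.05,
    enrich_method = "BH", cluster_k = 4, cluster_height = NULL,
    # synthetic-scenario parameters (the default study conditions)
    n_genes = 2000, n_tfs = 20, n_per_cell = 5, phi = 0.1,
    planted_frac = 0.1, planted_lfc = 2, jitter_sd = 0.2,
    n_trn_targets = 200, n_discordant = 10, n_concordant = 50,
    chip_depth = 100, chip_dap_fold = 8,
    regions = c("diencephalon", "telencephalon"))
  ov <- list(...)
  if (length(ov) && (is.null(names(ov)) || any(names(ov) == "")))
    stop2("config overrides must be named")
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown))
    stop2("unknown config entries: ", paste(unknown, collapse = ", "))
  cfg[names(ov)] <- ov
  bad <- c("deg_fdr", "mi_p", "rmsd", "dap_fold", "dap_p",
           "baseline_fold", "min_targets", "enrich_fdr")
  if (any(unlist(cfg[bad]) <= 0)) stop2("thresholds must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of `name: value` entries (nesting flattened).
#' @param ... further overrides passed to [pipeline_config()].
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, c(y, list(...)))
}

#' Run pipeline stages on the default synthetic scenario
#'
#' Orchestrates the full chain — synthetic data generation, per-region
#' differential expression, profile clustering, network inference,
#' chromatin calls and the integration statistics — writing each stage's
#' outputs (all through the package's readers/writers) plus a JSON
#' manifest with the config echo, seed and file checksums. Rerunning
#' with the same config is bit-identical for every deterministic stage.
#'
#' @param cfg a `pipeline_config`.
#' @param stage one of `"simulate"`, `"de"`, `"cluster"`, `"trn"`,
#'   `"chromatin"`, `"integrate"`, `"all"`. Stages after the first
#'   require the upstream outputs in `cfg$outdir`.
#' @return invisibly, a list of stage result objects.
#' @export
run_pipeline <- function(cfg, stage = "all") {
  stages_all <- c("simulate", "de", "cluster", "trn", "chromatin",
                  "integrate")
  stage <- match.arg(stage, c(stages_all, "all"))
  todo <- if (stage == "all") stages_all else stage
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  for (s in todo) {
    res[[s]] <- switch(s,
      simulate = stage_simulate(cfg),
      de = stage_de(cfg),
      cluster = stage_cluster(cfg),
      trn = stage_trn(cfg),
      chromatin = stage_chromatin(cfg),
      integrate = stage_integrate(cfg))
  }
  write_manifest(cfg, todo)
  invisible(res)
}

pth <- function(cfg, ...) file.path(cfg$outdir, paste0(...))

require_upstream <- function(cfg, file, producer) {
  p <- pth(cfg, file)
  if (!file.exists(p))
    stop2("missing upstream artifact '", file, "'; run the '", producer,
          "' stage first")
  p
}

# default planted scenario: clusters of +/- planted_lfc profiles in region
# A, a shared discordant/concordant subset in region B, one regulatory
# program, and ChIP peaks with planted DAPs near region-A DEGx genes
stage_simulate <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  tfs <- genes[seq_len(cfg$n_tfs)]
  n_planted <- round(cfg$planted_frac * cfg$n_genes)
  planted <- genes[seq(cfg$n_tfs + 1, cfg$n_tfs + n_planted)]
  L <- cfg$planted_lfc
  profs <- list(c1 = c(L, 0, L), c2 = c(-L, -L, 0),
                c3 = c(0, 0, L), c4 = c(0, L, -L))
  mem <- split(planted, rep(names(profs), length.out = n_planted))
  clusters_a <- planted_clusters(profs, mem[names(profs)],
                                 jitter_sd = cfg$jitter_sd)

  # region B shares the first genes of c3 discordantly (sign flipped at
  # the late time point) and genes of c1/c2 concordantly
  disc <- mem$c3[seq_len(cfg$n_discordant)]
  conc <- c(mem$c1, mem$c4)[seq_len(cfg$n_concordant)]
  clusters_b <- planted_clusters(
    list(disc = c(0, 0, -L), conc_c1 = profs$c1, conc_c4 = profs$c4),
    list(disc = disc,
         conc_c1 = intersect(conc, mem$c1),
         conc_c4 = intersect(conc, mem$c4)),
    jitter_sd = cfg$jitter_sd)

  trn_targets <- genes[seq(cfg$n_tfs + n_planted + 1,
                           cfg$n_tfs + n_planted + cfg$n_trn_targets)]
  program <- make_regulatory_program(
    tfs, trn_targets, seed = derive_seed(cfg$seed, "program"))

  sim_a <- simulate_expression(
    sim_config(n_genes = cfg$n_genes, n_tfs = cfg$n_tfs,
               n_per_cell = cfg$n_per_cell, phi = cfg$phi,
               seed = derive_seed(cfg$seed, "expr_a")),
    clusters = clusters_a, program = program,
    region = cfg$regions[1], gene_ids = genes)
  sim_b <- simulate_expression(
    sim_config(n_genes = cfg$n_genes, n_tfs = cfg$n_tfs,
               n_per_cell = cfg$n_per_cell, phi = cfg$phi,
               seed = derive_seed(cfg$seed, "expr_b")),
    clusters = clusters_b, program = program,
    region = cfg$regions[2], gene_ids = genes)

  gm <- simulate_genome(n_chrom = 4, n_genes = cfg$n_genes,
                        seed = derive_seed(cfg$seed, "genome"))
  gm$gene_id <- genes[match(gm$gene_id, unique(gm$gene_id))]

  # plant DAPs at 120 min near region-A planted genes plus null genes
  dap_genes <- c(planted[seq_len(40)],
                 genes[seq(cfg$n_genes - 19, cfg$n_genes)])
  dap_spec <- data.frame(
    gene = dap_genes,
    time = rep(c(120, 30), c(50, 10)),
    direction = rep(c("up", "down"), length.out = length(dap_genes)),
    fold = cfg$chip_dap_fold, stringsAsFactors = FALSE)
  chip <- simulate_chip(gm, dap_spec, depth = cfg$chip_depth,
                        seed = derive_seed(cfg$seed, "chip"))

  design <- rbind(sim_a$cm$design, sim_b$cm$design)
  write_design(design, pth(cfg, "design.tsv"))
  write_counts(sim_a$cm, pth(cfg, "counts_", cfg$regions[1], ".tsv"))
  write_counts(sim_b$cm, pth(cfg, "counts_", cfg$regions[2], ".tsv"))
  write_gtf(gm, pth(cfg, "genome.gtf"))
  writeLines(tfs, pth(cfg, "tf_list.txt"))
  write_peaks(chip$peaks, pth(cfg, "peaks.bed"))
  write.table(data.frame(gene = sim_a$truth$degx), pth(cfg, "truth_degx_a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim_a$truth$cluster, pth(cfg, "truth_cluster_a.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim_b$truth$cluster, pth(cfg, "truth_cluster_b.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(program$edges, pth(cfg, "truth_edges.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(peak_id = names(chip$truth$baseline),
                         baseline = chip$truth$baseline),
              pth(cfg, "truth_baseline.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(dap_spec, pth(cfg, "truth_dap.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(chip = chip, program = program))
}

load_region_counts <- function(cfg, region) {
  design <- read_design(require_upstream(cfg, "design.tsv", "simulate"))
  d <- design_region(design, region)
  read_counts(require_upstream(cfg, paste0("counts_", region, ".tsv"),
                               "simulate"), design = d)
}

stage_de <- function(cfg) {
  out <- list()
  for (region in cfg$regions) {
    cm <- load_region_counts(cfg, region)
    fit <- fit_nested_glm(cm)
    calls <- call_degs(fit, alpha = cfg$deg_fdr)
    write.table(calls$table, pth(cfg, "de_", region, ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene = calls$degx),
                pth(cfg, "degx_", region, ".tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    out[[region]] <- calls
  }
  out
}

read_de_calls <- function(cfg, region) {
  tab <- read.delim(require_upstream(cfg, paste0("de_", region, ".tsv"),
                                     "de"), stringsAsFactors = FALSE)
  degx <- read.delim(require_upstream(cfg, paste0("degx_", region, ".tsv"),
                                      "de"), stringsAsFactors = FALSE)$gene
  tl <- as.integer(sub("lfc_", "", grep("^lfc_", names(tab), value = TRUE)))
  profiles <- as.matrix(tab[match(degx, tab$gene_id), paste0("lfc_", tl),
                            drop = FALSE])
  rownames(profiles) <- degx
  structure(list(table = tab, degx = degx, profiles = profiles,
                 alpha = cfg$deg_fdr, time_levels = tl, region = region),
            class = "deg_calls")
}

stage_cluster <- function(cfg) {
  out <- list()
  for (region in cfg$regions) {
    calls <- read_de_calls(cfg, region)
    if (nrow(calls$profiles) < 2) {
      warning("region ", region, ": fewer than 2 DEGx; skipping clustering")
      next
    }
    dend <- ward_cluster(calls$profiles)
    assign <- if (!is.null(cfg$cluster_height))
      cut_tree(dend, height = cfg$cluster_height) else
      cut_tree(dend, k = min(cfg$cluster_k, nrow(calls$profiles)))
    summ <- summarize_clusters(assign, calls$profiles)
    write_clusters(summ$table, pth(cfg, "clusters_", region, ".tsv"))
    write_dendrogram_newick(dend, pth(cfg, "dendrogram_", region, ".nwk"))
    out[[region]] <- summ
  }
  out
}

stage_trn <- function(cfg) {
  tfs <- read_tf_list(require_upstream(cfg, "tf_list.txt", "simulate"))
  # expression from both regions jointly: network inference wants as many
  # samples as possible and the program is region-independent
  cms <- lapply(cfg$regions, function(r) load_region_counts(cfg, r))
  counts <- do.call(cbind, lapply(cms, function(cm) cm$counts))
  expr <- expression_profiles(count_matrix(counts))
  trn <- build_trn(expr, tfs, mi_p = cfg$mi_p, rmsd_max = cfg$rmsd,
                   seed = derive_seed(cfg$seed, "trn"))
  write_trn_edges(trn$edges, pth(cfg, "trn_edges.tsv"))
  write.table(data.frame(tf = names(trn$degree), degree = trn$degree,
                         hub = names(trn$degree) %in% trn$hubs),
              pth(cfg, "trn_degree.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  trn
}

stage_chromatin <- function(cfg) {
  gm <- read_annotation(require_upstream(cfg, "genome.gtf", "simulate"))
  pt <- read_peaks(require_upstream(cfg, "peaks.bed", "simulate"),
                   tag_cols = c("input", "ctrl_30", "exp_30",
                                "ctrl_120", "exp_120"))
  baseline <- call_baseline(pt, sample_col = "ctrl_30",
                            input_col = "input",
                            min_fold = cfg$baseline_fold,
                            max_p = cfg$dap_p)
  daps <- lapply(c(30, 120), function(t) {
    call_differential(pt, exp_col = paste0("exp_", t),
                      ctrl_col = paste0("ctrl_", t),
                      min_fold = cfg$dap_fold, max_p = cfg$dap_p)
  })
  names(daps) <- c("t30", "t120")
  domains <- build_domains(gm, window = cfg$domain_bp)
  links <- assign_peaks(pt, domains, gm)
  write.table(baseline, pth(cfg, "baseline_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (t in names(daps))
    write.table(daps[[t]], pth(cfg, "dap_calls_", t, ".tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  dom_flat <- unlist(domains, use.names = FALSE)
  dom_df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(dom_flat)),
    start = GenomicRanges::start(dom_flat) - 1L,
    end = GenomicRanges::end(dom_flat),
    gene_id = rep(names(domains), S4Vectors::elementNROWS(domains)),
    stringsAsFactors = FALSE)
  write.table(dom_df, pth(cfg, "domains.bed"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(links, pth(cfg, "peak_gene_links.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(baseline = baseline, daps = daps, domains = domains, links = links)
}

stage_integrate <- function(cfg) {
  calls_a <- read_de_calls(cfg, cfg$regions[1])
  calls_b <- read_de_calls(cfg, cfg$regions[2])
  clusters <- read_clusters(require_upstream(
    cfg, paste0("clusters_", cfg$regions[1], ".tsv"), "cluster"))
  edges <- read_trn_edges(require_upstream(cfg, "trn_edges.tsv", "trn"))
  links <- read.delim(require_upstream(cfg, "peak_gene_links.tsv",
                                       "chromatin"),
                      stringsAsFactors = FALSE)
  dap120 <- read.delim(require_upstream(cfg, "dap_calls_t120.tsv",
                                        "chromatin"),
                       stringsAsFactors = FALSE)

  enr <- adjust_and_call(
    tf_cluster_enrichment(edges, split(clusters$gene, clusters$cluster),
                          min_targets = cfg$min_targets),
    alpha = cfg$enrich_fdr, method = cfg$enrich_method)

  universe <- intersect(calls_a$table$gene_id, unique(links$gene_id))
  dap_genes <- unique(links$gene_id[links$peak_id %in%
                                    dap120$peak_id[dap120$call != "none"]])
  ov <- overlap_test(intersect(calls_a$degx, universe),
                     intersect(dap_genes, universe), universe)
  dd <- dapdegx(calls_a$degx, dap120, links)
  disc <- find_discordant(calls_a, calls_b, time_min = 120,
                          alpha = cfg$deg_fdr)

  write.table(enr, pth(cfg, "tf_cluster_enrichment.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene = dd), pth(cfg, "dapdegx.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(disc$discordant, pth(cfg, "discordant_genes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ov, pth(cfg, "degx_dap_overlap.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  list(enrichment = enr, overlap = ov, dapdegx = dd, discordant = disc)
}

write_manifest <- function(cfg, stages) {
  files <- setdiff(list.files(cfg$outdir), "manifest.json")
  manifest <- list(
    package = "genomewaves",
    version = as.character(packageVersion("genomewaves")),
    seed = cfg$seed,
    stages = stages,
    config = unclass(cfg)[order(names(unclass(cfg)))],
    files = as.list(tools::md5sum(file.path(cfg$outdir, files))))
  names(manifest$files) <- files
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
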