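#' Simulation configuration
#'
#' Bundles the parameters of the synthetic count generator: gene/TF
#' counts, replicates per (treatment, time) cell, the baseline abundance
#' distribution (log2 CPM scale), the negative-binomial dispersion and
#' the library-size range. A seed is mandatory — every generator in the
#' package is fully deterministic given its seed.
#'
#' @param n_genes number of genes (>= 2).
#' @param n_tfs number of transcription factors among them.
#' @param n_per_cell replicates per (treatment, time) cell (default 5,
#'   matching a 10-animals-per-time-point design split over two groups).
#' @param baseline_mean,baseline_sd normal parameters of per-gene baseline
#'   log2 CPM.
#' @param phi negative-binomial dispersion (variance mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param lib_size_range library sizes are drawn log-uniformly from this
#'   range (default 0.5e6 to 2e6, so TMM is exercised non-trivially).
#' @param time_levels time points in minutes.
#' @param seed RNG seed (required).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000, n_tfs = 20, n_per_cell = 5,
                       baseline_mean = 5, baseline_sd = 2, phi = 0.1,
                       lib_size_range = c(0.5e6, 2e6),
                       time_levels = c(30L, 60L, 120L), seed) {
  if (missing(seed)) stop2("sim_config requires an explicit seed")
  if (n_genes < 2 || n_tfs < 0 || n_per_cell < 1)
    stop2("all sizes must be >= 1 (n_genes >= 2)")
  if (phi < 0) stop2("phi must be >= 0")
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_per_cell = as.integer(n_per_cell),
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 phi = phi, lib_size_range = lib_size_range,
                 time_levels = as.integer(time_levels),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted temporal cluster specification
#'
#' @param profiles named list of log2 fold-change vectors (one value per
#'   time level) defining each cluster's treatment-response profile.
#' @param members named list (same names) of member gene ids; disjoint.
#' @param jitter_sd per-gene, per-time normal jitter around the cluster
#'   profile (log2 scale, default 0.2).
#' @return a `planted_clusters` list.
#' @export
planted_clusters <- function(profiles, members, jitter_sd = 0.2) {
  stopifnot(identical(names(profiles), names(members)))
  if (!all(vapply(profiles, function(p) all(is.finite(p)), logical(1))))
    stop2("profiles must be finite")
  all_members <- unlist(members)
  if (anyDuplicated(all_members))
    stop2("cluster members must be disjoint")
  structure(list(profiles = profiles, members = members,
                 jitter_sd = jitter_sd),
            class = "planted_clusters")
}

#' Planted TF-target regulatory program
#'
#' A linear program on the log2 scale: each TF has a latent per-sample
#' activity z ~ N(0, activity_sd) that is written into the TF's own
#' expression row (so TF-target dependence is visible to expression-only
#' network inference), and each target receives the weighted sum of its
#' regulators' activities plus Gaussian noise.
#'
#' @param edges data frame with columns `tf`, `target`, `weight`.
#' @param noise_sd per-target noise sd (log2 scale): scalar or named by
#'   target.
#' @param activity_sd sd of latent TF activities (log2 scale, default 2:
#'   responsive TFs swing several-fold across samples).
#' @return a `regulatory_program` list.
#' @export
regulatory_program <- function(edges, noise_sd, activity_sd = 2) {
  stopifnot(all(c("tf", "target", "weight") %in% names(edges)))
  if (any(edges$tf == edges$target)) stop2("self-edges are not allowed")
  if (any(!is.finite(edges$weight))) stop2("weights must be finite")
  if (anyDuplicated(edges[c("tf", "target")]))
    stop2("duplicate tf-target edge")
  structure(list(edges = edges, noise_sd = noise_sd,
                 activity_sd = activity_sd,
                 tfs = unique(edges$tf), targets = unique(edges$target)),
            class = "regulatory_program")
}

#' Random regulatory program with mostly single-regulator targets
#'
#' Default program generator for recovery studies: every target gets one
#' regulator (or two, with probability `p_two_tf`) with weight magnitudes
#' uniform in `weight_range` and random signs; each target's noise sd is
#' `noise_frac` of its regulatory signal sd, so the planted prediction
#' error sits well inside the network's RMSD gate.
#'
#' @param tf_ids,target_ids id vectors (disjoint).
#' @param weight_range magnitude range of edge weights.
#' @param p_two_tf probability a target has two regulators.
#' @param noise_frac target noise sd as a fraction of its signal sd.
#' @param activity_sd latent TF activity sd (log2 scale).
#' @param seed RNG seed.
#' @return a `regulatory_program`.
#' @export
make_regulatory_program <- function(tf_ids, target_ids,
                                    weight_range = c(0.5, 1),
                                    p_two_tf = 0.15, noise_frac = 0.25,
                                    activity_sd = 2, seed = 1L) {
  set.seed(seed)
  rows <- lapply(target_ids, function(tg) {
    k <- 1L + rbinom(1, 1, p_two_tf)
    tfs <- sample(tf_ids, k)
    w <- runif(k, weight_range[1], weight_range[2]) *
      sample(c(-1, 1), k, replace = TRUE)
    data.frame(tf = tfs, target = tg, weight = w, stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  sig_sd <- vapply(split(edges$weight, edges$target),
                   function(w) activity_sd * sqrt(sum(w^2)), numeric(1))
  regulatory_program(edges, noise_sd = noise_frac * sig_sd[target_ids],
                     activity_sd = activity_sd)
}

#' Simulate a toy annotated genome
#'
#' Places non-overlapping genes (1-3 transcripts each) along chromosomes
#' with intergenic gaps drawn from a two-component uniform mixture, so a
#' controllable fraction of gaps falls below the 20 kb domain window and
#' exercises domain truncation.
#'
#' @param n_chrom number of chromosomes.
#' @param n_genes number of genes (>= 2).
#' @param spacing list with `p_short`, `short = c(lo, hi)`,
#'   `long = c(lo, hi)` gap ranges in bp; all bounds must be positive.
#' @param gene_length range of gene span lengths in bp.
#' @param seed RNG seed.
#' @return a `gene_models` table with a `chrom_lengths` attribute.
#' @export
simulate_genome <- function(n_chrom = 2, n_genes = 100,
                            spacing = list(p_short = 0.3,
                                           short = c(5e3, 1.5e4),
                                           long = c(2.5e4, 1e5)),
                            gene_length = c(1e3, 1e4), seed = 1L) {
  if (n_genes < 2) stop2("n_genes must be >= 2")
  if (any(c(spacing$short, spacing$long) <= 0) ||
      spacing$p_short < 0 || spacing$p_short > 1)
    stop2("spacing distribution admits non-positive gaps")
  set.seed(seed)
  per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
  rows <- list()
  lens <- setNames(integer(n_chrom), paste0("chr", seq_len(n_chrom)))
  gi <- 0L
  for (ch in seq_len(n_chrom)) {
    pos <- 0L
    for (j in seq_len(per_chrom[ch])) {
      gi <- gi + 1L
      gap <- if (runif(1) < spacing$p_short)
        runif(1, spacing$short[1], spacing$short[2]) else
        runif(1, spacing$long[1], spacing$long[2])
      start <- pos + as.integer(round(gap))
      len <- as.integer(round(runif(1, gene_length[1], gene_length[2])))
      end <- start + len - 1L
      strand <- sample(c("+", "-"), 1)
      gene <- sprintf("g%04d", gi)
      ntx <- sample(1:3, 1)
      tx <- data.frame(gene_id = gene,
                       transcript_id = sprintf("%s.t%d", gene, seq_len(ntx)),
                       chrom = names(lens)[ch], strand = strand,
                       start = start, end = end,
                       stringsAsFactors = FALSE)
      if (ntx > 1) {
        for (t in 2:ntx) {
          tx$start[t] <- start + as.integer(round(runif(1, 0, len / 3)))
          tx$end[t] <- end - as.integer(round(runif(1, 0, len / 3)))
        }
      }
      rows[[gi]] <- tx
      pos <- end
    }
    lens[ch] <- pos + 50000L
  }
  gene_models(do.call(rbind, rows), chrom_lengths = lens)
}

#' Simulate a time-course count matrix with planted structure
#'
#' Draws negative-binomial counts whose mean structure is exactly the
#' nested interaction model fitted downstream: on the log2 scale, gene g
#' in sample i has mean
#' baseline_g + log2(library scaling) + treatment_i x profile_c(g)(time_i)
#' + regulatory-program input, with NB dispersion phi around that mean.
#' Returns the counts together with ground-truth tables sufficient to
#' score differential-expression recall, cluster recovery and network
#' precision/recall.
#'
#' @param cfg a `sim_config`.
#' @param clusters optional `planted_clusters` (treatment-response
#'   profiles).
#' @param program optional `regulatory_program`.
#' @param region region label written into the design.
#' @param gene_ids optional gene id vector (default g0001..).
#' @return list with `cm` (`count_matrix` with design) and `truth`
#'   (list: `degx`, `cluster` data frame with per-gene true profiles,
#'   `edges`, `tf_activity`).
#' @export
simulate_expression <- function(cfg, clusters = NULL, program = NULL,
                                region = "diencephalon", gene_ids = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  genes <- gene_ids %||% sprintf("g%04d", seq_len(cfg$n_genes))
  tl <- cfg$time_levels
  design <- sample_design(
    sample_id = paste0(substr(region, 1, 1), "_",
                       rep(rep(c("ctrl", "exp"), each = cfg$n_per_cell),
                           length(tl)), "_t",
                       rep(tl, each = 2 * cfg$n_per_cell), "_r",
                       rep(seq_len(cfg$n_per_cell), 2 * length(tl))),
    region = region,
    treatment = rep(rep(c("control", "experimental"),
                        each = cfg$n_per_cell), length(tl)),
    time_min = rep(tl, each = 2 * cfg$n_per_cell),
    time_levels = tl)
  n <- nrow(design)

  baseline <- rnorm(cfg$n_genes, cfg$baseline_mean, cfg$baseline_sd)
  lib <- exp(runif(n, log(cfg$lib_size_range[1]),
                   log(cfg$lib_size_range[2])))

  log2mu <- matrix(baseline, cfg$n_genes, n,
                   dimnames = list(genes, design$sample_id))

  # planted treatment-response profiles
  true_profile <- matrix(0, cfg$n_genes, length(tl),
                         dimnames = list(genes, paste0("lfc_", tl)))
  cluster_of <- setNames(rep(NA_character_, cfg$n_genes), genes)
  if (!is.null(clusters)) {
    for (cl in names(clusters$members)) {
      mem <- clusters$members[[cl]]
      if (!all(mem %in% genes)) stop2("cluster members outside gene set")
      prof <- clusters$profiles[[cl]]
      for (g in mem) {
        true_profile[g, ] <- prof + rnorm(length(tl), 0, clusters$jitter_sd)
        cluster_of[g] <- cl
      }
    }
    is_exp <- design$treatment == "experimental"
    tidx <- match(design$time_min, tl)
    for (i in which(is_exp)) {
      log2mu[, i] <- log2mu[, i] + true_profile[, tidx[i]]
    }
  }

  # regulatory program: latent TF activities drive TF and target rows
  z <- NULL
  if (!is.null(program)) {
    if (!all(c(program$tfs, program$targets) %in% genes))
      stop2("program genes outside gene set")
    z <- matrix(rnorm(length(program$tfs) * n, 0, program$activity_sd),
                length(program$tfs), n,
                dimnames = list(program$tfs, design$sample_id))
    log2mu[program$tfs, ] <- log2mu[program$tfs, , drop = FALSE] + z
    noise <- program$noise_sd
    if (is.null(names(noise))) noise <- setNames(
      rep_len(noise, length(program$targets)), program$targets)
    for (tg in program$targets) {
      e <- program$edges[program$edges$target == tg, ]
      contrib <- colSums(z[e$tf, , drop = FALSE] * e$weight)
      log2mu[tg, ] <- log2mu[tg, ] + contrib + rnorm(n, 0, noise[tg])
    }
  }

  mu <- 2^log2mu * matrix(lib / 1e6, cfg$n_genes, n, byrow = TRUE)
  counts <- if (cfg$phi == 0) {
    matrix(rpois(length(mu), mu), nrow(mu), dimnames = dimnames(mu))
  } else {
    matrix(rnbinom(length(mu), size = 1 / cfg$phi, mu = mu), nrow(mu),
           dimnames = dimnames(mu))
  }

  truth <- list(
    degx = genes[rowSums(true_profile != 0) > 0],
    cluster = data.frame(gene = genes, cluster = cluster_of,
                         true_profile, stringsAsFactors = FALSE,
                         row.names = NULL),
    edges = if (is.null(program)) NULL else program$edges,
    tf_activity = z)
  list(cm = count_matrix(counts, design), truth = truth)
}

#' Default planted differential-expression scenario
#'
#' The study-default synthetic conditions for scoring the differential-
#' expression chain: `planted_frac` of the genes receive one of four
#' temporal treatment-response profiles with entries of magnitude `lfc`
#' (log2), with 5 replicates per design cell and NB dispersion 0.1.
#' `planted_frac = 0` gives the null scenario used for FDR calibration.
#'
#' @param seed RNG seed.
#' @param n_genes genes simulated.
#' @param planted_frac fraction of genes with a planted profile.
#' @param lfc planted log2 fold-change magnitude.
#' @param n_per_cell replicates per (treatment, time) cell.
#' @param phi NB dispersion.
#' @param region region label.
#' @return the [simulate_expression()] result (`cm` + `truth`), with the
#'   planted cluster spec attached as `clusters`.
#' @export
sim_de_scenario <- function(seed, n_genes = 2000, planted_frac = 0.1,
                            lfc = 2, n_per_cell = 5, phi = 0.1,
                            region = "diencephalon") {
  cfg <- sim_config(n_genes = n_genes, n_per_cell = n_per_cell, phi = phi,
                    seed = seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  clusters <- NULL
  if (planted_frac > 0) {
    n_planted <- round(planted_frac * n_genes)
    profs <- list(c1 = c(lfc, 0, lfc), c2 = c(-lfc, -lfc, 0),
                  c3 = c(0, 0, lfc), c4 = c(0, lfc, -lfc))
    mem <- split(genes[seq_len(n_planted)],
                 rep(names(profs), length.out = n_planted))
    clusters <- planted_clusters(profs, mem[names(profs)])
  }
  out <- simulate_expression(cfg, clusters = clusters, region = region,
                             gene_ids = genes)
  out$clusters <- clusters
  out
}

#' Two-region scenario with planted discordant genes
#'
#' Simulates matched diencephalon/telencephalon count matrices sharing
#' `n_discordant` genes whose late (120 min) response has opposite signs
#' in the two regions, and `n_concordant` genes responding identically in
#' both, on a background of unaffected genes. Expression is strong and
#' dispersion moderate so the planted genes are detected with power close
#' to one, making exact recovery a meaningful check.
#'
#' @param seed RNG seed.
#' @param n_genes total genes.
#' @param n_discordant,n_concordant planted shared genes.
#' @param lfc planted log2 fold-change magnitude.
#' @return list with `cm_a`, `cm_b` (count matrices),
#'   `discordant`, `concordant` (gene id vectors).
#' @export
sim_discordant_scenario <- function(seed, n_genes = 800,
                                    n_discordant = 10,
                                    n_concordant = 50, lfc = 2) {
  genes <- sprintf("g%04d", seq_len(n_genes))
  disc <- genes[seq_len(n_discordant)]
  conc <- genes[n_discordant + seq_len(n_concordant)]
  half <- seq_len(ceiling(n_concordant / 2))
  conc_up <- conc[half]; conc_dn <- setdiff(conc, conc_up)
  cl_a <- planted_clusters(
    list(disc = c(0, 0, lfc), up = c(lfc, 0, lfc), dn = c(0, -lfc, -lfc)),
    list(disc = disc, up = conc_up, dn = conc_dn))
  cl_b <- planted_clusters(
    list(disc = c(0, 0, -lfc), up = c(lfc, 0, lfc), dn = c(0, -lfc, -lfc)),
    list(disc = disc, up = conc_up, dn = conc_dn))
  mk <- function(region, cl, sub) {
    cfg <- sim_config(n_genes = n_genes, n_per_cell = 5, phi = 0.05,
                      baseline_mean = 8, baseline_sd = 1,
                      seed = derive_seed(seed, sub))
    simulate_expression(cfg, clusters = cl, region = region,
                        gene_ids = genes)
  }
  list(cm_a = mk("diencephalon", cl_a, "region_a")$cm,
       cm_b = mk("telencephalon", cl_b, "region_b")$cm,
       discordant = disc, concordant = conc)
}

#' Planted-program scenario for network-inference recovery studies
#'
#' Convenience wrapper bundling the default network-recovery study
#' conditions: 20 TFs regulating 200 targets (weights of magnitude 0.5-1,
#' mostly one regulator per target) across 60 samples, with per-target
#' regulatory noise one quarter of the signal sd. Libraries are deep and
#' dispersion low so that the planted noise level — which the prediction-
#' error gate is calibrated against — is not distorted by count-level
#' measurement noise.
#'
#' @param seed RNG seed.
#' @param n_tfs,n_targets program size.
#' @param n_per_cell replicates per design cell (10 gives 60 samples).
#' @param n_fillers stably expressed non-program genes included so that
#'   library-size and TMM estimation rest on a realistic stable majority
#'   of the transcriptome rather than on the swinging program genes.
#' @param ... overrides passed to [make_regulatory_program()].
#' @return list with `expr` (log2 expression matrix), `tfs`, `truth`
#'   (edge data frame) and the underlying `sim` object.
#' @export
sim_trn_scenario <- function(seed, n_tfs = 20, n_targets = 200,
                             n_per_cell = 10, n_fillers = 400, ...) {
  tfs <- sprintf("tf%03d", seq_len(n_tfs))
  targets <- sprintf("tg%04d", seq_len(n_targets))
  fillers <- if (n_fillers > 0) sprintf("fl%04d", seq_len(n_fillers))
  program <- make_regulatory_program(
    tfs, targets, seed = derive_seed(seed, "program"), ...)
  cfg <- sim_config(n_genes = n_tfs + n_targets + n_fillers, n_tfs = n_tfs,
                    n_per_cell = n_per_cell, phi = 5e-4,
                    baseline_mean = 11, baseline_sd = 0.25,
                    lib_size_range = c(2e6, 3e6),
                    seed = derive_seed(seed, "expr"))
  sim <- simulate_expression(cfg, program = program,
                             gene_ids = c(tfs, targets, fillers))
  list(expr = expression_profiles(sim$cm), tfs = tfs,
       truth = program$edges, sim = sim)
}

#' Simulate ChIP tag tables with planted accessibility structure
#'
#' Places one candidate peak at each gene's TSS plus intergenic decoys,
#' then draws Poisson tag counts for an input library and the four
#' condition libraries (control/experimental at 30 and 120 minutes).
#' A configurable fraction of gene peaks is baseline accessible (mean
#' tags several-fold over input); `dap_spec` rows plant differential
#' accessibility of a requested fold and direction at a requested time.
#'
#' @param gm `gene_models` (e.g. from [simulate_genome()]).
#' @param dap_spec data frame with columns `gene`, `time` (30 or 120),
#'   `direction` (`"up"`/`"down"`), `fold` (> 0).
#' @param depth mean tag count of an accessible peak (default 100).
#' @param p_baseline fraction of gene peaks accessible at baseline.
#' @param decoy_frac intergenic decoy peaks per gene peak.
#' @param seed RNG seed.
#' @return list with `peaks` (a `peak_table` with tag columns `input`,
#'   `ctrl_30`, `exp_30`, `ctrl_120`, `exp_120`) and `truth`
#'   (`baseline` logical; `dap_30`, `dap_120` named direction vectors).
#' @export
simulate_chip <- function(gm, dap_spec = NULL, depth = 100,
                          p_baseline = 0.7, decoy_frac = 0.2, seed = 1L) {
  if (!is.null(dap_spec)) {
    if (any(dap_spec$fold <= 0)) stop2("requested fold must be > 0")
    if (!all(dap_spec$gene %in% gm$gene_id))
      stop2("dap_spec gene(s) not in genome: ",
            paste(setdiff(dap_spec$gene, gm$gene_id), collapse = ", "))
    if (!all(dap_spec$time %in% c(30, 120)))
      stop2("dap_spec time must be 30 or 120")
  }
  set.seed(seed)
  first_tx <- gm[!duplicated(gm$gene_id), ]
  tss <- transcript_tss(first_tx)
  peaks <- data.frame(chrom = first_tx$chrom,
                      start = pmax(1L, as.integer(tss - 500L)),
                      end = as.integer(tss + 499L),
                      peak_id = paste0("pk_", first_tx$gene_id),
                      stringsAsFactors = FALSE)
  # intergenic decoys midway between consecutive genes
  n_decoy <- round(decoy_frac * nrow(first_tx))
  if (n_decoy > 0) {
    ord <- order(first_tx$chrom, first_tx$start)
    same <- which(diff(as.integer(factor(first_tx$chrom[ord]))) == 0)
    if (length(same)) {
      pick <- sample(same, min(n_decoy, length(same)))
      mid <- as.integer((first_tx$end[ord][pick] +
                         first_tx$start[ord][pick + 1]) / 2)
      peaks <- rbind(peaks, data.frame(
        chrom = first_tx$chrom[ord][pick],
        start = pmax(1L, mid - 500L), end = mid + 499L,
        peak_id = paste0("decoy_", seq_along(pick)),
        stringsAsFactors = FALSE))
    }
  }
  np <- nrow(peaks)
  lambda_in <- depth / 8
  accessible <- c(runif(nrow(first_tx)) < p_baseline,
                  rep(FALSE, np - nrow(first_tx)))
  base_mean <- ifelse(accessible, depth, lambda_in)
  means <- list(input = rep(lambda_in, np),
                ctrl_30 = base_mean, exp_30 = base_mean,
                ctrl_120 = base_mean, exp_120 = base_mean)
  truth_dap <- list(`30` = character(), `120` = character())
  if (!is.null(dap_spec)) {
    for (r in seq_len(nrow(dap_spec))) {
      pid <- paste0("pk_", dap_spec$gene[r])
      idx <- match(pid, peaks$peak_id)
      col <- paste0("exp_", dap_spec$time[r])
      if (dap_spec$direction[r] == "up") {
        # gain of accessibility: quiescent at baseline, opens on challenge
        accessible[idx] <- FALSE
        for (nm in setdiff(names(means), "input"))
          means[[nm]][idx] <- lambda_in
        means[[col]][idx] <- lambda_in * dap_spec$fold[r]
      } else {
        # loss of accessibility from an accessible baseline peak
        accessible[idx] <- TRUE
        for (nm in setdiff(names(means), "input"))
          means[[nm]][idx] <- depth
        means[[col]][idx] <- depth / dap_spec$fold[r]
      }
      truth_dap[[as.character(dap_spec$time[r])]] <-
        c(truth_dap[[as.character(dap_spec$time[r])]],
          setNames(dap_spec$direction[r], pid))
    }
  }
  for (nm in names(means)) peaks[[nm]] <- rpois(np, means[[nm]])
  pt <- peak_table(peaks, tag_cols = names(means))
  list(peaks = pt,
       truth = list(baseline = setNames(accessible, peaks$peak_id),
                    dap_30 = truth_dap[["30"]],
                    dap_120 = truth_dap[["120"]]))
}
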