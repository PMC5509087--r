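#' Hypergeometric enrichment of a unit's targets in a gene cluster
#'
#' Upper-tail hypergeometric test of the overlap k between a unit's
#' target set (size K) and a cluster (size n) drawn from a universe of
#' size N: p = P(X >= k). Units with fewer than `min_targets` targets in
#' the universe are skipped (returned with `skipped = TRUE`), mirroring
#' the minimum-target rule for TF-cluster enrichment.
#'
#' @param unit_targets gene ids regulated by the unit (TF).
#' @param cluster gene ids in the cluster.
#' @param universe all eligible gene ids (targets and cluster are
#'   restricted to it).
#' @param min_targets minimum K for the unit to be tested (default 3).
#' @return one-row data frame: K, n, N, k, p, skipped.
#' @export
hypergeom_enrichment <- function(unit_targets, cluster, universe,
                                 min_targets = 3) {
  universe <- unique(universe)
  if (!length(universe)) stop2("empty universe")
  targets <- intersect(unique(unit_targets), universe)
  cl <- intersect(unique(cluster), universe)
  K <- length(targets); n <- length(cl); N <- length(universe)
  k <- length(intersect(targets, cl))
  skipped <- K < min_targets
  p <- if (skipped) NA_real_ else
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  data.frame(K = K, n = n, N = N, k = k, p = p, skipped = skipped)
}

#' Enrichment of every TF's targets in every cluster
#'
#' @param trn a `trn` (or a data frame of edges with columns tf, target).
#' @param clusters named list of gene-id vectors (cluster members).
#' @param universe gene universe; defaults to all TRN targets.
#' @param min_targets minimum targets per TF (default 3).
#' @return data frame with one row per tested (tf, cluster) pair.
#' @export
tf_cluster_enrichment <- function(trn, clusters, universe = NULL,
                                  min_targets = 3) {
  edges <- if (inherits(trn, "trn")) trn$edges else trn
  targets_by_tf <- split(edges$target, edges$tf)
  if (is.null(universe)) universe <- unique(edges$target)
  res <- list()
  for (tf in names(targets_by_tf)) {
    for (cl in names(clusters)) {
      r <- hypergeom_enrichment(targets_by_tf[[tf]], clusters[[cl]],
                                universe, min_targets)
      if (r$skipped) next
      res[[length(res) + 1L]] <- cbind(
        data.frame(tf = tf, cluster = cl, stringsAsFactors = FALSE), r)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(tf = character(), cluster = character(), K = integer(),
               n = integer(), N = integer(), k = integer(), p = numeric(),
               skipped = logical())
  rownames(out) <- NULL
  out
}

#' Multiple-testing adjustment over a family of enrichment tests
#'
#' Adjusts the p-values of an enrichment table over the full family of
#' tested pairs and flags significance at `alpha`. Default method is
#' Benjamini-Hochberg; `"bonferroni"` is available.
#'
#' @param results data frame with a `p` column (e.g. from
#'   [tf_cluster_enrichment()]).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @param method `"BH"` (default) or `"bonferroni"`.
#' @return `results` with `p_adj` and logical `significant` columns.
#' @export
adjust_and_call <- function(results, alpha = 0.05, method = "BH") {
  results$p_adj <- p.adjust(results$p, method = method)
  results$significant <- !is.na(results$p_adj) & results$p_adj < alpha
  results
}

#' Hypergeometric overlap test between two gene sets
#'
#' Upper-tail hypergeometric p for the observed intersection of two sets
#' within a universe; symmetric in its arguments. Used e.g. to test the
#' overlap between interaction-significant genes (DEGx) and genes linked
#' to differentially accessible peaks.
#'
#' @param set_a,set_b gene id vectors.
#' @param universe gene universe (typically all expressed,
#'   domain-annotated genes).
#' @return one-row data frame: K (|A|), n (|B|), N, k (|A and B|), p,
#'   with the intersection as attribute `intersection`.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop2("empty universe")
  a <- intersect(unique(set_a), universe)
  b <- intersect(unique(set_b), universe)
  k <- length(intersect(a, b))
  p <- phyper(k - 1, length(a), length(universe) - length(a), length(b),
              lower.tail = FALSE)
  structure(data.frame(K = length(a), n = length(b), N = length(universe),
                       k = k, p = p),
            intersection = intersect(a, b))
}

#' Genes regulated in opposite directions across brain regions
#'
#' Finds genes differentially expressed in both regions at one time point
#' (treatment-within-time q below `alpha` in each region) whose log2 fold
#' changes have opposite signs — the "discordant genes" pattern. Also
#' reports all shared DE genes at that time and the cross-region
#' correlation of their fold changes.
#'
#' @param calls_a,calls_b `deg_calls` for the two regions.
#' @param time_min time point to compare (default 120).
#' @param alpha per-region FDR threshold (default 0.1).
#' @return list with `discordant` (gene, lfc_a, lfc_b, q_a, q_b),
#'   `shared` (all genes DE in both regions at that time) and
#'   `correlation` (cross-region log2FC correlation among shared genes).
#' @export
find_discordant <- function(calls_a, calls_b, time_min = 120, alpha = 0.1) {
  pick <- function(calls) {
    tab <- calls$table
    data.frame(gene = tab$gene_id,
               lfc = tab[[paste0("lfc_", time_min)]],
               q = tab[[paste0("q_", time_min)]],
               stringsAsFactors = FALSE)
  }
  a <- pick(calls_a); b <- pick(calls_b)
  m <- merge(a, b, by = "gene", suffixes = c("_a", "_b"))
  de_both <- !is.na(m$q_a) & !is.na(m$q_b) & m$q_a < alpha & m$q_b < alpha
  shared <- m[de_both, ]
  disc <- shared[sign(shared$lfc_a) != sign(shared$lfc_b), ]
  rownames(shared) <- rownames(disc) <- NULL
  corr <- if (nrow(shared) >= 3) cor(shared$lfc_a, shared$lfc_b) else NA_real_
  list(discordant = disc, shared = shared, correlation = corr,
       time_min = time_min, alpha = alpha)
}

#' Interaction-significant genes linked to differential accessibility
#'
#' DAPDEGx: the genes in the DEGx set whose chromatin domain overlaps at
#' least one peak called differentially accessible at the queried time.
#'
#' @param degx gene ids with a significant time-by-treatment interaction.
#' @param dap_calls data frame from [call_differential()].
#' @param links peak-gene link table from [assign_peaks()].
#' @return character vector of DAPDEGx gene ids.
#' @export
dapdegx <- function(degx, dap_calls, links) {
  dap_ids <- dap_calls$peak_id[dap_calls$call != "none"]
  dap_genes <- unique(links$gene_id[links$peak_id %in% dap_ids])
  intersect(degx, dap_genes)
}
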