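#' Ward hierarchical clustering of temporal fold-change profiles
#'
#' Agglomerative clustering of per-gene log2 fold-change profiles over the
#' time course using the classical Ward objective ("ward.D"): at each step
#' the pair of clusters whose merge minimally increases the Lance-Williams
#' updated distance is joined. By default the Euclidean distance matrix is
#' used unsquared, mirroring the ward.D variant; squared distances are
#' available via `squared = TRUE`.
#'
#' @param profiles numeric matrix, genes x time points, finite entries,
#'   rownames = gene ids.
#' @param squared apply ward.D to squared Euclidean distances?
#' @return an `hclust` object (merge sequence, non-decreasing heights,
#'   leaf order).
#' @export
ward_cluster <- function(profiles, squared = FALSE) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) stop2("need >= 2 profiles to cluster")
  if (any(!is.finite(profiles))) stop2("profiles contain non-finite values")
  d <- dist(profiles)
  if (squared) d <- d^2
  hclust(d, method = "ward.D")
}

#' Cut a dendrogram into clusters
#'
#' Exactly one of `k` (number of clusters) or `height` (remove merges
#' above this height) must be given. Cluster labels are renumbered by
#' decreasing cluster size, ties broken by smallest member index, so
#' cluster 1 is always the largest.
#'
#' @param dend an `hclust` object.
#' @param k number of clusters.
#' @param height cut height.
#' @return integer vector of cluster labels named by row id.
#' @export
cut_tree <- function(dend, k = NULL, height = NULL) {
  if (is.null(k) == is.null(height))
    stop2("give exactly one of k or height")
  n <- length(dend$order)
  if (!is.null(k) && k > n) stop2("k = ", k, " exceeds ", n, " leaves")
  raw <- if (!is.null(k)) cutree(dend, k = k) else cutree(dend, h = height)
  relabel_by_size(raw)
}

relabel_by_size <- function(raw) {
  sizes <- table(raw)
  first_idx <- tapply(seq_along(raw), raw, min)
  ord <- order(-as.integer(sizes), as.integer(first_idx))
  map <- integer(length(sizes))
  map[as.integer(names(sizes))[ord]] <- seq_along(ord)
  out <- map[raw]
  names(out) <- names(raw)
  out
}

#' Summarize clusters of temporal profiles
#'
#' Computes per-cluster mean log2 fold-change profiles and a verbal
#' pattern code per time point: "up" or "down" by the sign of the mean,
#' "no change" when its magnitude is below `flat`.
#'
#' @param assign integer cluster labels named by gene (from [cut_tree()]).
#' @param profiles genes x time matrix matching `assign`.
#' @param flat absolute mean log2FC below which a time point is coded
#'   "no change" (default 0.1).
#' @return list with `means` (cluster x time matrix), `pattern`
#'   (named character, e.g. "no change, down, up"), `members` (list of
#'   gene ids), `table` (tidy gene/cluster/lfc table for export).
#' @export
summarize_clusters <- function(assign, profiles, flat = 0.1) {
  profiles <- as.matrix(profiles)
  if (is.null(names(assign))) names(assign) <- rownames(profiles)
  if (!all(rownames(profiles) %in% names(assign)))
    stop2("assignments must cover all profile rows")
  assign <- assign[rownames(profiles)]
  means <- rowsum(profiles, assign) / as.vector(table(assign))
  pattern <- apply(means, 1, function(m)
    paste(ifelse(abs(m) < flat, "no change",
                 ifelse(m > 0, "up", "down")), collapse = ", "))
  members <- split(rownames(profiles), assign)
  tab <- data.frame(gene = rownames(profiles),
                    cluster = as.integer(assign),
                    stringsAsFactors = FALSE)
  lfc <- as.data.frame(profiles)
  names(lfc) <- paste0("lfc_", sub("^lfc_", "", names(lfc)))
  tab <- cbind(tab, lfc)
  rownames(tab) <- NULL
  list(means = means, pattern = pattern, members = members, table = tab)
}

#' Export a dendrogram in Newick format
#'
#' @param dend an `hclust` object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(dend, path) {
  ape::write.tree(ape::as.phylo(dend), file = path)
  invisible(path)
}
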