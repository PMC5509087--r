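# Independent brute-force oracles used to check the implementation.
# These deliberately share no code with the package internals.

# step-by-step TMM factor for one column pair, written from the published
# algorithm description with explicit sorting instead of rank arithmetic
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  keep0 <- obs > 0 & ref > 0
  obs <- obs[keep0]; ref <- ref[keep0]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  rm_ <- rank(M); ra_ <- rank(A)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra_ >= lo_a & ra_ <= hi_a
  2^(sum((M / w)[keep]) / sum((1 / w)[keep]))
}

oracle_tmm <- function(counts, ref_col) {
  lib <- colSums(counts)
  f <- vapply(seq_len(ncol(counts)), function(i)
    oracle_tmm_pair(counts[, i], counts[, ref_col], lib[i], lib[ref_col]),
    numeric(1))
  f / exp(mean(log(f)))
}

# naive O(n^3) agglomerative clustering with the ward.D Lance-Williams
# update; returns the sorted merge heights
oracle_ward_heights <- function(x) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  active <- seq_len(n)
  sizes <- rep(1, n)
  heights <- numeric(0)
  repeat {
    if (length(active) == 1) break
    best <- c(Inf, NA, NA)
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < best[1]) best <- c(d[i, j], i, j)
    }
    i <- best[2]; j <- best[3]
    heights <- c(heights, best[1])
    for (k in setdiff(active, c(i, j))) {
      ni <- sizes[i]; nj <- sizes[j]; nk <- sizes[k]
      dn <- ((ni + nk) * d[i, k] + (nj + nk) * d[j, k] -
               nk * d[i, j]) / (ni + nj + nk)
      d[i, k] <- d[k, i] <- dn
    }
    sizes[i] <- sizes[i] + sizes[j]
    active <- setdiff(active, j)
  }
  heights
}

# literal Benjamini-Hochberg by its definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- vapply(seq(i, m), function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(cand))
  }
  q
}

oracle_bonferroni <- function(p) pmin(1, p * length(p))

# upper-tail hypergeometric by direct enumeration over choose()
oracle_hyper <- function(N, K, n, k) {
  tot <- choose(N, n)
  sum(vapply(k:min(K, n), function(x)
    choose(K, x) * choose(N - K, n - x), numeric(1))) / tot
}

# quadratic peak-domain overlap scan on plain interval arithmetic
# (1-based closed coordinates); domains are flattened to a plain table
# once, then every peak is compared against every domain piece
oracle_overlap_scan <- function(peaks, domains) {
  flat <- do.call(rbind, lapply(names(domains), function(g) {
    d <- domains[[g]]
    if (!length(d)) return(NULL)
    data.frame(gene_id = g,
               chrom = as.character(GenomicRanges::seqnames(d)),
               start = GenomicRanges::start(d),
               end = GenomicRanges::end(d),
               stringsAsFactors = FALSE)
  }))
  hits <- list()
  for (p in seq_len(nrow(peaks))) {
    ok <- flat$chrom == peaks$chrom[p] &
      flat$start <= peaks$end[p] & flat$end >= peaks$start[p]
    if (!any(ok)) next
    ov <- pmin(flat$end[ok], peaks$end[p]) -
      pmax(flat$start[ok], peaks$start[p]) + 1L
    agg <- rowsum(ov, flat$gene_id[ok])
    hits[[p]] <- data.frame(peak_id = peaks$peak_id[p],
                            gene_id = rownames(agg),
                            overlap_bp = as.integer(agg),
                            stringsAsFactors = FALSE)
  }
  if (!length(hits)) return(data.frame(peak_id = character(),
                                       gene_id = character(),
                                       overlap_bp = integer()))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

edge_key <- function(edges) paste(edges$tf, edges$target)
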