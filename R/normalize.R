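#' Counts per million
#'
#' @param cm `count_matrix` or plain matrix.
#' @param lib_size library sizes; defaults to column sums (optionally TMM
#'   effective sizes).
#' @param log return log2(CPM + prior)?
#' @param prior prior count added on the CPM scale before taking logs.
#' @return matrix of CPM values.
#' @export
cpm <- function(cm, lib_size = NULL, log = FALSE, prior = 0.5) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  if (is.null(lib_size)) lib_size <- colSums(m)
  if (any(lib_size <= 0)) stop2("library sizes must be positive")
  out <- t(t(m) / lib_size) * 1e6
  if (log) log2(out + prior) else out
}

#' Filter weakly expressed genes
#'
#' Keeps a gene if its CPM reaches `min_cpm` in at least `min_samples`
#' samples (boundary inclusive), computed on raw library sizes.
#'
#' @param cm `count_matrix`.
#' @param min_cpm CPM threshold (default 1).
#' @param min_samples minimum number of samples at or above the threshold
#'   (default 2).
#' @return logical vector over genes (`TRUE` = keep), named by gene id.
#' @export
filter_low_expression <- function(cm, min_cpm = 1, min_samples = 2) {
  x <- cpm(cm)
  keep <- rowSums(x >= min_cpm) >= min_samples
  names(keep) <- rownames(if (inherits(cm, "count_matrix")) cm$counts else cm)
  keep
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample scaling factors from a doubly trimmed,
#' precision-weighted mean of gene-wise log ratios against a reference
#' sample. For each sample i and reference r, genes positive in both
#' columns contribute M_g = log2((y_gi/N_i)/(y_gr/N_r)) and
#' A_g = 0.5 log2((y_gi/N_i)(y_gr/N_r)); genes in the upper/lower
#' `logratio_trim` tail of M or `abundance_trim` tail of A are discarded,
#' and the surviving M are averaged with inverse asymptotic binomial
#' variance weights. Factors are rescaled to geometric mean 1.
#'
#' @param cm `count_matrix` (typically after [filter_low_expression()]).
#' @param ref reference sample: column index/name or `"auto"` (sample
#'   whose upper-quartile relative abundance is closest to the mean).
#' @param logratio_trim tail fraction trimmed from each side of M
#'   (default 0.30).
#' @param abundance_trim tail fraction trimmed from each side of A
#'   (default 0.05).
#' @return list with `factors` (geometric mean 1), `effective_lib_size`
#'   (lib size times factor) and `ref` (reference column index).
#' @export
tmm_factors <- function(cm, ref = "auto", logratio_trim = 0.30,
                        abundance_trim = 0.05) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  lib <- colSums(m)
  if (any(lib <= 0)) stop2("reference/sample column with non-positive total")
  if (identical(ref, "auto")) {
    uq <- apply(m, 2, function(x) quantile(x, 0.75)) / lib
    ref <- which.min(abs(uq - mean(uq)))
  } else if (is.character(ref)) ref <- match(ref, colnames(m))
  ref <- as.integer(ref)
  f <- vapply(seq_len(ncol(m)), function(i) {
    tmm_pair(m[, i], m[, ref], lib[i], lib[ref],
             logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  names(f) <- colnames(m)
  list(factors = f, effective_lib_size = lib * f, ref = ref)
}

# single-pair TMM factor (ratio of column obs to column ref)
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, abundance_trim) {
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  if (!length(obs)) return(1)
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abundance_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (sum(keep) < 10) {
    warning("fewer than 10 genes survive TMM trimming; using untrimmed ",
            "weighted mean", call. = FALSE)
    keep <- rep(TRUE, n)
  }
  lf <- sum(M[keep] / w[keep]) / sum(1 / w[keep])
  if (!is.finite(lf)) lf <- 0
  2^lf
}
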