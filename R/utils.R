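#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx binom.test cor cutree dist hclust lm.fit median
#'   optimize p.adjust pchisq phyper pnbinom pgamma pbinom ppois quantile
#'   rbinom rlnorm rnbinom rnorm rpois runif sd setNames var dnbinom dpois
#' @importFrom utils read.delim write.table head packageVersion
#' @importFrom methods is
NULL

# deterministic sub-seed derived from a master seed and a stage label;
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 1000003L
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items,
#' used to score recovery of planted cluster structure.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

#' Precision and recall of a predicted set against a truth set
#'
#' @param predicted,truth character vectors (e.g. "tf->target" edge keys or
#'   gene ids).
#' @return named numeric vector with elements `precision`, `recall`, `tp`,
#'   `fp`, `fn`.
#' @export
precision_recall <- function(predicted, truth) {
  predicted <- unique(predicted)
  truth <- unique(truth)
  tp <- sum(predicted %in% truth)
  fp <- length(predicted) - tp
  fn <- length(truth) - tp
  c(precision = if (length(predicted)) tp / length(predicted) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_,
    tp = tp, fp = fp, fn = fn)
}
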