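#' Common, trended and tagwise dispersion estimates
#'
#' Estimates the negative-binomial dispersion phi (variance mu + phi mu^2)
#' shared by all genes, a smooth trend of dispersion against average
#' abundance, and per-gene (tagwise) values shrunk toward the trend.
#' All three derive from one matrix of Cox-Reid adjusted profile
#' log-likelihoods (APL) evaluated on a dispersion grid:
#'
#' * common = maximizer of the APL summed over genes (grid argmax refined
#'   by golden-section search);
#' * trend  = per-abundance-bin APL maximizer, smoothed by a running
#'   median across bins and interpolated at each gene's abundance;
#' * tagwise = per-gene maximizer of APL_g + `prior_n` x (mean APL of the
#'   gene's abundance bin), i.e. shrinkage with a prior weight equivalent
#'   to `prior_n` genes.
#'
#' @param y genes x samples count matrix (filtered).
#' @param X design matrix.
#' @param offset log effective library sizes (length n).
#' @param phi_grid dispersion grid; log-spaced by default.
#' @param n_bins abundance bins for the trend (default 20, fewer for small
#'   gene sets).
#' @param prior_n prior weight (in genes) pulling tagwise values toward
#'   the trend.
#' @return list with `common`, `trend` (per gene), `tagwise` (per gene),
#'   `abundance` (average log2 CPM) and the APL `grid`.
#' @export
estimate_dispersion <- function(y, X, offset,
                                phi_grid = exp(seq(log(1e-4), log(4),
                                                   length.out = 15)),
                                n_bins = 20, prior_n = 10) {
  y <- as.matrix(y)
  G <- nrow(y)
  apl <- vapply(phi_grid, function(phi) {
    fit <- nb_glm_fit(y, X, offset, phi = phi, tol = 1e-6, max_iter = 30L)
    val <- fit$loglik - 0.5 * fit$logdet_xtwx
    val[!is.finite(val)] <- -1e300
    val
  }, numeric(G))                      # G x length(grid)
  apl <- matrix(apl, nrow = G)
  lg <- log(phi_grid)

  # common: grid argmax refined by 1-d optimization of the summed APL
  tot <- colSums(apl)
  i0 <- which.max(tot)
  lo <- lg[max(1, i0 - 1)]; hi <- lg[min(length(lg), i0 + 1)]
  common <- if (lo == hi) phi_grid[i0] else {
    f <- function(lphi) {
      fit <- nb_glm_fit(y, X, offset, phi = exp(lphi), tol = 1e-6,
                        max_iter = 30L)
      sum(fit$loglik - 0.5 * fit$logdet_xtwx, na.rm = TRUE)
    }
    exp(optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-3)$maximum)
  }

  abundance <- rowMeans(cpm(y, lib_size = exp(offset) /
                              mean(exp(offset)) * mean(colSums(y)),
                            log = TRUE))
  n_bins <- max(1L, min(n_bins, floor(G / 10)))
  bin <- if (n_bins <= 1L) rep(1L, G) else {
    cut(rank(abundance, ties.method = "first"), n_bins, labels = FALSE)
  }

  argmax_interp <- function(v) {
    # quadratic interpolation of the maximizer on the log-phi grid
    i <- which.max(v)
    if (i == 1 || i == length(v)) return(exp(lg[i]))
    h <- (lg[i + 1] - lg[i - 1]) / 2
    den <- 2 * (v[i - 1] - 2 * v[i] + v[i + 1])
    if (den == 0) return(exp(lg[i]))
    exp(lg[i] + h * (v[i - 1] - v[i + 1]) / den)
  }

  bin_mean_apl <- rowsum(apl, bin) / as.vector(table(bin))   # bins x grid
  bin_phi <- apply(bin_mean_apl, 1, argmax_interp)
  if (length(bin_phi) >= 3) {
    bin_phi <- exp(as.numeric(stats::runmed(log(bin_phi), 3)))
  }
  bin_ab <- tapply(abundance, bin, median)
  trend <- if (length(bin_phi) == 1L) rep(bin_phi, G) else {
    exp(approx(bin_ab, log(bin_phi), xout = abundance, rule = 2)$y)
  }

  tagwise <- vapply(seq_len(G), function(g) {
    wl <- apl[g, ] + prior_n * bin_mean_apl[bin[g], ]
    argmax_interp(wl)
  }, numeric(1))
  names(tagwise) <- rownames(y)

  list(common = common, trend = trend, tagwise = tagwise,
       abundance = abundance,
       grid = list(phi = phi_grid, apl = apl, bin = bin))
}
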