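#' Negative-binomial GLM fits for many genes sharing one design
#'
#' Fits, for every row of `y`, a log-link negative-binomial GLM with
#' variance mu + phi mu^2 by iteratively reweighted least squares with
#' step halving, so the deviance is non-increasing across iterations.
#' `phi = 0` gives the Poisson special case. All genes are iterated
#' simultaneously with shared matrix algebra; per-gene normal equations
#' are solved exactly.
#'
#' @param y genes x samples count matrix.
#' @param X samples x coefficients design matrix (full rank).
#' @param offset per-sample offset on the log scale (length n or G x n
#'   matrix), typically log effective library size.
#' @param phi dispersion: scalar or per-gene vector, >= 0.
#' @param tol relative deviance convergence tolerance.
#' @param max_iter maximum IRLS iterations.
#' @param trace keep the per-iteration deviance matrix?
#' @return list with `beta` (G x p), `mu`, `deviance`, `loglik`,
#'   `logdet_xtwx` (Cox-Reid adjustment term), `iterations`, `converged`,
#'   `failed` (logical per gene) and, if `trace`, `deviance_trace`.
#' @export
nb_glm_fit <- function(y, X, offset = 0, phi = 0, tol = 1e-8,
                       max_iter = 50L, trace = FALSE) {
  y <- as.matrix(y)
  G <- nrow(y); n <- ncol(y); p <- ncol(X)
  if (nrow(X) != n) stop2("design matrix rows must match sample count")
  if (any(phi < 0)) stop2("phi must be >= 0")
  phi <- rep_len(phi, G)
  if (length(offset) == 1L) offset <- rep(offset, n)
  O <- if (is.matrix(offset)) offset else matrix(offset, G, n, byrow = TRUE)

  # index pairs for the packed X'WX cross-products
  pr <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pr[, 1], drop = FALSE] * X[, pr[, 2], drop = FALSE]  # n x P

  beta <- (log(y + 0.5) - O) %*% X %*% solve(crossprod(X))
  mu <- mu_clamp(exp(O + tcrossprod(beta, X)))
  dev <- nb_deviance(y, mu, phi)
  dev_trace <- if (trace) list(dev) else NULL
  failed <- rep(FALSE, G)
  converged <- rep(FALSE, G)
  iter <- 0L
  logdet <- rep(NA_real_, G)

  while (iter < max_iter && !all(converged | failed)) {
    iter <- iter + 1L
    w <- mu / (1 + mu * phi)          # phi recycles over rows
    z <- tcrossprod(beta, X) + (y - mu) / mu  # working response minus offset
    A <- w %*% XX                      # G x P packed X'WX
    B <- (w * z) %*% X                 # G x p rhs
    sol <- chol_solve_packed(A, B, pr, p)
    beta_new <- beta
    beta_new[sol$ok, ] <- sol$x[sol$ok, , drop = FALSE]
    logdet[sol$ok] <- sol$logdet[sol$ok]
    failed <- failed | !sol$ok
    mu_new <- mu_clamp(exp(O + tcrossprod(beta_new, X)))
    dev_new <- nb_deviance(y, mu_new, phi)
    # step-halve any gene whose deviance rose (guarantees monotone trace)
    for (h in seq_len(30)) {
      bad <- which(!failed & dev_new > dev + 1e-12)
      if (!length(bad)) break
      beta_new[bad, ] <- (beta_new[bad, , drop = FALSE] +
                          beta[bad, , drop = FALSE]) / 2
      mu_new[bad, ] <- mu_clamp(exp(O[bad, , drop = FALSE] +
        tcrossprod(beta_new[bad, , drop = FALSE], X)))
      dev_new[bad] <- nb_deviance(y[bad, , drop = FALSE],
                                  mu_new[bad, , drop = FALSE], phi[bad])
    }
    still_bad <- !failed & dev_new > dev + 1e-8
    failed[still_bad] <- TRUE
    keep <- !failed
    converged[keep] <- abs(dev[keep] - dev_new[keep]) /
      (abs(dev_new[keep]) + 1) < tol
    beta[keep, ] <- beta_new[keep, , drop = FALSE]
    mu[keep, ] <- mu_new[keep, , drop = FALSE]
    dev[keep] <- dev_new[keep]
    if (trace) dev_trace[[iter + 1L]] <- dev
  }
  ll <- nb_loglik(y, mu, phi)
  rownames(beta) <- rownames(y)
  out <- list(beta = beta, mu = mu, deviance = dev, loglik = ll,
              logdet_xtwx = logdet, iterations = iter,
              converged = converged, failed = failed)
  if (trace) out$deviance_trace <- do.call(cbind, dev_trace)
  out
}

mu_clamp <- function(mu) pmin(pmax(mu, 1e-10), 1e12)

# Cholesky factor + solve of G small symmetric systems at once.
# A holds the packed upper triangles (G x p(p+1)/2, ordering given by pr),
# B the right-hand sides (G x p). All arithmetic is vectorized over genes.
chol_solve_packed <- function(A, B, pr, p) {
  G <- nrow(A)
  idx <- matrix(0L, p, p)
  idx[cbind(pr[, 1], pr[, 2])] <- seq_len(nrow(pr))
  idx[cbind(pr[, 2], pr[, 1])] <- seq_len(nrow(pr))
  L <- vector("list", p)
  for (j in seq_len(p)) L[[j]] <- vector("list", p)
  ok <- rep(TRUE, G)
  logdet <- numeric(G)
  for (j in seq_len(p)) {
    s <- A[, idx[j, j]]
    for (k in seq_len(j - 1)) s <- s - L[[j]][[k]]^2
    ok <- ok & is.finite(s) & s > 0
    s[!ok | s <= 0] <- 1
    L[[j]][[j]] <- sqrt(s)
    logdet <- logdet + log(s)
    if (j < p) for (i in (j + 1):p) {
      t <- A[, idx[i, j]]
      for (k in seq_len(j - 1)) t <- t - L[[i]][[k]] * L[[j]][[k]]
      L[[i]][[j]] <- t / L[[j]][[j]]
    }
  }
  # forward substitution L w = b, then backward L' x = w
  W <- matrix(0, G, p)
  for (i in seq_len(p)) {
    t <- B[, i]
    for (k in seq_len(i - 1)) t <- t - L[[i]][[k]] * W[, k]
    W[, i] <- t / L[[i]][[i]]
  }
  X <- matrix(0, G, p)
  for (i in rev(seq_len(p))) {
    t <- W[, i]
    if (i < p) for (k in (i + 1):p) t <- t - L[[k]][[i]] * X[, k]
    X[, i] <- t / L[[i]][[i]]
  }
  list(x = X, logdet = logdet, ok = ok & apply(is.finite(X), 1, all))
}

# 2 * sum over samples of unit deviances; Poisson limit at phi = 0
nb_deviance <- function(y, mu, phi) {
  phi <- rep_len(phi, nrow(y))
  ylogy <- y * log(ifelse(y > 0, y / mu, 1))
  pois <- phi == 0
  out <- numeric(nrow(y))
  if (any(pois)) {
    out[pois] <- 2 * rowSums(ylogy[pois, , drop = FALSE] -
      (y[pois, , drop = FALSE] - mu[pois, , drop = FALSE]))
  }
  if (any(!pois)) {
    yy <- y[!pois, , drop = FALSE]; mm <- mu[!pois, , drop = FALSE]
    ph <- phi[!pois]
    out[!pois] <- 2 * rowSums(ylogy[!pois, , drop = FALSE] -
      (yy + 1 / ph) * log((1 + ph * yy) / (1 + ph * mm)))
  }
  out
}

nb_loglik <- function(y, mu, phi) {
  phi <- rep_len(phi, nrow(y))
  out <- numeric(nrow(y))
  pois <- phi == 0
  if (any(pois)) {
    out[pois] <- rowSums(dpois(y[pois, , drop = FALSE],
                               mu[pois, , drop = FALSE], log = TRUE))
  }
  if (any(!pois)) {
    yy <- y[!pois, , drop = FALSE]
    sz <- matrix(1 / phi[!pois], nrow(yy), ncol(yy))
    out[!pois] <- rowSums(dnbinom(yy, size = sz,
                                  mu = mu[!pois, , drop = FALSE],
                                  log = TRUE))
  }
  out
}

#' Nested interaction design matrix for a one-region time course
#'
#' Parameterization `~ time + treatment:time`: intercept, main effects for
#' the non-reference time levels, and one treatment effect nested within
#' each time level, so each treatment coefficient is the log fold change
#' (experimental vs control) at that time point.
#'
#' @param design `sample_design` rows for a single region.
#' @return design matrix with columns `(Intercept)`, `time<t>` for
#'   non-reference times and `trt<t>` for every time level.
#' @export
build_nested_design <- function(design) {
  tl <- attr(design, "time_levels") %||% sort(unique(design$time_min))
  tf <- factor(design$time_min, levels = tl)
  trt <- as.integer(design$treatment == "experimental")
  X <- matrix(1, nrow(design), 1, dimnames = list(NULL, "(Intercept)"))
  for (t in tl[-1]) X <- cbind(X, setNames(data.frame(as.integer(tf == t)),
                                           paste0("time", t)))
  for (t in tl) X <- cbind(X, setNames(data.frame(trt * (tf == t)),
                                       paste0("trt", t)))
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop2("nested design matrix is not full rank")
  X
}
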