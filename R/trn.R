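#' Normalized expression profiles for network inference
#'
#' Converts raw counts to log2(CPM + 0.5) using TMM effective library
#' sizes — the continuous, variance-stabilized scale on which mutual
#' information and regression operate — and drops genes with zero
#' variance across samples.
#'
#' @param cm `count_matrix`.
#' @param norm optional result of [tmm_factors()]; computed if missing.
#' @return genes x samples matrix of log2 expression.
#' @export
expression_profiles <- function(cm, norm = NULL) {
  if (is.null(norm)) norm <- tmm_factors(cm)
  e <- cpm(cm, lib_size = norm$effective_lib_size, log = TRUE, prior = 0.5)
  keep <- apply(e, 1, sd) > 0
  e[keep, , drop = FALSE]
}

#' Predictive model for one target gene from candidate regulators
#'
#' Forward selection in the least-angle spirit: starting from the
#' intercept model, the candidate most correlated with the current
#' residual is added at each step. The selection size is chosen by 5-fold
#' cross-validation (smallest size whose out-of-fold RMSD is within 0.5%
#' of the minimum, preferring parsimony), and the reported prediction
#' error is the out-of-fold RMSD divided by the target's standard
#' deviation — out-of-fold, so the error gate cannot be gamed by adding
#' regressors.
#'
#' @param target numeric vector of the target gene's expression.
#' @param candidates samples x TFs matrix of candidate regulator
#'   expression (column names = TF ids).
#' @param n_folds cross-validation folds (default 5).
#' @param max_terms cap on model size (default n/10, at least 1).
#' @param fold_seed seed for the fold shuffle.
#' @return list with `selected` (TF ids, possibly empty), `weights`
#'   (full-data OLS coefficients for the selected TFs), `rmsd_norm`
#'   (out-of-fold RMSD / sd(target)), `cv_rmsd` (per size, starting at 0).
#' @export
fit_target_model <- function(target, candidates, n_folds = 5,
                             max_terms = NULL, fold_seed = 1L) {
  candidates <- as.matrix(candidates)
  n <- length(target)
  if (nrow(candidates) != n) stop2("candidate rows must match target length")
  k_all <- ncol(candidates)
  if (k_all == 0) stop2("no candidate regulators")
  sigma <- sd(target)
  if (sigma == 0) stop2("constant target profile")
  if (is.null(max_terms)) max_terms <- max(1L, floor(n / 10))
  max_terms <- min(max_terms, k_all, n - 2L)

  # forward selection order on the full data
  order_sel <- integer(0)
  resid <- target - mean(target)
  for (s in seq_len(max_terms)) {
    avail <- setdiff(seq_len(k_all), order_sel)
    cc <- abs(suppressWarnings(
      cor(resid, candidates[, avail, drop = FALSE])))
    cc[is.na(cc)] <- 0
    pick <- avail[which.max(cc)]
    order_sel <- c(order_sel, pick)
    Xs <- cbind(1, candidates[, order_sel, drop = FALSE])
    resid <- target - Xs %*% qr.solve(Xs, target)
  }

  folds <- local({
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(fold_seed)
    f <- sample(rep_len(seq_len(n_folds), n))
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
    f
  })
  sizes <- 0:length(order_sel)
  fold_rmsd <- matrix(NA_real_, length(sizes), n_folds)
  cv_rmsd <- numeric(length(sizes))
  pred <- numeric(n)
  for (ki in seq_along(sizes)) {
    k <- sizes[ki]
    for (f in seq_len(n_folds)) {
      te <- folds == f; tr <- !te
      if (k == 0) {
        pred[te] <- mean(target[tr])
      } else {
        Xtr <- cbind(1, candidates[tr, order_sel[seq_len(k)], drop = FALSE])
        Xte <- cbind(1, candidates[te, order_sel[seq_len(k)], drop = FALSE])
        pred[te] <- Xte %*% qr.solve(Xtr, target[tr])
      }
      fold_rmsd[ki, f] <- sqrt(mean((target[te] - pred[te])^2))
    }
    cv_rmsd[ki] <- sqrt(mean((target - pred)^2))
  }

  # one-standard-error rule: smallest size whose out-of-fold error is
  # within one SE of the minimum (guards against decoy regressors that
  # shave a sliver off the CV error)
  i_min <- which.min(cv_rmsd)
  se_min <- sd(fold_rmsd[i_min, ]) / sqrt(n_folds)
  k_star <- sizes[which(cv_rmsd <= cv_rmsd[i_min] + se_min)[1]]
  sel <- order_sel[seq_len(k_star)]
  weights <- if (k_star > 0) {
    Xs <- cbind(1, candidates[, sel, drop = FALSE])
    qr.solve(Xs, target)[-1]
  } else numeric(0)
  list(selected = colnames(candidates)[sel],
       weights = setNames(as.numeric(weights), colnames(candidates)[sel]),
       rmsd_norm = cv_rmsd[k_star + 1L] / sigma,
       cv_rmsd = cv_rmsd)
}

#' Infer a transcriptional regulatory network from expression data
#'
#' Two-stage TF-target inference: (1) a mutual-information screen keeps
#' the TF-gene pairs whose MI is significant at `mi_p` against a pooled
#' permutation null; (2) each gene's screened TFs enter a forward-
#' selection regression ([fit_target_model()]) and edges to the selected
#' TFs are accepted only when the normalized out-of-fold prediction error
#' is below `rmsd_max` — i.e. the gene's expression is quantitatively
#' predictable from its regulators. Out-degrees and hub TFs are computed
#' from the accepted edge list.
#'
#' @param expr genes x samples log2 expression matrix (see
#'   [expression_profiles()]).
#' @param tf_ids character vector of TF gene ids.
#' @param mi_p MI screen threshold (default 1e-6).
#' @param rmsd_max normalized prediction-error gate (default 0.33, i.e.
#'   error below one third of the target's standard deviation).
#' @param bins MI bins; default `mi_default_bins(ncol(expr))`.
#' @param n_perm size of the pooled permutation null.
#' @param seed seed for the null pool and cross-validation folds.
#' @param hub_top number of top-degree TFs eligible as hubs.
#' @param hub_min_degree minimum out-degree for a hub.
#' @return a `trn` list: `edges` (tf, target, mi, p, rmsd, weight),
#'   `degree` (named per-TF out-degree), `hubs`, `tfs`, `null`.
#' @export
build_trn <- function(expr, tf_ids, mi_p = 1e-6, rmsd_max = 0.33,
                      bins = mi_default_bins(ncol(expr)), n_perm = 1e5,
                      seed = 1L, hub_top = 20L, hub_min_degree = 30L) {
  expr <- as.matrix(expr)
  n <- ncol(expr)
  tfs <- intersect(tf_ids, rownames(expr))
  if (!length(tfs)) stop2("no TF ids present in the expression matrix")
  genes <- rownames(expr)

  binned <- t(apply(expr, 1, equal_freq_bins, bins = bins))
  null <- mi_null_pool(n, bins, n_perm = n_perm,
                       seed = derive_seed(seed, "mi_null"))
  # invert the screen: smallest uncorrected MI whose gamma tail is <= mi_p
  mi_cut <- stats::qgamma(mi_p, shape = null$gamma_shape,
                          rate = null$gamma_rate, lower.tail = FALSE)

  mi_raw <- matrix(0, length(tfs), length(genes),
                   dimnames = list(tfs, genes))
  for (tf in tfs) {
    btf <- binned[tf, ]
    mi_raw[tf, ] <- vapply(genes, function(g)
      mi_from_bins(btf, binned[g, ], bins, correction = FALSE), numeric(1))
  }

  edges <- vector("list", length(genes))
  names(edges) <- genes
  for (g in genes) {
    cand <- tfs[tfs != g & mi_raw[, g] >= mi_cut]
    if (!length(cand)) next
    fitm <- fit_target_model(expr[g, ], t(expr[cand, , drop = FALSE]),
                             fold_seed = derive_seed(seed, paste0("cv_", g)))
    if (!length(fitm$selected) || fitm$rmsd_norm >= rmsd_max) next
    sel <- fitm$selected
    edges[[g]] <- data.frame(
      tf = sel, target = g,
      mi = vapply(sel, function(tf)
        mi_from_bins(binned[tf, ], binned[g, ], bins), numeric(1)),
      p = vapply(sel, function(tf)
        as.numeric(mi_significance(mi_raw[tf, g], null)), numeric(1)),
      rmsd = fitm$rmsd_norm,
      weight = as.numeric(fitm$weights[sel]),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges[!vapply(edges, is.null, logical(1))])
  if (is.null(edges))
    edges <- data.frame(tf = character(), target = character(),
                        mi = numeric(), p = numeric(), rmsd = numeric(),
                        weight = numeric(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  stopifnot(all(edges$p <= mi_p), all(edges$rmsd < rmsd_max),
            all(edges$tf != edges$target))

  degree <- setNames(integer(length(tfs)), tfs)
  if (nrow(edges)) {
    tb <- table(edges$tf)
    degree[names(tb)] <- as.integer(tb)
  }
  ranked <- sort(degree, decreasing = TRUE)
  hubs <- names(ranked)[seq_len(min(hub_top, length(ranked)))]
  hubs <- hubs[ranked[hubs] > hub_min_degree]

  structure(list(edges = edges, degree = degree, hubs = hubs, tfs = tfs,
                 mi_p = mi_p, rmsd_max = rmsd_max, bins = bins,
                 null = null),
            class = "trn")
}

#' @export
print.trn <- function(x, ...) {
  cat("trn:", nrow(x$edges), "edges,", sum(x$degree > 0), "active TFs,",
      length(unique(x$edges$target)), "targets,", length(x$hubs), "hubs\n")
  invisible(x)
}
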