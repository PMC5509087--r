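#' Fit the nested time-course model for one brain region
#'
#' Runs the full per-region differential-expression chain: low-expression
#' filtering, TMM normalization, dispersion estimation and negative-
#' binomial GLM fits of the nested interaction model
#' `~ time + treatment:time`. Likelihood-ratio tests are computed for each
#' treatment-within-time coefficient (1 df each) and for all of them
#' jointly (the time-by-treatment interaction test, 3 df for three time
#' levels).
#'
#' @param cm `count_matrix` whose design covers exactly one region (or
#'   pass `region` to subset).
#' @param region optional region label to subset the design.
#' @param min_cpm,min_samples low-expression filter, see
#'   [filter_low_expression()].
#' @param dispersion `"tagwise"` (default), `"common"`, `"trend"`, or a
#'   numeric value/vector used as-is.
#' @param tol,max_iter IRLS controls, see [nb_glm_fit()].
#' @return a `de_fit` list: `table` (per-gene coefficients, log2 fold
#'   changes per time, LRT p-values), `norm` (TMM result),
#'   `dispersion`, `design`, `X`, plus the underlying full fit.
#' @export
fit_nested_glm <- function(cm, region = NULL, min_cpm = 1, min_samples = 2,
                           dispersion = "tagwise", tol = 1e-8,
                           max_iter = 50L) {
  design <- cm$design
  if (is.null(design)) stop2("count matrix must carry a sample design")
  if (!is.null(region)) {
    design <- design_region(design, region)
    cm <- count_matrix(cm$counts[, design$sample_id, drop = FALSE], design)
  }
  if (length(unique(design$region)) > 1)
    stop2("fit_nested_glm expects samples from a single region; got: ",
          paste(unique(design$region), collapse = ", "),
          " (use the region argument)")
  keep <- filter_low_expression(cm, min_cpm, min_samples)
  y <- cm$counts[keep, , drop = FALSE]
  if (!nrow(y)) stop2("no genes survive the expression filter")
  norm <- tmm_factors(count_matrix(y, design))
  offset <- log(norm$effective_lib_size)
  X <- build_nested_design(design)

  disp <- estimate_dispersion(y, X, offset)
  phi <- if (is.numeric(dispersion)) rep_len(dispersion, nrow(y)) else {
    switch(dispersion,
           tagwise = disp$tagwise,
           trend = disp$trend,
           common = rep(disp$common, nrow(y)),
           stop2("unknown dispersion choice: ", dispersion))
  }

  full <- nb_glm_fit(y, X, offset, phi = phi, tol = tol,
                     max_iter = max_iter)
  trt_cols <- grep("^trt", colnames(X))
  tl <- attr(design, "time_levels") %||% sort(unique(design$time_min))

  lrt_p <- function(drop_cols) {
    red <- nb_glm_fit(y, X[, -drop_cols, drop = FALSE], offset, phi = phi,
                      tol = tol, max_iter = max_iter)
    stat <- pmax(red$deviance - full$deviance, 0)
    p <- pchisq(stat, df = length(drop_cols), lower.tail = FALSE)
    p[full$failed | red$failed] <- NA_real_
    list(stat = stat, p = p)
  }

  tab <- data.frame(gene_id = rownames(y), stringsAsFactors = FALSE)
  cpm_mat <- cpm(y, lib_size = norm$effective_lib_size)
  for (j in seq_along(tl)) {
    t <- tl[j]
    lfc <- full$beta[, trt_cols[j]] / log(2)
    # zero design cells make the MLE diverge; report a 0.5-count-offset
    # fold change for those genes (test statistics are untouched)
    for (tr in c("control", "experimental")) {
      sel <- design$treatment == tr & design$time_min == t
      zero <- rowSums(y[, sel, drop = FALSE]) == 0
      if (any(zero)) {
        exp_sel <- design$treatment == "experimental" & design$time_min == t
        ctl_sel <- design$treatment == "control" & design$time_min == t
        lfc[zero] <- log2((rowMeans(cpm_mat[zero, exp_sel, drop = FALSE]) + 0.5) /
                          (rowMeans(cpm_mat[zero, ctl_sel, drop = FALSE]) + 0.5))
      }
    }
    r <- lrt_p(trt_cols[j])
    tab[[paste0("lfc_", t)]] <- lfc
    tab[[paste0("stat_", t)]] <- r$stat
    tab[[paste0("p_", t)]] <- r$p
  }
  rx <- lrt_p(trt_cols)
  tab$stat_x <- rx$stat
  tab$p_x <- rx$p

  structure(list(table = tab, norm = norm, dispersion = disp, phi = phi,
                 design = design, X = X, fit = full,
                 time_levels = tl,
                 region = unique(design$region)),
            class = "de_fit")
}

#' @export
print.de_fit <- function(x, ...) {
  cat("de_fit:", nrow(x$table), "genes,", nrow(x$design), "samples, region",
      x$region, "\n")
  invisible(x)
}

#' Call differentially expressed genes with a joint FDR adjustment
#'
#' Benjamini-Hochberg adjustment is applied once to the pooled vector of
#' p-values from all contrasts of the region (the per-time treatment tests
#' and the interaction test), and sets are thresholded at `q < alpha`.
#' Genes significant for the interaction test form the DEGx set: genes
#' whose time course of expression is altered by the treatment.
#'
#' @param fit a `de_fit`.
#' @param alpha FDR threshold (default 0.1).
#' @return a `deg_calls` list: `table` (per-gene q-values added),
#'   `degs` (per-time DEG id lists), `degx` (gene ids), `profiles`
#'   (DEGx genes x time log2 fold-change matrix).
#' @export
call_degs <- function(fit, alpha = 0.1) {
  tab <- fit$table
  tl <- fit$time_levels
  pcols <- c(paste0("p_", tl), "p_x")
  pooled <- unlist(tab[pcols], use.names = FALSE)
  q <- rep(NA_real_, length(pooled))
  ok <- !is.na(pooled)
  q[ok] <- p.adjust(pooled[ok], method = "BH")
  qm <- matrix(q, ncol = length(pcols))
  colnames(qm) <- sub("^p_", "q_", pcols)
  tab <- cbind(tab, qm)

  degs <- lapply(seq_along(tl), function(j)
    tab$gene_id[!is.na(qm[, j]) & qm[, j] < alpha])
  names(degs) <- paste0("time_", tl)
  degx <- tab$gene_id[!is.na(qm[, "q_x"]) & qm[, "q_x"] < alpha]
  profiles <- as.matrix(tab[match(degx, tab$gene_id),
                            paste0("lfc_", tl), drop = FALSE])
  rownames(profiles) <- degx

  structure(list(table = tab, degs = degs, degx = degx,
                 profiles = profiles, alpha = alpha,
                 time_levels = tl, region = fit$region),
            class = "deg_calls")
}

#' @export
print.deg_calls <- function(x, ...) {
  cat("deg_calls (", x$region, "): ", length(x$degx), " DEGx at q < ",
      x$alpha, "; per-time DEGs: ",
      paste(vapply(x$degs, length, integer(1)), collapse = "/"), "\n",
      sep = "")
  invisible(x)
}
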