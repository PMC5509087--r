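#' Baseline chromatin accessibility calls
#'
#' Compares per-peak tag counts in a (control) sample library against the
#' input library. The fold enrichment is the ratio of library-normalized
#' tags with a 0.5-tag continuity offset, and the p-value comes from a
#' one-sided binomial test of the sample tags among (sample + input) tags
#' against the library-ratio null. A peak is called baseline accessible
#' when fold >= `min_fold` (inclusive) and p < `max_p`.
#'
#' @param pt `peak_table` carrying both tag columns.
#' @param sample_col,input_col names of the sample and input tag columns.
#' @param sample_lib,input_lib library totals; default to the column sums.
#' @param min_fold fold threshold (default 4, boundary inclusive).
#' @param max_p p-value threshold (default 1e-4, strict).
#' @return data frame: peak_id, comparison, fold, p, call
#'   ("baseline"/"none").
#' @export
call_baseline <- function(pt, sample_col = "sample", input_col = "input",
                          sample_lib = NULL, input_lib = NULL,
                          min_fold = 4, max_p = 1e-4) {
  s <- pt[[sample_col]]; i <- pt[[input_col]]
  if (is.null(s) || is.null(i)) stop2("missing tag column(s)")
  sample_lib <- sample_lib %||% sum(s)
  input_lib <- input_lib %||% sum(i)
  if (sample_lib <= 0 || input_lib <= 0) stop2("zero total tags in a library")
  fold <- ((s + 0.5) / sample_lib) / ((i + 0.5) / input_lib)
  p0 <- sample_lib / (sample_lib + input_lib)
  p <- binom_upper_tail(s, s + i, p0)
  data.frame(peak_id = pt$peak_id, comparison = "sample_vs_input",
             fold = fold, p = p,
             call = ifelse(fold >= min_fold & p < max_p, "baseline", "none"),
             stringsAsFactors = FALSE)
}

# P(X >= k) for X ~ Binomial(n, p0), vectorized; k = 0 gives 1
binom_upper_tail <- function(k, n, p0) {
  ifelse(k <= 0, 1, pbinom(k - 1, n, p0, lower.tail = FALSE))
}

#' Differentially accessible peak calls
#'
#' Computes both directed comparisons between an experimental and a
#' control tag library on a shared peak universe — once treating control
#' as background and once treating experimental as background — and calls
#' a peak differentially accessible (DAP) when the library-normalized
#' fold change exceeds `min_fold` (strict) in either direction with a
#' one-sided exact binomial p below `max_p`. Direction "up" means more
#' accessible in the experimental group. Peak tables over different
#' universes are first unified with [merge_peak_universes()].
#'
#' @param pt `peak_table` with tag columns for both conditions.
#' @param exp_col,ctrl_col names of the experimental and control tag
#'   columns.
#' @param exp_lib,ctrl_lib library totals; default to column sums.
#' @param min_fold fold threshold (default 2, strict `>`).
#' @param max_p p-value threshold (default 1e-4).
#' @return data frame: peak_id, fold (experimental over control,
#'   normalized, offset), p_up, p_down, call
#'   ("DAP_up"/"DAP_down"/"none").
#' @export
call_differential <- function(pt, exp_col = "exp", ctrl_col = "ctrl",
                              exp_lib = NULL, ctrl_lib = NULL,
                              min_fold = 2, max_p = 1e-4) {
  e <- pt[[exp_col]]; k <- pt[[ctrl_col]]
  if (is.null(e) || is.null(k)) stop2("missing tag column(s)")
  exp_lib <- exp_lib %||% sum(e)
  ctrl_lib <- ctrl_lib %||% sum(k)
  if (exp_lib <= 0 || ctrl_lib <= 0) stop2("zero total tags in a library")
  fold_up <- ((e + 0.5) / exp_lib) / ((k + 0.5) / ctrl_lib)
  p0 <- exp_lib / (exp_lib + ctrl_lib)
  p_up <- binom_upper_tail(e, e + k, p0)
  p_down <- binom_upper_tail(k, e + k, 1 - p0)
  up <- fold_up > min_fold & p_up < max_p
  down <- (1 / fold_up) > min_fold & p_down < max_p
  data.frame(peak_id = pt$peak_id, fold = fold_up,
             p_up = p_up, p_down = p_down,
             call = ifelse(up, "DAP_up", ifelse(down, "DAP_down", "none")),
             stringsAsFactors = FALSE)
}

#' Merge two peak universes by any-overlap union
#'
#' Peaks from two condition-specific tables are unified: overlapping
#' intervals are merged and the tag counts of each table's constituent
#' peaks are summed onto the merged intervals, giving a common universe
#' on which directed differential comparisons are well defined.
#'
#' @param pt_a,pt_b `peak_table`s with a single tag column each.
#' @param tag_a,tag_b names for the two tag columns in the result.
#' @return `peak_table` over merged intervals with both tag columns.
#' @export
merge_peak_universes <- function(pt_a, pt_b, tag_a = "a", tag_b = "b") {
  ga <- peaks_granges(pt_a); gb <- peaks_granges(pt_b)
  u <- GenomicRanges::reduce(c(ga, gb))
  ta <- attr(pt_a, "tag_cols")[1]; tb <- attr(pt_b, "tag_cols")[1]
  sum_onto <- function(g, tags) {
    hits <- GenomicRanges::findOverlaps(g, u)
    out <- numeric(length(u))
    agg <- tapply(tags[S4Vectors::queryHits(hits)],
                  S4Vectors::subjectHits(hits), sum)
    out[as.integer(names(agg))] <- agg
    out
  }
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(u)),
                   start = GenomicRanges::start(u),
                   end = GenomicRanges::end(u),
                   peak_id = paste0("m", seq_along(u)),
                   stringsAsFactors = FALSE)
  df[[tag_a]] <- sum_onto(ga, pt_a[[ta]])
  df[[tag_b]] <- sum_onto(gb, pt_b[[tb]])
  peak_table(df, tag_cols = c(tag_a, tag_b))
}

#' Truncated chromatin domains for each gene
#'
#' For every transcript of a gene, a window is defined extending `window`
#' bp upstream of the transcript start and `window` bp downstream of the
#' transcript end (both ends extended regardless of strand), clipped at
#' chromosome bounds. Each window is truncated so that it does not
#' intersect any transcript of any other gene (a gene's own transcripts
#' never truncate); the union of the truncated windows over the gene's
#' transcripts is the gene's chromatin domain. Truncation shortens the
#' window rather than perforating it: after other-gene transcript bodies
#' are subtracted, only the pieces that touch the gene's own transcript
#' are kept, so a domain never reaches across a neighboring gene.
#' Overlapping genes can yield empty domains, which are kept (zero
#' intervals) and logged.
#'
#' @param gm `gene_models`.
#' @param window extension in bp (default 20000).
#' @return named `GRangesList` of per-gene domain ranges (possibly empty
#'   for genes fully covered by other genes' transcripts).
#' @export
build_domains <- function(gm, window = 20000) {
  if (window < 0) stop2("window must be >= 0")
  chrom <- gm$chrom
  s <- gm$start; e <- gm$end
  gene <- gm$gene_id
  lens <- attr(gm, "chrom_lengths")
  ws <- pmax(1L, s - as.integer(window))
  we <- e + as.integer(window)
  if (!is.null(lens)) {
    has <- chrom %in% names(lens)
    we[has] <- pmin(we[has], as.integer(lens[chrom[has]]))
  }
  win <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ws, we))
  tx <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, e))
  hits <- GenomicRanges::findOverlaps(win, tx)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  other <- gene[qh] != gene[sh]
  ov_by_win <- split(sh[other], qh[other])

  piece_rows <- vector("list", length(win))
  for (i in seq_along(win)) {
    os <- ov_by_win[[as.character(i)]]
    if (is.null(os)) {
      piece_rows[[i]] <- cbind(ws[i], we[i])
      next
    }
    # subtract other-gene transcript bodies from the window, then keep
    # only the pieces that still touch the own transcript (truncation)
    cur_s <- ws[i]; cur_e <- we[i]
    o <- cbind(pmax(s[os], cur_s), pmin(e[os], cur_e))
    o <- o[order(o[, 1]), , drop = FALSE]
    pieces <- NULL
    pos <- cur_s
    for (r in seq_len(nrow(o))) {
      if (o[r, 1] > pos) pieces <- rbind(pieces, c(pos, o[r, 1] - 1L))
      pos <- max(pos, o[r, 2] + 1L)
    }
    if (pos <= cur_e) pieces <- rbind(pieces, c(pos, cur_e))
    if (!is.null(pieces)) {
      keep <- pieces[, 1] <= e[i] & pieces[, 2] >= s[i]
      pieces <- pieces[keep, , drop = FALSE]
    }
    piece_rows[[i]] <- pieces
  }
  np <- vapply(piece_rows, function(p) if (is.null(p)) 0L else nrow(p),
               integer(1))
  flat <- do.call(rbind, piece_rows[np > 0])
  pg <- GenomicRanges::GRanges(rep(chrom, np),
                               IRanges::IRanges(flat[, 1], flat[, 2]))
  doms <- GenomicRanges::reduce(
    GenomicRanges::split(pg, factor(rep(gene, np), levels = unique(gene))))
  empty <- names(doms)[S4Vectors::elementNROWS(doms) == 0]
  if (length(empty))
    message("gene(s) with an empty chromatin domain: ",
            paste(empty, collapse = ", "))
  doms
}

#' Assign peaks to genes by domain overlap
#'
#' A peak is linked to a gene when it overlaps the gene's chromatin
#' domain by at least one base pair ("any overlap"); a peak may link to
#' multiple genes. The signed distance from the peak midpoint to the
#' nearest transcript TSS of the gene is reported for context (positive =
#' downstream of the TSS in the gene's orientation).
#'
#' @param pt `peak_table`.
#' @param domains per-gene domain list from [build_domains()].
#' @param gm `gene_models` (for TSS distances); optional.
#' @return data frame: peak_id, gene_id, overlap_bp, distance_to_tss.
#' @export
assign_peaks <- function(pt, domains, gm = NULL) {
  gp <- peaks_granges(pt)
  doml <- if (methods::is(domains, "GRangesList")) domains else
    GenomicRanges::GRangesList(domains)
  nper <- S4Vectors::elementNROWS(doml)
  flat <- unlist(doml, use.names = FALSE)
  dom_gene <- rep(names(doml), nper)
  hits <- GenomicRanges::findOverlaps(gp, flat, minoverlap = 1L)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  if (!length(hits)) {
    return(data.frame(peak_id = character(), gene_id = character(),
                      overlap_bp = integer(),
                      distance_to_tss = numeric(),
                      stringsAsFactors = FALSE))
  }
  ov <- GenomicRanges::width(IRanges::pintersect(gp[qh], flat[sh]))
  ng <- length(doml)
  gidx <- match(dom_gene[sh], names(doml))
  key <- (as.numeric(qh) - 1) * ng + gidx
  agg <- rowsum(as.numeric(ov), key)
  k <- as.numeric(rownames(agg))
  gidx_out <- as.integer((k - 1) %% ng) + 1L
  idx <- as.integer((k - 1 - (gidx_out - 1)) / ng) + 1L
  gid <- names(doml)[gidx_out]
  d <- rep(NA_real_, length(idx))
  if (!is.null(gm)) {
    tss_by_gene <- split(transcript_tss(gm), gm$gene_id)
    strand_by_gene <- vapply(split(gm$strand, gm$gene_id), `[`, "", 1)
    mid <- (pt$start[idx] + pt$end[idx]) / 2
    d <- vapply(seq_along(idx), function(j) {
      tss <- tss_by_gene[[gid[j]]]
      sgn <- if (strand_by_gene[[gid[j]]] == "+") 1 else -1
      dd <- (mid[j] - tss) * sgn
      dd[which.min(abs(dd))]
    }, numeric(1))
  }
  out <- data.frame(peak_id = pt$peak_id[idx], gene_id = gid,
                    overlap_bp = as.integer(agg),
                    distance_to_tss = d, stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, match(out$peak_id, pt$peak_id)), ]
  rownames(out) <- NULL
  out
}
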