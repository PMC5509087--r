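#' Gene-by-sample count container
#'
#' Thin validated container for raw counts: an integer-like matrix with
#' unique gene ids, per-sample library sizes (column sums) and, optionally,
#' the sample design.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). Non-negative and finite.
#' @param design optional `sample_design`; columns are reordered to match.
#' @return a `count_matrix` list with elements `counts`, `lib_size`,
#'   `design`.
#' @export
count_matrix <- function(counts, design = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop2("counts must have gene ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop2("duplicate gene id(s): ",
          paste(unique(rownames(counts)[duplicated(rownames(counts))]),
                collapse = ", "))
  if (any(!is.finite(counts)))
    stop2("non-finite count at row(s): ",
          paste(head(rownames(counts)[rowSums(!is.finite(counts)) > 0]),
                collapse = ", "))
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop2("negative count for gene ", rownames(counts)[bad[1]],
          ", sample ", colnames(counts)[bad[2]])
  }
  if (!is.null(design)) {
    if (is.null(colnames(counts))) stop2("counts must have sample ids as colnames")
    unknown <- setdiff(colnames(counts), design$sample_id)
    if (length(unknown))
      stop2("sample id(s) not in design: ", paste(unknown, collapse = ", "))
    missing <- setdiff(design$sample_id, colnames(counts))
    if (length(missing))
      stop2("design sample id(s) absent from counts: ",
            paste(missing, collapse = ", "))
    counts <- counts[, design$sample_id, drop = FALSE]
  }
  structure(list(counts = counts,
                 lib_size = colSums(counts),
                 design = design),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Read a gene count matrix
#'
#' Expects a tab-separated file whose first column holds gene ids and whose
#' header row holds sample ids; no quoting.
#'
#' @param path TSV file.
#' @param design optional `sample_design` used to validate and order
#'   samples.
#' @return a `count_matrix`.
#' @export
read_counts <- function(path, design = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(x) < 2) stop2("counts file ", path, " needs gene id + >=1 sample column")
  gid <- as.character(x[[1]])
  if (anyDuplicated(gid)) {
    dup <- unique(gid[duplicated(gid)])
    stop2("counts file ", path, ": duplicated gene row(s): ",
          paste(head(dup), collapse = ", "))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- names(x)[-1][!vapply(x[-1], is.numeric, logical(1))][1]
    stop2("counts file ", path, ": non-numeric values in column ", badcol)
  }
  rownames(m) <- gid
  if (any(!is.finite(m))) {
    bad <- which(rowSums(!is.finite(m)) > 0)[1]
    stop2("counts file ", path, ": NaN/NA count in gene row ", gid[bad])
  }
  count_matrix(m, design = design)
}

#' Write a count matrix as TSV
#'
#' @param cm `count_matrix` (or plain matrix with dimnames).
#' @param path output file.
#' @export
write_counts <- function(cm, path) {
  m <- if (inherits(cm, "count_matrix")) cm$counts else as.matrix(cm)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
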