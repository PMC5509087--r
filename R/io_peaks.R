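#' Peak table with per-library tag counts
#'
#' Container for BED-derived peak intervals carrying one or more tag-count
#' columns (one per sequencing library). Coordinates are stored in the
#' package-wide 1-based closed convention; [read_peaks()]/[write_peaks()]
#' translate from/to BED's 0-based half-open columns, so a written file
#' round-trips losslessly.
#'
#' @param df data frame with columns `chrom`, `start`, `end`, `peak_id`
#'   plus one numeric column per tag library.
#' @param tag_cols character names of the tag-count columns; defaults to
#'   every column after `peak_id`.
#' @return a `peak_table` data frame.
#' @export
peak_table <- function(df, tag_cols = NULL) {
  need <- c("chrom", "start", "end", "peak_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("peak table lacks: ", paste(miss, collapse = ", "))
  if (is.null(tag_cols)) tag_cols <- setdiff(names(df), need)
  df <- df[c(need, tag_cols)]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) {
    bad <- which(df$start > df$end)[1]
    stop2("peak ", df$peak_id[bad], " (row ", bad, ") has start > end")
  }
  if (anyDuplicated(df$peak_id))
    stop2("duplicate peak_id: ",
          paste(unique(df$peak_id[duplicated(df$peak_id)]), collapse = ", "))
  for (tc in tag_cols) {
    if (!is.numeric(df[[tc]]) || any(!is.finite(df[[tc]])) || any(df[[tc]] < 0))
      stop2("tag column '", tc, "' must be finite and >= 0")
  }
  rownames(df) <- NULL
  attr(df, "tag_cols") <- tag_cols
  class(df) <- c("peak_table", "data.frame")
  df
}

#' Read a BED-like peak/tag table
#'
#' Columns: chrom, start (0-based), end (half-open), peak id, then one
#' numeric tag-count column per library. No header.
#'
#' @param path BED-like TSV file.
#' @param tag_cols names for the tag columns, in file order.
#' @return a `peak_table` (1-based closed coordinates).
#' @export
read_peaks <- function(path, tag_cols = "tag") {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 4 + length(tag_cols))
    stop2("peak file ", path, " has ", ncol(x), " columns; need >= ",
          4 + length(tag_cols))
  names(x)[1:4] <- c("chrom", "start", "end", "peak_id")
  names(x)[5:(4 + length(tag_cols))] <- tag_cols
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x$start))) |
                 is.na(suppressWarnings(as.numeric(x$end))))[1]
    stop2("peak file ", path, " line ", bad, ": malformed coordinate")
  }
  if (any(x$start >= x$end)) {
    bad <- which(x$start >= x$end)[1]
    stop2("peak file ", path, " line ", bad, ": start >= end")
  }
  x$start <- x$start + 1L  # BED 0-based half-open -> 1-based closed
  peak_table(x[c("chrom", "start", "end", "peak_id", tag_cols)],
             tag_cols = tag_cols)
}

#' Write a peak table as BED-like TSV
#'
#' @param pt `peak_table`.
#' @param path output file.
#' @export
write_peaks <- function(pt, path) {
  out <- as.data.frame(pt)
  out$start <- out$start - 1L  # back to BED convention
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

peaks_granges <- function(pt) {
  GenomicRanges::GRanges(pt$chrom, IRanges::IRanges(pt$start, pt$end),
                         peak_id = pt$peak_id)
}

#' Width of each peak in base pairs
#' @param pt `peak_table`.
#' @export
peak_width <- function(pt) pt$end - pt$start + 1L
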