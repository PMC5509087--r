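#' Read/write regulatory-network edge tables
#'
#' Edges are stored as TSV with columns `tf`, `target`, `mi`, `p`, `rmsd`
#' and (optionally) `weight`.
#'
#' @param path TSV file.
#' @return data frame of edges.
#' @export
read_trn_edges <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("tf", "target", "mi", "p", "rmsd")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop2("edge file lacks: ", paste(miss, collapse = ", "))
  if (any(x$tf == x$target)) stop2("self-edge in TRN table")
  x
}

#' @rdname read_trn_edges
#' @param edges data frame of edges.
#' @export
write_trn_edges <- function(edges, path) {
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write cluster assignment tables
#'
#' Cluster assignments are stored as TSV with columns `gene`, `cluster`,
#' `lfc_30`, `lfc_60`, `lfc_120`.
#'
#' @param path TSV file.
#' @return data frame of assignments.
#' @export
read_clusters <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "cluster", "lfc_30", "lfc_60", "lfc_120")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop2("cluster file lacks: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$gene)) stop2("duplicate gene in cluster table")
  x
}

#' @rdname read_clusters
#' @param assign data frame of assignments.
#' @export
write_clusters <- function(assign, path) {
  write.table(assign, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor list
#'
#' Plain text, one gene id per line; blank lines and `#` comments ignored.
#'
#' @param path text file.
#' @return character vector of TF gene ids.
#' @export
read_tf_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
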