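#' Transcript-level gene models
#'
#' Validated transcript table underlying chromatin-domain construction.
#' Coordinates follow the package-wide convention: 1-based, closed
#' intervals (GTF native); BED input is converted on ingest so all interval
#' arithmetic sees a single convention.
#'
#' @param df data frame with columns `gene_id`, `transcript_id`, `chrom`,
#'   `strand`, `start`, `end`.
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   clip domain windows.
#' @return a `gene_models` data frame.
#' @export
gene_models <- function(df, chrom_lengths = NULL) {
  need <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop2("gene model table lacks: ", paste(miss, collapse = ", "))
  df <- df[need]
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$start > df$end)) {
    bad <- df$transcript_id[df$start > df$end][1]
    stop2("transcript ", bad, " has start > end")
  }
  if (!all(df$strand %in% c("+", "-")))
    stop2("strand must be '+' or '-'")
  nchr <- tapply(df$chrom, df$gene_id, function(x) length(unique(x)))
  if (any(nchr > 1))
    stop2("gene(s) with transcripts on multiple chromosomes: ",
          paste(names(nchr)[nchr > 1], collapse = ", "))
  if (anyDuplicated(df$transcript_id))
    stop2("duplicate transcript_id: ",
          paste(unique(df$transcript_id[duplicated(df$transcript_id)]),
                collapse = ", "))
  rownames(df) <- NULL
  attr(df, "chrom_lengths") <- chrom_lengths
  class(df) <- c("gene_models", "data.frame")
  df
}

#' Read gene models from a GTF annotation
#'
#' Reads an Ensembl-dialect GTF (attributes `gene_id`, `transcript_id`).
#' Transcript extents are taken from `transcript` feature rows when
#' present, otherwise computed as the span of each transcript's exons.
#'
#' @param path GTF file.
#' @return a `gene_models` data frame (one row per transcript).
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  if (is.null(md$gene_id) || is.null(md$transcript_id))
    stop2("GTF ", path, " lacks gene_id/transcript_id attributes")
  keep <- !is.na(md$transcript_id)
  if (!is.null(md$type) && any(md$type == "transcript", na.rm = TRUE))
    keep <- keep & md$type == "transcript"
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  df <- data.frame(gene_id = md$gene_id,
                   transcript_id = md$transcript_id,
                   chrom = as.character(GenomicRanges::seqnames(gr)),
                   strand = as.character(GenomicRanges::strand(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$transcript_id)) {
    # exon rows: span per transcript
    sp <- lapply(split(seq_len(nrow(df)), df$transcript_id), function(i) {
      r <- df[i, ]
      r$start[1] <- min(r$start); r$end[1] <- max(r$end); r[1, ]
    })
    df <- do.call(rbind, sp)
  }
  len <- tryCatch({
    sl <- GenomicRanges::seqinfo(gr)
    L <- GenomeInfoDb_seqlengths(sl)
    if (all(is.na(L))) NULL else L
  }, error = function(e) NULL)
  gene_models(df, chrom_lengths = len)
}

# small indirection kept testable without importing GenomeInfoDb directly
GenomeInfoDb_seqlengths <- function(si) {
  getExportedValue("GenomeInfoDb", "seqlengths")(si)
}

#' Write gene models as GTF
#'
#' Emits one `transcript` feature per transcript with `gene_id` and
#' `transcript_id` attributes, readable by [read_annotation()].
#'
#' @param gm `gene_models`.
#' @param path output GTF file.
#' @export
write_gtf <- function(gm, path) {
  gr <- GenomicRanges::GRanges(gm$chrom,
                               IRanges::IRanges(gm$start, gm$end),
                               strand = gm$strand,
                               type = "transcript",
                               gene_id = gm$gene_id,
                               transcript_id = gm$transcript_id)
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

# GRanges view of transcripts, gene_id carried in mcols
models_granges <- function(gm) {
  GenomicRanges::GRanges(gm$chrom, IRanges::IRanges(gm$start, gm$end),
                         strand = gm$strand, gene_id = gm$gene_id,
                         transcript_id = gm$transcript_id)
}

# strand-aware TSS position per transcript (1-based)
transcript_tss <- function(gm) {
  ifelse(gm$strand == "+", gm$start, gm$end)
}
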