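#' Sample design for a treatment-by-time experiment
#'
#' Builds and validates the sample sheet describing a two-group
#' (control vs experimental) time-course with samples drawn from one or
#' more brain regions. Every downstream model is fitted separately per
#' region, so each (region, treatment, time) cell that is analyzed must
#' contain at least one sample.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param region character, one of `"diencephalon"`/`"telencephalon"` (any
#'   label set is accepted but must be consistent).
#' @param treatment character, `"control"` or `"experimental"`.
#' @param time_min integer time point in minutes; levels default to
#'   30/60/120.
#' @param pair_id optional character pairing control and experimental
#'   samples (paired flasks); kept as metadata, not used in the model.
#' @param time_levels permitted time levels.
#' @return a `sample_design` data frame.
#' @export
sample_design <- function(sample_id, region, treatment, time_min,
                          pair_id = NULL,
                          time_levels = c(30L, 60L, 120L)) {
  d <- data.frame(sample_id = as.character(sample_id),
                  region = as.character(region),
                  treatment = as.character(treatment),
                  time_min = as.integer(time_min),
                  stringsAsFactors = FALSE)
  d$pair_id <- if (is.null(pair_id)) NA_character_ else as.character(pair_id)
  if (anyDuplicated(d$sample_id))
    stop2("duplicate sample_id: ",
          paste(unique(d$sample_id[duplicated(d$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(d$treatment), c("control", "experimental"))
  if (length(bad))
    stop2("treatment must be 'control' or 'experimental'; got: ",
          paste(bad, collapse = ", "))
  if (!all(d$time_min %in% time_levels))
    stop2("time_min outside declared levels (",
          paste(time_levels, collapse = ", "), "): ",
          paste(setdiff(d$time_min, time_levels), collapse = ", "))
  attr(d, "time_levels") <- as.integer(time_levels)
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Read a sample design table
#'
#' @param path TSV with columns `sample_id`, `region`, `treatment`,
#'   `time_min` and optionally `pair_id`.
#' @param ... passed to [sample_design()].
#' @return a `sample_design` data frame.
#' @export
read_design <- function(path, ...) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "region", "treatment", "time_min")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop2("design file ", path, " lacks column(s): ", paste(miss, collapse = ", "))
  sample_design(x$sample_id, x$region, x$treatment, x$time_min,
                pair_id = x$pair_id, ...)
}

#' @export
write_design <- function(design, path) {
  write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# subset a design to one region, erroring on empty cells
design_region <- function(design, region) {
  d <- design[design$region == region, , drop = FALSE]
  if (!nrow(d)) stop2("no samples for region '", region, "'")
  cells <- table(d$treatment, d$time_min)
  if (any(cells == 0))
    stop2("region '", region, "' has empty (treatment, time) design cells")
  d
}
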