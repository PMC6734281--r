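#' Genomic interval tables
#'
#' Throughout the package an interval table is a plain `data.frame` with
#' columns `chrom`, `start`, `end` (0-based, half-open, as in BED) and
#' optionally `label` and `strand`. SNP positions are 1-based in catalog
#' files and converted to length-1 half-open intervals internally.
#'
#' @param chrom character vector of chromosome names
#' @param start,end integer vectors; 0-based half-open
#' @param label optional labels
#' @param strand optional strand ("+", "-" or NA)
#' @return a validated interval `data.frame`
#' @export
genomic_intervals <- function(chrom, start, end, label = NULL, strand = NULL) {
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (!is.null(label)) df$label <- as.character(label)
  if (!is.null(strand)) df$strand <- as.character(strand)
  validate_intervals(df)
  df
}

validate_intervals <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) {
    stop("invalid intervals (need 0 <= start < end) at rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(df)
}

#' Convert a 1-based point position to a length-1 half-open interval
#' @param chrom chromosome names
#' @param pos 1-based positions
#' @keywords internal
point_interval <- function(chrom, pos) {
  genomic_intervals(chrom, pos - 1, pos)
}

as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end))
}

#' All pairs of overlapping intervals between two sets
#'
#' Overlap uses the half-open convention: `[10,20)` and `[20,30)` do not
#' overlap. Backed by \code{GenomicRanges::findOverlaps}.
#'
#' @param query,subject interval `data.frame`s (see [genomic_intervals()])
#' @return a `data.frame` with columns `query` and `subject`, the row
#'   indices of each overlapping pair
#' @export
interval_overlap <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(data.frame(query = integer(), subject = integer()))
  }
  validate_intervals(query)
  validate_intervals(subject)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(as_granges(query), as_granges(subject)))
  data.frame(query = S4Vectors::queryHits(hits),
             subject = S4Vectors::subjectHits(hits))
}

#' Read a BED3+ file into an interval table
#'
#' Columns beyond the third are kept; the fourth is named `label`.
#' @param path file path
#' @return interval `data.frame`
#' @export
read_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  names(dt)[1:3] <- c("chrom", "start", "end")
  if (ncol(dt) >= 4) names(dt)[4] <- "label"
  if (ncol(dt) >= 6) names(dt)[6] <- "strand"
  df <- as.data.frame(dt)
  validate_intervals(df)
  df
}

#' Write an interval table as BED
#' @param df interval `data.frame`
#' @param path output path
#' @export
write_bed <- function(df, path) {
  validate_intervals(df)
  cols <- intersect(c("chrom", "start", "end", "label"), names(df))
  out <- df[, cols, drop = FALSE]
  out$start <- format(out$start, scientific = FALSE, trim = TRUE)
  out$end <- format(out$end, scientific = FALSE, trim = TRUE)
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, ...) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, ...))
}
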