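#' Gene model tables
#'
#' A gene model set is a list with two data.frames:
#' \describe{
#'   \item{genes}{`gene_id, chrom, start, end, strand, tss, pseudogene` —
#'     gene bodies, 0-based half-open; `tss` is the 0-based position of the
#'     transcription start site (start for "+", end-1 for "-").}
#'   \item{features}{`chrom, start, end, gene_id, feature` with feature in
#'     `cds`, `utr`, `intron` — the within-gene decomposition used for
#'     region classification. Pseudogenes contribute no `cds` features.}
#' }
#' @name gene_models
NULL

new_gene_models <- function(genes, features, chrom_lengths) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand",
                  "tss", "pseudogene") %in% names(genes)))
  validate_intervals(features)
  obj <- list(genes = genes, features = features,
              chrom_lengths = chrom_lengths)
  class(obj) <- "gene_models"
  obj
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d pseudogenes) on %d chromosome(s)\n",
              nrow(x$genes), sum(x$genes$pseudogene),
              length(x$chrom_lengths)))
  invisible(x)
}

#' Write gene models as GFF3
#'
#' Emits `gene` records (with `ID`, `pseudogene` and `tss` attributes) and
#' `CDS` / `UTR` / `intron` child records.
#' @param gm a `gene_models` object
#' @param path output path
#' @export
write_gene_models_gff <- function(gm, path) {
  g <- gm$genes
  gene_lines <- sprintf(
    "%s\tenhloop\tgene\t%d\t%d\t.\t%s\t.\tID=%s;pseudogene=%s;tss=%d",
    g$chrom, g$start + 1, g$end, g$strand, g$gene_id,
    ifelse(g$pseudogene, "true", "false"), g$tss + 1)
  f <- gm$features
  type <- c(cds = "CDS", utr = "UTR", intron = "intron")[f$feature]
  feat_lines <- sprintf("%s\tenhloop\t%s\t%d\t%d\t.\t.\t.\tParent=%s",
                        f$chrom, type, f$start + 1, f$end, f$gene_id)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (chrom in names(gm$chrom_lengths)) {
    writeLines(sprintf("##sequence-region %s 1 %d", chrom,
                       as.integer(gm$chrom_lengths[[chrom]])), con)
  }
  writeLines(c(gene_lines, feat_lines), con)
  invisible(path)
}

gff_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
  out <- rep(NA_character_, length(attrs))
  hit <- grepl(paste0(key, "="), attrs)
  out[hit] <- sub(paste0(key, "="), "", m)
  out
}

#' Read gene models from the GFF3 dialect written by
#' [write_gene_models_gff()]
#' @param path GFF3 path
#' @return a `gene_models` object
#' @export
read_gene_models_gff <- function(path) {
  lines <- readLines(path)
  seqreg <- grep("^##sequence-region", lines, value = TRUE)
  parts <- strsplit(seqreg, " ")
  chrom_lengths <- stats::setNames(
    vapply(parts, function(p) as.numeric(p[4]), numeric(1)),
    vapply(parts, function(p) p[2], character(1)))
  body <- lines[!startsWith(lines, "#")]
  fields <- do.call(rbind, strsplit(body, "\t"))
  df <- data.frame(chrom = fields[, 1], type = fields[, 3],
                   start = as.numeric(fields[, 4]) - 1,
                   end = as.numeric(fields[, 5]),
                   strand = fields[, 7], attrs = fields[, 9],
                   stringsAsFactors = FALSE)
  gr <- df[df$type == "gene", ]
  genes <- data.frame(gene_id = gff_attr(gr$attrs, "ID"),
                      chrom = gr$chrom, start = gr$start, end = gr$end,
                      strand = gr$strand,
                      tss = as.numeric(gff_attr(gr$attrs, "tss")) - 1,
                      pseudogene = gff_attr(gr$attrs, "pseudogene") == "true",
                      stringsAsFactors = FALSE)
  fr <- df[df$type %in% c("CDS", "UTR", "intron"), ]
  features <- data.frame(chrom = fr$chrom, start = fr$start, end = fr$end,
                         gene_id = gff_attr(fr$attrs, "Parent"),
                         feature = c(CDS = "cds", UTR = "utr",
                                     intron = "intron")[fr$type],
                         stringsAsFactors = FALSE)
  rownames(features) <- NULL
  new_gene_models(genes, features, chrom_lengths)
}
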