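#' Load and filter a GWAS-catalog-style SNP association table
#'
#' Retains rows whose trait matches `trait_pattern` (regular expression,
#' case sensitive as in the catalog's DISEASE/TRAIT column) and whose
#' association p-value is strictly below `p_threshold`. Rows whose rsID is
#' in `include_list` are retained regardless of p-value — this models a
#' confirmed-SNP list that bypasses the suggestive-significance screen.
#'
#' Rows without an rsID receive a synthesized identifier
#' (`novel_<row>`) and a `curated` flag; rows with an unparseable p-value
#' are skipped with a warning. Duplicate rsIDs are collapsed to the row
#' with the smallest p-value.
#'
#' Expected columns (tab-separated): `rsid`, `chrom`, `pos` (1-based),
#' `trait`, `pvalue`, `consequence`, `mapped_gene`.
#'
#' @param path catalog TSV path
#' @param trait_pattern regular expression matched against `trait`
#' @param p_threshold retain p strictly below this (default 1e-6, the
#'   conventional GWAS suggestive threshold)
#' @param include_list character vector of rsIDs kept regardless of p
#' @return `data.frame` of SNP records: rsid, chrom, pos, pvalue, trait,
#'   consequence, curated, source_row, region_class (NA until classified)
#' @export
load_snp_catalog <- function(path, trait_pattern = "Alzheimer",
                             p_threshold = 1e-6,
                             include_list = character()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- read_tsv(path)
  if ("rsid" %in% names(raw)) raw$rsid <- as.character(raw$rsid)
  required <- c("rsid", "chrom", "pos", "trait", "pvalue", "consequence")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("catalog missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  raw$source_row <- seq_len(nrow(raw))
  p <- suppressWarnings(as.numeric(raw$pvalue))
  bad_p <- is.na(p) | p <= 0 | p > 1
  if (any(bad_p)) {
    warning(sum(bad_p), " row(s) with malformed p-value skipped")
    raw <- raw[!bad_p, , drop = FALSE]
    p <- p[!bad_p]
  }
  raw$pvalue <- p
  no_id <- is.na(raw$rsid) | raw$rsid == ""
  if (any(no_id)) {
    message(sum(no_id), " row(s) without rsID flagged for manual curation")
    raw$rsid[no_id] <- paste0("novel_", raw$source_row[no_id])
  }
  raw$curated <- no_id
  keep <- (grepl(trait_pattern, raw$trait) & raw$pvalue < p_threshold) |
    raw$rsid %in% include_list
  snps <- raw[keep, c("rsid", "chrom", "pos", "pvalue", "trait",
                      "consequence", "curated", "source_row")]
  if (nrow(snps) > 1) {
    snps <- snps[order(snps$rsid, snps$pvalue), ]
    snps <- snps[!duplicated(snps$rsid), ]
    snps <- snps[order(snps$source_row), ]
  }
  rownames(snps) <- NULL
  snps$region_class <- NA_character_
  snps
}

NONCODING_CLASSES <- c("intronic", "utr", "intergenic")

#' Classify SNPs by genomic region against gene models
#'
#' A coding consequence label on the input (`missense*` or `synonymous*`)
#' is honored as-is. Otherwise the SNP position is intersected with the
#' gene-model feature decomposition with precedence CDS > UTR > intron:
#' CDS hits become `other-coding`, UTR hits `utr`, intron hits `intronic`
#' and everything else `intergenic`. The non-coding set is
#' \{intronic, utr, intergenic\}.
#'
#' @param snps SNP `data.frame` from [load_snp_catalog()]
#' @param genes a `gene_models` object
#' @return `snps` with `region_class` filled and a logical `noncoding`
#'   column added
#' @export
classify_snp_region <- function(snps, genes) {
  cls <- rep(NA_character_, nrow(snps))
  cons <- tolower(ifelse(is.na(snps$consequence), "", snps$consequence))
  cls[grepl("^missense", cons)] <- "missense"
  cls[grepl("^synonymous", cons)] <- "synonymous"
  todo <- which(is.na(cls))
  if (length(todo)) {
    unknown <- !(snps$chrom[todo] %in% unique(genes$features$chrom)) &
      !(snps$chrom[todo] %in% names(genes$chrom_lengths))
    if (any(unknown)) {
      warning("SNP chromosome(s) absent from gene models, classified ",
              "intergenic: ", paste(unique(snps$chrom[todo][unknown]),
                                    collapse = ", "))
    }
    pts <- point_interval(snps$chrom[todo], snps$pos[todo])
    hits <- interval_overlap(pts, genes$features)
    cls[todo] <- "intergenic"
    if (nrow(hits)) {
      feat <- genes$features$feature[hits$subject]
      rank <- c(cds = 1, utr = 2, intron = 3)[feat]
      best <- tapply(rank, hits$query, min)
      idx <- todo[as.integer(names(best))]
      cls[idx] <- c("other-coding", "utr", "intronic")[best]
    }
  }
  snps$region_class <- cls
  snps$noncoding <- cls %in% NONCODING_CLASSES
  snps
}
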