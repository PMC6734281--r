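#' Filter eQTL associations with chromosome-wise q-value control
#'
#' Applies the eQTL retention rules: drop associations whose gene lies on
#' a different chromosome than the SNP, drop pseudogene targets, then
#' compute Storey q-values within each chromosome-wise family (all
#' remaining associations whose SNP lies on a given chromosome form one
#' family, mirroring correction "across genes on the same chromosome")
#' and retain q-values strictly below `alpha`. The per-SNP eQTL gene set
#' is the union of retained target genes across tissues.
#'
#' @param eqtl `data.frame` with columns rsid, gene_id, tissue, pvalue
#' @param snps SNP `data.frame` (needs rsid, chrom)
#' @param genes a `gene_models` object (supplies gene chromosome and
#'   pseudogene flag)
#' @param alpha q-value cutoff (default 0.05)
#' @param lambda Storey lambda passed to [storey_qvalue()]
#' @return list with `associations` (retained rows with qvalue,
#'   same_chrom, pseudogene columns), `snp_genes` (named list of gene
#'   sets per SNP with at least one retained association) and `dropped`
#'   (counts per filtering rule)
#' @export
filter_eqtl_associations <- function(eqtl, snps, genes, alpha = 0.05,
                                     lambda = 0.5) {
  stopifnot(all(c("rsid", "gene_id", "tissue", "pvalue") %in% names(eqtl)))
  snp_chrom <- stats::setNames(snps$chrom, snps$rsid)
  gene_chrom <- stats::setNames(genes$genes$chrom, genes$genes$gene_id)
  gene_pseudo <- stats::setNames(genes$genes$pseudogene, genes$genes$gene_id)

  known <- eqtl$rsid %in% names(snp_chrom) & eqtl$gene_id %in% names(gene_chrom)
  if (any(!known)) {
    warning(sum(!known), " association(s) with unknown SNP or gene dropped")
  }
  x <- eqtl[known, , drop = FALSE]
  x$same_chrom <- snp_chrom[x$rsid] == gene_chrom[x$gene_id]
  x$pseudogene <- unname(gene_pseudo[x$gene_id])
  dropped <- c(unknown_id = sum(!known),
               cross_chrom = sum(!x$same_chrom),
               pseudogene = sum(x$same_chrom & x$pseudogene))
  x <- x[x$same_chrom & !x$pseudogene, , drop = FALSE]

  x$qvalue <- NA_real_
  fam <- unname(snp_chrom[x$rsid])
  for (chrom in unique(fam)) {
    idx <- which(fam == chrom)
    x$qvalue[idx] <- storey_qvalue(x$pvalue[idx], lambda = lambda)
  }
  dropped <- c(dropped, not_significant = sum(x$qvalue >= alpha))
  kept <- x[x$qvalue < alpha, , drop = FALSE]
  rownames(kept) <- NULL
  snp_genes <- lapply(split(kept$gene_id, kept$rsid), function(g)
    sort(unique(g)))
  list(associations = kept, snp_genes = snp_genes, dropped = dropped)
}
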