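#' Generate a synthetic multi-chromosome genome with gene models
#'
#' Produces random-sequence chromosomes with HindIII motifs planted at a
#' controllable spacing (random sequence contributes additional motifs at
#' the natural ~4^-6 rate), and non-overlapping gene bodies with strand,
#' TSS, exon/intron structure and a pseudogene flag at the requested
#' fraction (rounded). Genes can be kept out of `exclude` zones (e.g.
#' around planted TAD boundaries).
#'
#' @param n_chrom number of chromosomes
#' @param chrom_len chromosome length in bp (all chromosomes equal)
#' @param n_genes total gene count (>= 1)
#' @param pseudogene_frac fraction of genes flagged pseudogene, in \[0,1)
#' @param seed integer seed for this generator's stream
#' @param hindiii_spacing planted HindIII motif spacing in bp
#' @param gene_len_range min/max gene body length in bp
#' @param exclude optional interval `data.frame` genes must avoid
#' @return list(genes = `gene_models`, fasta = `DNAStringSet`)
#' @export
gen_genome_annotation <- function(n_chrom = 2, chrom_len = 6e6,
                                  n_genes = 80, pseudogene_frac = 0.1,
                                  seed = 1, hindiii_spacing = 4000,
                                  gene_len_range = c(5000, 20000),
                                  exclude = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (pseudogene_frac < 0 || pseudogene_frac >= 1) {
    stop("pseudogene_frac must be in [0, 1)")
  }
  chroms <- paste0("chr", seq_len(n_chrom))
  chrom_lengths <- stats::setNames(rep(chrom_len, n_chrom), chroms)
  with_seed(seed, {
    seqs <- lapply(chroms, function(chrom) {
      s <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
      at <- seq(hindiii_spacing, chrom_len - 10, by = hindiii_spacing)
      at <- at + sample(-500:500, length(at), replace = TRUE)
      at <- at[at > 0 & at + 6 <= chrom_len]
      for (p in at) s[p:(p + 5)] <- c("A", "A", "G", "C", "T", "T")
      paste(s, collapse = "")
    })
    fasta <- Biostrings::DNAStringSet(unlist(seqs))
    names(fasta) <- chroms

    # slot-based placement guarantees non-overlap inside allowed space
    slot <- gene_len_range[2] + 5000
    slots <- do.call(rbind, lapply(chroms, function(chrom) {
      free <- free_segments(chrom_len, exclude[exclude$chrom == chrom, ])
      do.call(rbind, lapply(seq_len(nrow(free)), function(i) {
        k <- floor((free$end[i] - free$start[i]) / slot)
        if (k < 1) return(NULL)
        data.frame(chrom = chrom,
                   start = free$start[i] + (seq_len(k) - 1) * slot)
      }))
    }))
    if (is.null(slots) || nrow(slots) < n_genes) {
      stop("genome too small to place ", n_genes,
           " genes without overlap (capacity ",
           if (is.null(slots)) 0 else nrow(slots), ")")
    }
    pick <- sort(sample.int(nrow(slots), n_genes))
    glen <- round(stats::runif(n_genes, gene_len_range[1],
                               gene_len_range[2]))
    offset <- vapply(glen, function(l)
      sample.int(slot - l - 1000, 1), numeric(1))
    gstart <- slots$start[pick] + offset
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    n_pseudo <- round(pseudogene_frac * n_genes)
    pseudo <- rep(FALSE, n_genes)
    if (n_pseudo > 0) pseudo[sample.int(n_genes, n_pseudo)] <- TRUE
    genes <- data.frame(
      gene_id = sprintf("GENE%04d", seq_len(n_genes)),
      chrom = slots$chrom[pick],
      start = gstart, end = gstart + glen, strand = strand,
      tss = ifelse(strand == "+", gstart, gstart + glen - 1),
      pseudogene = pseudo, stringsAsFactors = FALSE)

    features <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      gene_features(genes[i, ])
    }))
    rownames(features) <- NULL
    list(genes = new_gene_models(genes, features, chrom_lengths),
         fasta = fasta)
  })
}

# exon/intron decomposition: 2-5 exons, CDS in the interior exons of
# protein-coding genes, UTR at the ends; pseudogene exons are all "utr"
gene_features <- function(g) {
  len <- g$end - g$start
  n_exons <- sample(2:5, 1)
  cuts <- sort(sample.int(len - 2, 2 * n_exons - 2)) # internal breakpoints
  bounds <- c(0, cuts, len)
  starts <- bounds[seq(1, 2 * n_exons - 1, by = 2)]
  ends <- bounds[seq(2, 2 * n_exons, by = 2)]
  exons <- data.frame(start = g$start + starts, end = g$start + ends)
  introns <- if (n_exons > 1) {
    data.frame(start = exons$end[-n_exons], end = exons$start[-1])
  } else NULL
  if (g$pseudogene) {
    feat <- rbind(
      data.frame(exons, feature = "utr"),
      if (!is.null(introns)) data.frame(introns, feature = "intron"))
  } else {
    # first and last ~1/3 of the terminal exons are UTR, the rest CDS
    utr5 <- round((exons$end[1] - exons$start[1]) / 3)
    utr3 <- round((exons$end[n_exons] - exons$start[n_exons]) / 3)
    cds <- exons
    cds$start[1] <- cds$start[1] + utr5
    cds$end[n_exons] <- cds$end[n_exons] - utr3
    feat <- rbind(
      data.frame(start = exons$start[1], end = exons$start[1] + utr5,
                 feature = "utr"),
      data.frame(cds, feature = "cds"),
      data.frame(start = exons$end[n_exons] - utr3,
                 end = exons$end[n_exons], feature = "utr"),
      if (!is.null(introns)) data.frame(introns, feature = "intron"))
  }
  feat <- feat[feat$end > feat$start, , drop = FALSE]
  data.frame(chrom = g$chrom, start = feat$start, end = feat$end,
             gene_id = g$gene_id, feature = feat$feature,
             stringsAsFactors = FALSE)
}
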