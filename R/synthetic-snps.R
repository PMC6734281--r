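#' Generate a GWAS-catalog-dialect SNP table with planted structure
#'
#' Emits rsID-like identifiers, 1-based positions, consequence labels
#' (intergenic/intronic/utr/missense/synonymous placements drawn against
#' the gene models), trait text and association p-values log-uniform over
#' `p_range` so the conventional 1e-6 suggestive threshold is straddled.
#' A planted subset of the sub-threshold non-coding SNPs is designated
#' for enhancer placement downstream. Decoy rows with an unrelated trait
#' and a couple of confirmed-list SNPs above the threshold exercise the
#' catalog filter.
#'
#' @param genes a `gene_models` object
#' @param n_snps number of main-trait SNPs (0 gives an empty table)
#' @param frac_noncoding fraction of SNPs placed in non-coding space
#' @param frac_enhancer fraction of sub-threshold non-coding SNPs
#'   designated enhancer-resident
#' @param p_range (min, max) of association p-values
#' @param seed generator stream seed
#' @param trait main trait text
#' @param decoy_trait trait for decoy rows (filtered out downstream)
#' @param n_decoys decoy row count
#' @param n_confirmed SNPs given p above threshold but meant for the
#'   confirmed include-list
#' @param exclude interval `data.frame` SNP positions must avoid
#' @param min_spacing minimum distance between SNPs in bp
#' @return list(catalog, truth, include_list); truth has one row per
#'   main-trait SNP with placement class and planted flags
#' @export
gen_snp_catalog <- function(genes, n_snps = 80, frac_noncoding = 0.9,
                            frac_enhancer = 0.45,
                            p_range = c(1e-9, 1e-4), seed = 1,
                            trait = "Alzheimer's disease",
                            decoy_trait = "Type 2 diabetes",
                            n_decoys = 4, n_confirmed = 2,
                            exclude = NULL, min_spacing = 10000) {
  stopifnot(frac_noncoding >= 0, frac_noncoding <= 1,
            frac_enhancer >= 0, frac_enhancer <= 1)
  cols <- c("rsid", "chrom", "pos", "trait", "pvalue", "consequence",
            "mapped_gene")
  if (n_snps == 0) {
    empty <- stats::setNames(
      data.frame(character(), character(), integer(), character(),
                 numeric(), character(), character()), cols)
    return(list(catalog = empty, truth = empty[0, ],
                include_list = character()))
  }
  with_seed(seed, {
    n_nc <- round(frac_noncoding * n_snps)
    n_cod <- n_snps - n_nc
    classes <- c(sample(rep(c("intronic", "intergenic", "utr"),
                            length.out = n_nc)),
                 sample(rep(c("missense", "synonymous"),
                            length.out = n_cod)))
    pos <- place_snps(genes, classes, exclude, min_spacing)
    n_total <- n_snps + n_decoys + n_confirmed
    rsid <- sprintf("rs%07d", sample.int(9999999, n_total))
    lp <- stats::runif(n_snps, log10(p_range[1]), log10(p_range[2]))
    sub <- which(lp < -6 & classes %in% NONCODING_CLASSES)
    n_enh <- round(frac_enhancer * length(sub))
    enh_idx <- sort(sample(sub, n_enh))
    truth <- data.frame(
      rsid = rsid[seq_len(n_snps)], chrom = pos$chrom, pos = pos$pos,
      class = classes, pvalue = 10^lp,
      below_threshold = lp < -6,
      planted_enhancer = seq_len(n_snps) %in% enh_idx,
      stringsAsFactors = FALSE)
    consequence <- c(intronic = "intron_variant",
                     intergenic = "intergenic_variant",
                     utr = "UTR_variant",
                     missense = "missense_variant",
                     synonymous = "synonymous_variant")[classes]
    mapped <- nearest_gene(genes, pos$chrom, pos$pos)
    catalog <- data.frame(rsid = truth$rsid, chrom = truth$chrom,
                          pos = truth$pos, trait = trait,
                          pvalue = truth$pvalue,
                          consequence = unname(consequence),
                          mapped_gene = mapped, stringsAsFactors = FALSE)
    # confirmed SNPs: main trait, p above threshold, kept via include_list
    conf_idx <- n_snps + seq_len(n_confirmed)
    if (n_confirmed > 0) {
      cpos <- place_snps(genes, rep("intronic", n_confirmed), exclude,
                         min_spacing, avoid = pos)
      conf <- data.frame(rsid = rsid[conf_idx], chrom = cpos$chrom,
                         pos = cpos$pos, trait = trait,
                         pvalue = 10^stats::runif(n_confirmed, -5.5, -4.5),
                         consequence = "intron_variant",
                         mapped_gene = nearest_gene(genes, cpos$chrom,
                                                    cpos$pos),
                         stringsAsFactors = FALSE)
      catalog <- rbind(catalog, conf)
      truth <- rbind(truth, data.frame(
        rsid = conf$rsid, chrom = conf$chrom, pos = conf$pos,
        class = "intronic", pvalue = conf$pvalue,
        below_threshold = FALSE, planted_enhancer = FALSE))
    }
    if (n_decoys > 0) {
      didx <- n_snps + n_confirmed + seq_len(n_decoys)
      dpos <- place_snps(genes, rep("intergenic", n_decoys), exclude,
                         min_spacing, avoid = pos)
      catalog <- rbind(catalog, data.frame(
        rsid = rsid[didx], chrom = dpos$chrom, pos = dpos$pos,
        trait = decoy_trait,
        pvalue = 10^stats::runif(n_decoys, -9, -7),
        consequence = "intergenic_variant",
        mapped_gene = nearest_gene(genes, dpos$chrom, dpos$pos),
        stringsAsFactors = FALSE))
    }
    catalog <- catalog[sample.int(nrow(catalog)), ]
    rownames(catalog) <- NULL
    list(catalog = catalog, truth = truth,
         include_list = rsid[if (n_confirmed > 0) conf_idx else integer()])
  })
}

# draw SNP positions of requested placement classes, respecting
# exclusion zones and minimum spacing
place_snps <- function(genes, classes, exclude, min_spacing,
                       avoid = NULL) {
  feats <- genes$features
  gb <- genes$genes
  chrom_lengths <- genes$chrom_lengths
  taken <- if (is.null(avoid)) {
    data.frame(chrom = character(), pos = integer())
  } else avoid[, c("chrom", "pos")]
  ok_pos <- function(chrom, p) {
    if (!is.null(exclude) && nrow(exclude)) {
      ex <- exclude[exclude$chrom == chrom, , drop = FALSE]
      if (any(p > ex$start & p <= ex$end)) return(FALSE)
    }
    near <- taken$pos[taken$chrom == chrom]
    !length(near) || min(abs(near - p)) >= min_spacing
  }
  draw_from <- function(iv) {
    # iv: candidate intervals (0-based half-open); returns 1-based pos
    for (try in seq_len(2000)) {
      i <- sample.int(nrow(iv), 1)
      if (iv$end[i] - iv$start[i] < 3) next
      p <- sample((iv$start[i] + 1):(iv$end[i]), 1)
      if (ok_pos(iv$chrom[i], p)) {
        return(list(chrom = iv$chrom[i], pos = p))
      }
    }
    stop("could not place SNP; relax exclusion or spacing")
  }
  intergenic <- do.call(rbind, lapply(names(chrom_lengths), function(chrom) {
    g <- gb[gb$chrom == chrom, ]
    fs <- free_segments(chrom_lengths[[chrom]],
                        data.frame(start = g$start, end = g$end))
    data.frame(chrom = chrom, fs)
  }))
  pool <- list(
    intronic = feats[feats$feature == "intron", c("chrom", "start", "end")],
    utr = feats[feats$feature == "utr" &
                  !feats$gene_id %in% gb$gene_id[gb$pseudogene],
                c("chrom", "start", "end")],
    missense = feats[feats$feature == "cds", c("chrom", "start", "end")],
    synonymous = feats[feats$feature == "cds", c("chrom", "start", "end")],
    intergenic = intergenic)
  out <- data.frame(chrom = character(length(classes)),
                    pos = integer(length(classes)))
  for (i in seq_along(classes)) {
    hit <- draw_from(pool[[classes[i]]])
    out$chrom[i] <- hit$chrom
    out$pos[i] <- hit$pos
    taken <- rbind(taken, data.frame(chrom = hit$chrom, pos = hit$pos))
  }
  out
}

nearest_gene <- function(genes, chrom, pos) {
  vapply(seq_along(chrom), function(i) {
    g <- genes$genes[genes$genes$chrom == chrom[i], ]
    if (nrow(g) == 0) return(NA_character_)
    d <- abs(g$tss - (pos[i] - 1))
    g$gene_id[order(d, g$tss)][1]
  }, character(1))
}

#' Write a SNP catalog table as TSV
#' @param catalog catalog `data.frame`
#' @param path output path
#' @export
write_snp_catalog <- function(catalog, path) {
  write_tsv(catalog, path)
}
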