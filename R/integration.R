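#' Count peak-bearing cell types per SNP and factor
#'
#' For each ChIP-seq factor (e.g. CTCF, RNAPII), counts the cell types
#' whose peak intervals contain the SNP position.
#'
#' @param snps SNP `data.frame` (rsid, chrom, pos)
#' @param peaks `data.frame` with columns factor, cell_type, path (one
#'   peak BED per factor x cell type)
#' @return `data.frame` with rsid and one `<factor>_celltypes` count
#'   column per factor
#' @export
ctcf_overlap <- function(snps, peaks) {
  pts <- point_interval(snps$chrom, snps$pos)
  out <- data.frame(rsid = snps$rsid, stringsAsFactors = FALSE)
  for (fac in unique(peaks$factor)) {
    sel <- peaks[peaks$factor == fac, ]
    count <- integer(nrow(snps))
    for (i in seq_len(nrow(sel))) {
      iv <- read_bed(sel$path[i])
      hit <- interval_overlap(pts, iv)
      count[unique(hit$query)] <- count[unique(hit$query)] + 1L
    }
    out[[paste0(fac, "_celltypes")]] <- count
  }
  out
}

#' TAD co-localization of a SNP with its eQTL genes
#'
#' A gene co-localizes with the SNP iff its TSS bin and the SNP's bin
#' fall in the same TAD block (half-open blocks; boundary bins belong to
#' the block containing the bin index). Genes on another chromosome
#' cannot co-localize by definition.
#'
#' @param snp one-row SNP `data.frame` (chrom, pos)
#' @param gene_ids the SNP's eQTL gene ids
#' @param genes a `gene_models` object
#' @param tads named list of `tad_segmentation` per chromosome
#' @return list(flags = named logical per gene, fraction, over80)
#' @export
snp_gene_tad_colocalization <- function(snp, gene_ids, genes, tads) {
  stopifnot(nrow(snp) == 1)
  seg <- tads[[snp$chrom]]
  if (is.null(seg)) stop("no TAD segmentation for ", snp$chrom)
  bin_size <- seg$bin_size
  snp_block <- tad_block_of(seg, floor((snp$pos - 1) / bin_size))
  g <- genes$genes[match(gene_ids, genes$genes$gene_id), ]
  flags <- stats::setNames(rep(FALSE, length(gene_ids)), gene_ids)
  same <- g$chrom == snp$chrom
  if (any(!same)) {
    message(sum(!same), " eQTL gene(s) on another chromosome than ",
            snp$rsid %||% "SNP", ": not co-localizable")
  }
  if (any(same)) {
    segs <- tads[[snp$chrom]]
    gb <- tad_block_of(segs, floor(g$tss[same] / bin_size))
    flags[same] <- gb == snp_block
  }
  frac <- if (length(flags)) mean(flags) else NA_real_
  list(flags = flags, fraction = frac,
       over80 = !is.na(frac) && frac > 0.8)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genes whose TSS lies near a significant viewpoint interaction
#'
#' A gene is contacted iff any significant target fragment lies within
#' `max_dist` of its TSS (interval-to-point distance; 0 when the
#' fragment contains the TSS).
#'
#' @param calls output of [call_viewpoint_interactions()]
#' @param genes a `gene_models` object
#' @param max_dist maximum fragment-to-TSS distance in bp (default 5000)
#' @return character vector of contacted gene ids
#' @export
loops_near_tss <- function(calls, genes, max_dist = 5000) {
  sig <- calls[calls$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(character(0))
  g <- genes$genes
  g <- g[g$chrom %in% unique(sig$chrom), , drop = FALSE]
  hit <- vapply(seq_len(nrow(g)), function(i) {
    s <- sig[sig$chrom == g$chrom[i], , drop = FALSE]
    d <- pmax(s$start - g$tss[i], g$tss[i] - (s$end - 1), 0)
    any(d <= max_dist)
  }, logical(1))
  sort(g$gene_id[hit])
}

#' Run the full evidence cascade on a scenario configuration
#'
#' Stages, in order: catalog filter, region classification, enhancer
#' annotation, eQTL join, DEG overlap, TF peak overlap, Hi-C matrix
#' build + TAD calling per cell line, TAD co-localization, and viewpoint
#' loop calling for the configured SNPs. Per-stage tables are written
#' under `paths$outdir`; each stage consumes only the outputs of earlier
#' stages, so the surviving SNP set shrinks monotonically.
#'
#' @param config a list (or path to a YAML file) with `paths`, `params`
#'   and `stages` entries as written by [generate_scenario()]
#' @return list with `evidence` (per-SNP table), `stage_counts`,
#'   `enrichment` (per dataset x region), `summary` and the fitted
#'   per-cell-line `tads`
#' @export
run_cascade <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  p <- config$paths
  prm <- config$params
  stages <- config$stages %||% list()
  outdir <- p$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  genes <- read_gene_models_gff(p$genes_gff)
  snps <- load_snp_catalog(p$catalog, trait_pattern = prm$trait_pattern,
                           p_threshold = prm$p_threshold,
                           include_list = unlist(prm$include_list))
  snps <- classify_snp_region(snps, genes)
  write_tsv(snps, file.path(outdir, "snps_classified.tsv"))
  nc <- snps[snps$noncoding, , drop = FALSE]

  counts <- c(catalog_rows = nrow(read_tsv(p$catalog)),
              retained = nrow(snps), noncoding = nrow(nc))

  enhancer_enabled <- !identical(stages$enhancer, FALSE)
  if (enhancer_enabled) {
    meta <- read_tsv(file.path(p$states_dir, "epigenomes.tsv"))
    segs <- lapply(seq_len(nrow(meta)), function(i)
      load_state_segmentation(meta$path[i], meta$epigenome_id[i],
                              meta$epigenome_id[meta$is_brain]))
    ann <- annotate_snp_enhancers(nc, segs,
                                  enhancer_states =
                                    unlist(prm$enhancer_states) %||%
                                    ENHANCER_STATES)
    write_tsv(ann, file.path(outdir, "enhancer_annotation.tsv"))
    enh_summary <- summarize_enhancer_tissues(ann)
    write_tsv(enh_summary, file.path(outdir, "enhancer_summary.tsv"))
    enh <- nc[ann$in_enhancer, , drop = FALSE]
    enh_ann <- ann[ann$in_enhancer, , drop = FALSE]
  } else {
    message("enhancer stage disabled: passing all non-coding SNPs through")
    ann <- data.frame(rsid = nc$rsid, enhancer_count = NA_integer_,
                      brain_enhancer_count = NA_integer_,
                      in_enhancer = NA, in_brain_enhancer = NA)
    enh_summary <- NULL
    enh <- nc
    enh_ann <- ann
  }
  counts <- c(counts, enhancer = nrow(enh),
              brain_enhancer = sum(enh_ann$in_brain_enhancer %in% TRUE))

  eqtl_raw <- read_tsv(p$eqtl)
  eq <- filter_eqtl_associations(eqtl_raw, enh, genes,
                                 alpha = prm$q_alpha %||% 0.05)
  write_tsv(eq$associations, file.path(outdir, "eqtl_associations.tsv"))
  eqtl_snps <- enh[enh$rsid %in% names(eq$snp_genes), , drop = FALSE]
  counts <- c(counts, eqtl_snps = nrow(eqtl_snps),
              eqtl_genes = length(unique(unlist(eq$snp_genes))))

  degs <- do.call(rbind, lapply(config$paths$expression, function(ds) {
    expr_df <- read_tsv(ds$expr)
    expr <- as.matrix(expr_df[, -1])
    rownames(expr) <- expr_df$gene_id
    meta <- read_tsv(ds$samples)
    call_degs(expr, labels = meta$diagnosis,
              covariates = meta[, setdiff(names(meta),
                                          c("sample_id", "diagnosis")),
                                drop = FALSE],
              model = ds$model, alpha = prm$deg_alpha %||% 0.05,
              case_level = "AD", dataset = ds$dataset,
              brain_region = ds$region)
  }))
  write_tsv(degs, file.path(outdir, "degs.tsv"))
  ov <- overlap_eqtl_degs(eq$snp_genes, degs)
  write_tsv(ov$enrichment, file.path(outdir, "deg_enrichment.tsv"))
  counts <- c(counts,
              deg_overlap_snps = sum(ov$deg_overlap[eqtl_snps$rsid]))

  peaks <- do.call(rbind, lapply(p$peaks, as.data.frame))
  tf <- ctcf_overlap(eqtl_snps, peaks)
  fac_cols <- setdiff(names(tf), "rsid")
  counts <- c(counts,
              tf_snps = sum(rowSums(tf[, fac_cols, drop = FALSE]) > 0))

  frag <- if (!is.null(p$fasta)) digest_fragments(fasta = p$fasta) else
    digest_fragments(sites_bed = p$sites_bed,
                     chrom_lengths = unlist(p$chrom_lengths))
  cell_lines <- lapply(p$pairs, function(cl) {
    rec <- assign_pairs_to_fragments(read_pairs(cl$path), frag)
    # matrix building applies all three filters; viewpoint profiles keep
    # the capture-enriched fragments the coverage cut would remove
    loop_filt <- filter_pairs(rec$records, remove_high_coverage = FALSE)
    filt <- filter_pairs(rec$records)
    yaml::write_yaml(list(assign = as.list(rec$qc),
                          filter = as.list(filt$qc)),
                     file.path(outdir, paste0("qc_", cl$cell_line,
                                              ".yaml")))
    mats <- bin_contacts(filt$records, frag,
                         bin_size = prm$bin_size %||% 1e5)
    tads <- lapply(mats, function(cm) {
      norm <- ice_normalize(cm)
      seg <- tad_segment_ml(norm, K_max = prm$tad_k_max %||% 20)
      write_tads_bed(seg, file.path(outdir, paste0(
        "tads_", cl$cell_line, "_", cm$chrom, ".bed")))
      seg
    })
    list(cell_line = cl$cell_line, records = filt$records,
         loop_records = loop_filt$records, tads = tads)
  })

  tad_cols <- lapply(cell_lines, function(cl) {
    vapply(seq_len(nrow(eqtl_snps)), function(i) {
      res <- snp_gene_tad_colocalization(
        eqtl_snps[i, ], eq$snp_genes[[eqtl_snps$rsid[i]]], genes,
        cl$tads)
      res$fraction
    }, numeric(1))
  })
  names(tad_cols) <- vapply(cell_lines, `[[`, "", "cell_line")

  loop_genes <- list()
  vp_snps <- unlist(prm$viewpoint_snps)
  if (length(vp_snps)) {
    cl <- cell_lines[[prm$loop_cell_line %||% 1]]
    for (rs in vp_snps) {
      snp <- snps[snps$rsid == rs, , drop = FALSE]
      vp <- select_viewpoint(snp, frag)
      calls <- call_viewpoint_interactions(
        vp, cl$loop_records, frag, window = prm$window %||% 1,
        alpha = prm$loop_alpha %||% 0.05)
      write_tsv(calls, file.path(outdir, paste0("loops_", rs, ".tsv")))
      loop_genes[[rs]] <- loops_near_tss(calls, genes,
                                         max_dist = prm$tss_max_dist %||%
                                           5000)
    }
  }
  counts <- c(counts,
              loop_genes = length(unique(unlist(loop_genes))))

  evidence <- data.frame(
    rsid = eqtl_snps$rsid, chrom = eqtl_snps$chrom, pos = eqtl_snps$pos,
    region_class = eqtl_snps$region_class,
    enhancer_count =
      enh_ann$enhancer_count[match(eqtl_snps$rsid, enh_ann$rsid)],
    brain_enhancer_count =
      enh_ann$brain_enhancer_count[match(eqtl_snps$rsid, enh_ann$rsid)],
    n_eqtl_genes = lengths(eq$snp_genes[eqtl_snps$rsid]),
    eqtl_genes = vapply(eq$snp_genes[eqtl_snps$rsid], paste,
                        "", collapse = ","),
    deg_overlap = unname(ov$deg_overlap[eqtl_snps$rsid]),
    closest_gene = closest_gene(genes, eqtl_snps),
    stringsAsFactors = FALSE)
  for (fc in fac_cols) evidence[[fc]] <- tf[[fc]]
  for (cl in names(tad_cols)) {
    evidence[[paste0("tad_frac_", cl)]] <- tad_cols[[cl]]
    evidence[[paste0("tad_over80_", cl)]] <- tad_cols[[cl]] > 0.8
  }
  frac_mat <- do.call(cbind, tad_cols)
  evidence$tad_any <- if (length(tad_cols))
    rowSums(frac_mat > 0, na.rm = TRUE) > 0 else NA
  evidence$loop_genes <- vapply(evidence$rsid, function(rs)
    paste(loop_genes[[rs]] %||% character(0), collapse = ","), "")
  counts <- c(counts, tad_coloc_snps = sum(evidence$tad_any))
  write_tsv(evidence, file.path(outdir, "evidence.tsv"))

  res <- list(evidence = evidence, stage_counts = counts,
              enrichment = ov$enrichment, enhancer_summary = enh_summary,
              snp_genes = eq$snp_genes, loop_genes = loop_genes,
              tads = lapply(cell_lines, `[[`, "tads"))
  res$summary <- cascade_summary(res)
  writeLines(write_report(res), file.path(outdir, "report.txt"))
  res
}

closest_gene <- function(genes, snps) {
  nearest_gene(genes, snps$chrom, snps$pos)
}

cascade_summary <- function(res) {
  ct <- res$stage_counts
  pct <- function(num, den) if (den == 0) 0 else 100 * num / den
  data.frame(
    n_retained = ct[["retained"]],
    n_noncoding = ct[["noncoding"]],
    pct_noncoding = pct(ct[["noncoding"]], ct[["retained"]]),
    n_enhancer = ct[["enhancer"]],
    pct_enhancer = pct(ct[["enhancer"]], ct[["noncoding"]]),
    n_brain_enhancer = ct[["brain_enhancer"]],
    pct_brain_enhancer = pct(ct[["brain_enhancer"]], ct[["noncoding"]]),
    n_eqtl_snps = ct[["eqtl_snps"]],
    n_eqtl_genes = ct[["eqtl_genes"]],
    n_deg_overlap = ct[["deg_overlap_snps"]],
    pct_deg_overlap = pct(ct[["deg_overlap_snps"]], ct[["eqtl_snps"]]),
    n_tad_coloc = ct[["tad_coloc_snps"]],
    pct_tad_coloc = pct(ct[["tad_coloc_snps"]], ct[["eqtl_snps"]]),
    n_loop_genes = ct[["loop_genes"]])
}

#' Render the cascade summary as a human-readable report
#' @param res result of [run_cascade()]
#' @return character vector of report lines
#' @export
write_report <- function(res) {
  s <- res$summary
  c(sprintf("SNPs retained after catalog filter: %d", s$n_retained),
    sprintf("Non-coding: %d (%.1f%%)", s$n_noncoding, s$pct_noncoding),
    sprintf("In enhancers (>=1 epigenome): %d (%.1f%% of non-coding)",
            s$n_enhancer, s$pct_enhancer),
    sprintf("In brain enhancers: %d (%.1f%% of non-coding)",
            s$n_brain_enhancer, s$pct_brain_enhancer),
    sprintf("With >=1 eQTL gene: %d (eQTL genes: %d)",
            s$n_eqtl_snps, s$n_eqtl_genes),
    sprintf("With >=1 differentially expressed eQTL gene: %d (%.1f%%)",
            s$n_deg_overlap, s$pct_deg_overlap),
    sprintf("TAD co-localized with >=1 eQTL gene: %d (%.1f%%)",
            s$n_tad_coloc, s$pct_tad_coloc),
    sprintf("Genes contacted by viewpoint loops: %d", s$n_loop_genes))
}
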