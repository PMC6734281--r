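#' Default synthetic-scenario configuration
#'
#' The packaged study conditions: a two-chromosome 5-Mb-per-chromosome
#' genome, 70 genes (10% pseudogenes), 70 main-trait SNPs straddling the
#' 1e-6 threshold, 8 epigenomes (3 brain), three expression datasets of
#' 20 cases vs 20 controls with a 2-SD planted DEG shift, and two Hi-C
#' cell-line libraries of 120,000 pairs each with distance-decay
#' exponent -1, intra-TAD fold 3 and viewpoint loops of fold 15 under
#' 40x viewpoint capture enrichment. Thresholds mirror the cascade's
#' conventions: p < 1e-6, q < 0.05, FDR < 0.05, 100-kb bins, window 1,
#' 5-kb TSS distance.
#'
#' @return nested list of scenario parameters
#' @export
scenario_config <- function() {
  list(
    genome = list(n_chrom = 2, chrom_len = 5e6, n_genes = 70,
                  pseudogene_frac = 0.1, hindiii_spacing = 6000),
    bin_size = 1e5,
    tads = list(min_bins = 5, max_bins = 12),
    snps = list(n_snps = 70, frac_noncoding = 0.9, frac_enhancer = 0.5,
                p_range = c(1e-9, 1e-4), trait = "Alzheimer's disease"),
    states = list(n_epigenomes = 8, n_brain = 3),
    eqtl = list(frac_eqtl_snps = 0.6, genes_per_snp = c(1, 3),
                viewpoint_genes = c(4, 6), frac_off_platform = 0.3),
    expression = list(
      n_case = 20, n_control = 20, deg_effect = 2,
      deg_frac_eqtl = 0.6, deg_frac_other = 0.1,
      datasets = list(
        list(dataset = "rnaseq1", region = "TC",
             model = "linear_covariates"),
        list(dataset = "array1", region = "HIP", model = "ttest"),
        list(dataset = "array2", region = "PFC",
             model = "logistic_covariates"))),
    peaks = list(factors = list(CTCF = 10, RNAPII = 6)),
    hic = list(n_pairs = 120000, decay_exponent = -1, intra_tad_fold = 3,
               dup_frac = 0.05, self_frac = 0.02, loop_fold = 15,
               viewpoint_enrichment = 40, cell_lines = c("cl1", "cl2")),
    params = list(trait_pattern = "Alzheimer", p_threshold = 1e-6,
                  q_alpha = 0.05, deg_alpha = 0.05, bin_size = 1e5,
                  window = 1, loop_alpha = 0.05, tss_max_dist = 5000,
                  tad_k_max = 15, loop_cell_line = 1))
}

#' Generate the complete synthetic scenario with planted ground truth
#'
#' Writes every input the cascade consumes (genome FASTA, GFF gene
#' models, SNP catalog, per-epigenome state BEDs, eQTL table, three
#' expression datasets, ChIP-seq peak BEDs, two Hi-C pair libraries and
#' a scenario YAML) into `dir`, and returns the planted truth: TAD
#' boundaries, loop anchors, enhancer SNP counts, eQTL pairs, DEG genes,
#' and the derived per-stage expectations the cascade should reproduce
#' exactly.
#'
#' @param dir output directory
#' @param seed master seed; all generator streams derive from it
#' @param config scenario configuration (see [scenario_config()])
#' @return list(config_path, config, truth)
#' @export
generate_scenario <- function(dir, seed = 1, config = scenario_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- config
  bin_size <- cfg$bin_size

  # planted TAD boundaries and the exclusion buffer around them
  n_bins <- ceiling(cfg$genome$chrom_len / bin_size)
  chroms <- paste0("chr", seq_len(cfg$genome$n_chrom))
  tad_boundaries <- with_seed(child_seed(seed, "tads"), {
    out <- lapply(chroms, function(chrom) {
      b <- 0
      while (utils::tail(b, 1) < n_bins) {
        b <- c(b, utils::tail(b, 1) +
                 sample(cfg$tads$min_bins:cfg$tads$max_bins, 1))
      }
      b[length(b)] <- n_bins
      if (b[length(b)] - b[length(b) - 1] < cfg$tads$min_bins) {
        b <- b[-(length(b) - 1)]
      }
      b
    })
    names(out) <- chroms
    out
  })
  buffer <- do.call(rbind, lapply(chroms, function(chrom) {
    inner <- setdiff(tad_boundaries[[chrom]], c(0, n_bins))
    if (!length(inner)) return(NULL)
    data.frame(chrom = chrom, start = pmax(0, inner * bin_size - 2 * bin_size),
               end = pmin(cfg$genome$chrom_len, inner * bin_size +
                            2 * bin_size))
  }))

  gen <- gen_genome_annotation(
    n_chrom = cfg$genome$n_chrom, chrom_len = cfg$genome$chrom_len,
    n_genes = cfg$genome$n_genes,
    pseudogene_frac = cfg$genome$pseudogene_frac,
    seed = child_seed(seed, "genome"),
    hindiii_spacing = cfg$genome$hindiii_spacing, exclude = buffer)
  genes <- gen$genes
  fasta_path <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(gen$fasta, fasta_path)
  gff_path <- file.path(dir, "genes.gff3")
  write_gene_models_gff(genes, gff_path)

  snp_gen <- gen_snp_catalog(
    genes, n_snps = cfg$snps$n_snps,
    frac_noncoding = cfg$snps$frac_noncoding,
    frac_enhancer = cfg$snps$frac_enhancer,
    p_range = cfg$snps$p_range, seed = child_seed(seed, "snps"),
    trait = cfg$snps$trait, exclude = buffer)
  catalog_path <- file.path(dir, "snp_catalog.tsv")
  write_snp_catalog(snp_gen$catalog, catalog_path)
  st <- snp_gen$truth
  st$retained <- st$below_threshold | st$rsid %in% snp_gen$include_list
  planted_enh <- st[st$planted_enhancer, , drop = FALSE]

  epi <- cfg$states
  brain_ids <- sprintf("E%03d", seq_len(epi$n_brain))
  states <- gen_chromatin_states(
    genes$chrom_lengths, n_epigenomes = epi$n_epigenomes,
    brain_ids = brain_ids,
    plant = planted_enh[, c("rsid", "chrom", "pos")],
    keep_clear = rbind(
      st[!st$planted_enhancer, c("chrom", "pos")],
      snp_gen$catalog[!snp_gen$catalog$rsid %in% st$rsid,
                      c("chrom", "pos")]),
    seed = child_seed(seed, "states"))
  states_meta <- write_chromatin_states(states, file.path(dir, "states"))

  truth_eqtl <- plant_eqtl_structure(genes, planted_enh, cfg,
                                     child_seed(seed, "eqtl_pairs"))

  expr_cfg <- cfg$expression
  # every SNP with platform-covered eQTL genes gets >= 1 planted DEG,
  # so the per-SNP DEG-overlap flag is exact ground truth
  deg_genes <- with_seed(child_seed(seed, "degs"), {
    on_platform <- truth_eqtl$pairs[
      !truth_eqtl$pairs$rsid %in% truth_eqtl$off_platform_snps, ]
    per_snp <- lapply(split(on_platform$gene_id, on_platform$rsid),
                      function(gset) {
                        k <- max(1, round(expr_cfg$deg_frac_eqtl *
                                            length(gset)))
                        sample(gset, k)
                      })
    other <- setdiff(genes$genes$gene_id[!genes$genes$pseudogene],
                     truth_eqtl$pairs$gene_id)
    sort(unique(c(unlist(per_snp),
                  sample(other, round(expr_cfg$deg_frac_other *
                                        length(other))))))
  })
  datasets <- list()
  eqtl_path <- file.path(dir, "eqtl.tsv")
  for (i in seq_along(expr_cfg$datasets)) {
    ds_cfg <- expr_cfg$datasets[[i]]
    ds <- gen_expression_and_eqtl(
      genes, snps = st, n_case = expr_cfg$n_case,
      n_control = expr_cfg$n_control, deg_effect = expr_cfg$deg_effect,
      eqtl_pairs = truth_eqtl$pairs,
      seed = child_seed(seed, paste0("expr_", ds_cfg$dataset)),
      deg_genes = deg_genes, dataset = ds_cfg$dataset,
      exclude_genes = truth_eqtl$off_platform_genes)
    paths <- write_expression_dataset(ds, file.path(dir, "expression"),
                                      ds_cfg$dataset)
    if (i == 1) write_tsv(ds$eqtl, eqtl_path)
    datasets[[i]] <- c(ds_cfg, list(expr = paths$expr,
                                    samples = paths$samples))
  }

  eqtl_snp_ids <- unique(truth_eqtl$pairs$rsid)
  peak_truth <- gen_peak_tracks(
    dir, st, snp_gen$catalog, eqtl_snp_ids, truth_eqtl$viewpoint,
    cfg$peaks$factors, genes$chrom_lengths,
    child_seed(seed, "peaks"))

  frag <- digest_fragments(fasta = gen$fasta)
  vp_snp <- st[st$rsid == truth_eqtl$viewpoint, , drop = FALSE]
  vp_frags <- select_viewpoint(vp_snp, frag)
  central <- frag_of(frag, vp_snp$chrom, vp_snp$pos - 1)
  loop_target_frags <- unique(frag_of(
    frag, genes$genes$chrom[match(truth_eqtl$loop_genes,
                                  genes$genes$gene_id)],
    genes$genes$tss[match(truth_eqtl$loop_genes, genes$genes$gene_id)]))
  loop_anchors <- expand.grid(viewpoint_frag = vp_frags,
                              target_frag = loop_target_frags)
  loop_anchors$fold <- cfg$hic$loop_fold
  pair_paths <- list()
  for (cl in cfg$hic$cell_lines) {
    hic <- gen_hic_pairs(
      frag, tad_boundaries, bin_size, loop_anchors,
      n_pairs = cfg$hic$n_pairs,
      decay_exponent = cfg$hic$decay_exponent,
      intra_tad_fold = cfg$hic$intra_tad_fold,
      dup_frac = cfg$hic$dup_frac, self_frac = cfg$hic$self_frac,
      enriched_frags = vp_frags,
      viewpoint_enrichment = cfg$hic$viewpoint_enrichment,
      seed = child_seed(seed, paste0("hic_", cl)))
    path <- file.path(dir, paste0("pairs_", cl, ".tsv"))
    write_pairs(hic$pairs, path)
    pair_paths[[length(pair_paths) + 1]] <-
      list(cell_line = cl, path = path)
  }

  config_out <- list(
    paths = list(catalog = catalog_path, genes_gff = gff_path,
                 fasta = fasta_path,
                 states_dir = file.path(dir, "states"),
                 eqtl = eqtl_path, expression = datasets,
                 peaks = peak_truth$peak_index, pairs = pair_paths,
                 outdir = file.path(dir, "out")),
    params = c(cfg$params,
               list(include_list = as.list(snp_gen$include_list),
                    viewpoint_snps = list(truth_eqtl$viewpoint))),
    stages = list(enhancer = TRUE))
  config_path <- file.path(dir, "scenario.yaml")
  yaml::write_yaml(config_out, config_path)

  truth <- build_truth(st, snp_gen, states, truth_eqtl, deg_genes,
                       peak_truth, tad_boundaries, loop_anchors, genes,
                       frag, bin_size, brain_ids, cfg)
  yaml::write_yaml(truth_to_yaml(truth), file.path(dir, "truth.yaml"))
  list(config_path = config_path, config = config_out, truth = truth,
       genes = genes, frag = frag)
}

# choose the viewpoint SNP, its loop genes and all planted eQTL pairs;
# gene sets are disjoint across SNPs, and a fraction of non-viewpoint
# SNPs get genes that will be absent from the expression platforms so
# their DEG-overlap status is deterministically false
plant_eqtl_structure <- function(genes, planted_enh, cfg, seed) {
  g <- genes$genes[!genes$genes$pseudogene, ]
  with_seed(seed, {
    cand <- planted_enh[sample.int(nrow(planted_enh)), ]
    viewpoint <- NULL
    best_n <- -1L
    for (i in seq_len(nrow(cand))) {
      near <- g[g$chrom == cand$chrom[i] &
                  abs(g$tss - cand$pos[i]) <= 6e5 &
                  abs(g$tss - cand$pos[i]) >= 5e4, ]
      if (nrow(near) >= cfg$eqtl$viewpoint_genes[1]) {
        viewpoint <- cand$rsid[i]
        vp_near <- near
        break
      }
      if (nrow(near) > best_n) {   # fallback: densest neighbourhood
        best_n <- nrow(near)
        viewpoint <- cand$rsid[i]
        vp_near <- near
      }
    }
    if (is.null(viewpoint) || nrow(vp_near) < 2) {
      stop("no viewpoint candidate with enough nearby genes; ",
           "enlarge the scenario")
    }
    n_vp_genes <- min(sample(cfg$eqtl$viewpoint_genes[1]:
                               cfg$eqtl$viewpoint_genes[2], 1),
                      nrow(vp_near))
    vp_genes <- sample(vp_near$gene_id, n_vp_genes)
    others <- planted_enh[planted_enh$rsid != viewpoint, ]
    n_eqtl <- round(cfg$eqtl$frac_eqtl_snps * nrow(others))
    chosen <- others[sample.int(nrow(others), n_eqtl), ]
    available <- setdiff(g$gene_id, vp_genes)
    pairs <- list(data.frame(rsid = viewpoint, gene_id = vp_genes))
    for (i in seq_len(nrow(chosen))) {
      pool <- intersect(g$gene_id[g$chrom == chosen$chrom[i]], available)
      if (!length(pool)) next
      k <- sample(cfg$eqtl$genes_per_snp[1]:cfg$eqtl$genes_per_snp[2], 1)
      picked <- sample(pool, min(k, length(pool)))
      available <- setdiff(available, picked)
      pairs[[length(pairs) + 1]] <-
        data.frame(rsid = chosen$rsid[i], gene_id = picked)
    }
    pairs <- unique(do.call(rbind, pairs))
    rownames(pairs) <- NULL
    loop_genes <- sort(sample(vp_genes,
                              max(2, round(0.6 * length(vp_genes)))))
    non_vp_snps <- setdiff(unique(pairs$rsid), viewpoint)
    off_platform_snps <- sort(sample(
      non_vp_snps, round(cfg$eqtl$frac_off_platform *
                           length(non_vp_snps))))
    off_platform_genes <-
      sort(unique(pairs$gene_id[pairs$rsid %in% off_platform_snps]))
    list(pairs = pairs, viewpoint = viewpoint, loop_genes = loop_genes,
         off_platform_snps = off_platform_snps,
         off_platform_genes = off_platform_genes)
  })
}

# peak BEDs per factor x cell type with planted per-SNP cell-type counts
gen_peak_tracks <- function(dir, st, catalog, eqtl_snp_ids, viewpoint,
                            factors, chrom_lengths, seed) {
  pdir <- file.path(dir, "peaks")
  dir.create(pdir, showWarnings = FALSE, recursive = TRUE)
  all_pos <- catalog[, c("chrom", "pos")]
  with_seed(seed, {
    peak_index <- list()
    truth <- list()
    for (fac in names(factors)) {
      n_ct <- factors[[fac]]
      counts <- stats::setNames(sample(0:n_ct, length(eqtl_snp_ids),
                                       replace = TRUE), eqtl_snp_ids)
      if (fac == "CTCF") counts[viewpoint] <- max(counts[viewpoint], 1L)
      member <- lapply(eqtl_snp_ids, function(rs)
        if (counts[rs] > 0) sample.int(n_ct, counts[rs]) else integer())
      names(member) <- eqtl_snp_ids
      for (ct in seq_len(n_ct)) {
        rows <- list()
        for (rs in eqtl_snp_ids) {
          if (ct %in% member[[rs]]) {
            s <- st[st$rsid == rs, ]
            rows[[length(rows) + 1]] <-
              data.frame(chrom = s$chrom,
                         start = max(0, s$pos - 1 - 150),
                         end = s$pos - 1 + 150)
          }
        }
        # background peaks away from every SNP
        for (k in 1:15) {
          chrom <- sample(names(chrom_lengths), 1)
          for (try in 1:50) {
            p <- sample.int(chrom_lengths[[chrom]] - 400, 1)
            near <- all_pos$pos[all_pos$chrom == chrom]
            if (!length(near) || min(abs(near - p)) > 2000) break
            p <- NA
          }
          if (!is.na(p)) {
            rows[[length(rows) + 1]] <-
              data.frame(chrom = chrom, start = p, end = p + 300)
          }
        }
        bed <- do.call(rbind, rows)
        bed <- bed[order(bed$chrom, bed$start), ]
        bed$label <- paste0(fac, "_peak")
        path <- file.path(pdir, sprintf("%s_ct%02d.bed", fac, ct))
        write_bed(bed, path)
        peak_index[[length(peak_index) + 1]] <-
          list(factor = fac, cell_type = sprintf("ct%02d", ct),
               path = path)
      }
      truth[[fac]] <- counts
    }
    list(peak_index = peak_index, truth = truth)
  })
}

build_truth <- function(st, snp_gen, states, truth_eqtl, deg_genes,
                        peak_truth, tad_boundaries, loop_anchors, genes,
                        frag, bin_size, brain_ids, cfg) {
  retained <- st[st$retained, ]
  noncoding <- retained[retained$class %in% NONCODING_CLASSES, ]
  enh_truth <- states$truth
  eqtl_snp_ids <- unique(truth_eqtl$pairs$rsid)
  snp_genes <- lapply(split(truth_eqtl$pairs$gene_id,
                            truth_eqtl$pairs$rsid), function(g)
                              sort(unique(g)))
  deg_overlap <- vapply(snp_genes, function(g) any(g %in% deg_genes),
                        logical(1))
  stopifnot(identical(unname(deg_overlap),
                      !names(snp_genes) %in% truth_eqtl$off_platform_snps))
  # TAD co-localization from planted boundaries
  tad_seg <- lapply(names(tad_boundaries), function(chrom)
    structure(list(chrom = chrom, bin_size = bin_size,
                   boundaries = tad_boundaries[[chrom]],
                   K = length(tad_boundaries[[chrom]]) - 1),
              class = "tad_segmentation"))
  names(tad_seg) <- names(tad_boundaries)
  tad_frac <- vapply(eqtl_snp_ids, function(rs) {
    s <- st[st$rsid == rs, ]
    snp_gene_tad_colocalization(s, snp_genes[[rs]], genes,
                                tad_seg)$fraction
  }, numeric(1))
  # loop-contacted genes from the planted target fragments
  target_frags <- unique(loop_anchors$target_frag)
  fake_calls <- data.frame(
    target_frag = target_frags,
    chrom = frag$chrom[target_frags],
    start = frag$start[target_frags], end = frag$end[target_frags],
    distance = 0, observed = 1, expected = 1, pvalue = 0, padj = 0,
    significant = TRUE)
  loop_genes_expected <- loops_near_tss(fake_calls, genes,
                                        cfg$params$tss_max_dist)
  list(
    tad_boundaries = tad_boundaries,
    loop_anchors = loop_anchors,
    enhancer_snps = enh_truth$rsid,
    enhancer_counts = enh_truth,
    eqtl_pairs = truth_eqtl$pairs,
    snp_genes = snp_genes,
    deg_genes = deg_genes,
    brain_epigenomes = brain_ids,
    viewpoint = truth_eqtl$viewpoint,
    loop_genes = loop_genes_expected,
    peak_counts = peak_truth$truth,
    deg_overlap = deg_overlap,
    tad_frac = tad_frac,
    stage_counts = c(
      catalog_rows = nrow(snp_gen$catalog),
      retained = nrow(retained),
      noncoding = nrow(noncoding),
      enhancer = nrow(enh_truth),
      brain_enhancer = sum(enh_truth$brain_enhancer_count > 0),
      eqtl_snps = length(eqtl_snp_ids),
      eqtl_genes = length(unique(truth_eqtl$pairs$gene_id)),
      deg_overlap_snps = sum(deg_overlap),
      loop_genes = length(loop_genes_expected),
      tad_coloc_snps = sum(tad_frac > 0)))
}

truth_to_yaml <- function(truth) {
  list(
    tad_boundaries = truth$tad_boundaries,
    loop_anchors = as.list(truth$loop_anchors),
    enhancer_snps = truth$enhancer_snps,
    eqtl_pairs = as.list(truth$eqtl_pairs),
    deg_genes = truth$deg_genes,
    brain_epigenomes = truth$brain_epigenomes,
    viewpoint = truth$viewpoint,
    loop_genes = truth$loop_genes,
    stage_counts = as.list(truth$stage_counts))
}
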