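test_that("genome generator honors the pseudogene fraction, capacity
          and determinism contracts", {
  g <- gen_genome_annotation(n_chrom = 1, chrom_len = 10e6, n_genes = 50,
                             pseudogene_frac = 0.1, seed = 7)
  expect_equal(nrow(g$genes$genes), 50)
  expect_equal(sum(g$genes$genes$pseudogene), 5)
  # gene bodies do not overlap
  gb <- g$genes$genes[order(g$genes$genes$start), ]
  expect_true(all(gb$start[-1] >= gb$end[-nrow(gb)]))
  expect_error(gen_genome_annotation(n_genes = 0), "n_genes")
  expect_error(gen_genome_annotation(n_chrom = 1, chrom_len = 1e5,
                                     n_genes = 50, seed = 1),
               "capacity")
  g2 <- gen_genome_annotation(n_chrom = 1, chrom_len = 10e6,
                              n_genes = 50, pseudogene_frac = 0.1,
                              seed = 7)
  expect_identical(g$genes, g2$genes)
  expect_identical(as.character(g$fasta), as.character(g2$fasta))
})

test_that("SNP generator respects fractions, threshold straddling and
          identical-seed reproducibility", {
  g <- gen_genome_annotation(n_chrom = 2, chrom_len = 8e6, n_genes = 80,
                             pseudogene_frac = 0.1, seed = 2)
  snp <- gen_snp_catalog(g$genes, n_snps = 100, frac_noncoding = 0.9,
                         seed = 3)
  main <- snp$truth[seq_len(100), ]
  expect_equal(sum(main$class %in% c("intronic", "intergenic", "utr")),
               90)
  expect_true(any(main$pvalue < 1e-6) && any(main$pvalue >= 1e-6))
  expect_true(all(main$pvalue[main$planted_enhancer] < 1e-6))
  snp2 <- gen_snp_catalog(g$genes, n_snps = 100, frac_noncoding = 0.9,
                          seed = 3)
  expect_identical(snp$catalog, snp2$catalog)
  empty <- gen_snp_catalog(g$genes, n_snps = 0)
  expect_equal(nrow(empty$catalog), 0)
  expect_true(all(c("rsid", "pvalue") %in% names(empty$catalog)))
})

test_that("state generator keeps the partition property and exact
          planted counts in every epigenome", {
  g <- gen_genome_annotation(n_chrom = 2, chrom_len = 2e6, n_genes = 20,
                             pseudogene_frac = 0, seed = 5)
  snp <- gen_snp_catalog(g$genes, n_snps = 30, seed = 6)
  planted <- snp$truth[snp$truth$planted_enhancer,
                       c("rsid", "chrom", "pos")]
  clear <- snp$truth[!snp$truth$planted_enhancer, c("chrom", "pos")]
  states <- gen_chromatin_states(g$genes$chrom_lengths,
                                 n_epigenomes = 6,
                                 brain_ids = c("E001", "E002"),
                                 plant = planted, keep_clear = clear,
                                 seed = 8)
  for (seg in states$segmentations) {
    for (chrom in names(g$genes$chrom_lengths)) {
      iv <- seg[seg$chrom == chrom, ]
      expect_equal(iv$start[1], 0)
      expect_equal(iv$end[nrow(iv)],
                   unname(g$genes$chrom_lengths[[chrom]]))
      expect_true(all(iv$start[-1] == iv$end[-nrow(iv)]))
      expect_true(all(iv$label %in% STATE_MNEMONICS_25))
    }
  }
  expect_true(all(states$truth$enhancer_count >= 1))
  expect_true(all(states$truth$brain_enhancer_count <=
                    states$truth$enhancer_count))
  expect_error(gen_chromatin_states(g$genes$chrom_lengths,
                                    brain_ids = "E999"),
               "brain_ids")
  expect_error(gen_chromatin_states(g$genes$chrom_lengths,
                                    enhancer_states = "Enh99"),
               "unknown state")
})

test_that("expression generator plants detectable effects and validates
          the effect argument", {
  g <- gen_genome_annotation(n_chrom = 1, chrom_len = 3e6, n_genes = 30,
                             pseudogene_frac = 0.1, seed = 9)
  st <- gen_snp_catalog(g$genes, n_snps = 20, seed = 10)$truth
  pool <- g$genes$genes
  pairs <- data.frame(rsid = st$rsid[1],
                      gene_id = pool$gene_id[pool$chrom == st$chrom[1] &
                                               !pool$pseudogene][1])
  ds <- gen_expression_and_eqtl(g$genes, st, eqtl_pairs = pairs,
                                seed = 11)
  planted_p <- ds$eqtl$pvalue[paste(ds$eqtl$rsid, ds$eqtl$gene_id) %in%
                                paste(pairs$rsid, pairs$gene_id)]
  same_chrom_decoys <- ds$eqtl$pvalue[ds$eqtl$pvalue >= 0.05]
  expect_true(max(planted_p) < min(same_chrom_decoys))
  ds0 <- gen_expression_and_eqtl(g$genes, st, deg_effect = 0, seed = 11)
  expect_length(ds0$truth$deg_genes, 0)
  expect_error(gen_expression_and_eqtl(g$genes, st, deg_effect = NaN),
               "deg_effect")
  expect_error(gen_expression_and_eqtl(g$genes, st, n_case = 2),
               "3 samples")
  ds2 <- gen_expression_and_eqtl(g$genes, st, eqtl_pairs = pairs,
                                 seed = 11)
  expect_identical(ds$covariates, ds2$covariates)
  expect_identical(ds$expr, ds2$expr)
})

test_that("read-pair generator plants duplicates, self-ligations and a
          recoverable decay exponent", {
  frag <- regular_frag(L = 2e6, size = 4000)
  expect_warning(gen_hic_pairs(frag, NULL, 1e5, NULL, n_pairs = 100,
                               seed = 1),
                 "sparse")
  hic <- gen_hic_pairs(frag, NULL, 1e5, NULL, n_pairs = 10000,
                       dup_frac = 0.1, self_frac = 0.05, seed = 13)
  expect_equal(hic$truth$n_duplicates, 1000)
  expect_equal(hic$truth$n_self, 500)
  expect_equal(nrow(hic$pairs), 10000 + 1000 + 500)
  rec <- assign_pairs_to_fragments(hic$pairs, frag)
  filt <- filter_pairs(rec$records, remove_high_coverage = FALSE)
  # planted duplicates are removed modulo jitter collisions
  expect_gte(filt$qc[["duplicate"]], 1000)
  expect_lt(filt$qc[["duplicate"]], 1100)
  expect_gte(filt$qc[["same_fragment"]], 500)
  expect_error(gen_hic_pairs(frag, NULL, 1e5, NULL, n_pairs = 100,
                             decay_exponent = 1), "negative")
  expect_error(gen_hic_pairs(frag, NULL, 1e5, NULL, n_pairs = 100,
                             intra_tad_fold = 0.5), ">= 1")
})
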