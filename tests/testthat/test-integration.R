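test_that("peak overlap counts cell types per factor", {
  dir <- withr::local_tempdir()
  snps <- data.frame(rsid = c("rsA", "rsB"), chrom = "chr1",
                     pos = c(5000, 9000))
  paths <- vapply(1:3, function(ct) {
    p <- file.path(dir, sprintf("ctcf_%d.bed", ct))
    iv <- if (ct < 3) {
      data.frame(chrom = "chr1", start = 4800, end = 5200)
    } else {
      data.frame(chrom = "chr1", start = 100, end = 200)
    }
    write_bed(iv, p)
    p
  }, character(1))
  peaks <- data.frame(factor = "CTCF", cell_type = paste0("ct", 1:3),
                      path = paths)
  out <- ctcf_overlap(snps, peaks)
  expect_equal(out$CTCF_celltypes, c(2L, 0L))
})

test_that("TAD co-localization uses half-open blocks on bins", {
  genes <- enhloop:::new_gene_models(
    data.frame(gene_id = c("G1", "G2", "G3"),
               chrom = c("chr1", "chr1", "chr2"),
               start = c(1.70e6, 2.30e6, 1e5),
               end = c(1.75e6, 2.35e6, 2e5), strand = "+",
               tss = c(1.70e6, 2.30e6, 1e5),
               pseudogene = FALSE),
    data.frame(chrom = "chr1", start = 1.70e6, end = 1.75e6,
               gene_id = "G1", feature = "cds"),
    c(chr1 = 4e6, chr2 = 1e6))
  tads <- list(chr1 = structure(
    list(chrom = "chr1", bin_size = 1e5, boundaries = c(0, 10, 20, 40),
         K = 3), class = "tad_segmentation"))
  snp <- data.frame(rsid = "rsA", chrom = "chr1", pos = 1.25e6 + 1)
  res <- suppressMessages(snp_gene_tad_colocalization(
    snp, c("G1", "G2", "G3"), genes, tads))
  # SNP bin 12 and G1 TSS bin 17 share block [10,20); G2 bin 23 does
  # not; G3 is on another chromosome
  expect_equal(unname(res$flags), c(TRUE, FALSE, FALSE))
  expect_equal(res$fraction, 1 / 3)
  expect_false(res$over80)
})

test_that("loop-to-TSS proximity applies the distance cutoff", {
  genes <- enhloop:::new_gene_models(
    data.frame(gene_id = c("G1", "G2"), chrom = "chr1",
               start = c(50000, 90000), end = c(60000, 99000),
               strand = "+", tss = c(50000, 90000), pseudogene = FALSE),
    data.frame(chrom = "chr1", start = 50000, end = 60000,
               gene_id = "G1", feature = "cds"),
    c(chr1 = 2e5))
  calls <- data.frame(
    target_frag = 1:2, chrom = "chr1",
    start = c(44000, 80000), end = c(47000, 82000),
    distance = 0, observed = 10, expected = 1, pvalue = 1e-6,
    padj = 1e-5, significant = TRUE)
  # fragment ending 3 kb upstream of G1's TSS is within 5 kb; the one
  # 8 kb from G2's TSS is not
  expect_equal(loops_near_tss(calls, genes), "G1")
  calls$significant <- FALSE
  expect_equal(loops_near_tss(calls, genes), character(0))
})

test_that("report percentages recompute from their own counts", {
  summary <- data.frame(
    n_retained = 19, n_noncoding = 19, pct_noncoding = 100,
    n_enhancer = 10, pct_enhancer = 100 * 10 / 19,
    n_brain_enhancer = 4, pct_brain_enhancer = 100 * 4 / 19,
    n_eqtl_snps = 19, n_eqtl_genes = 40,
    n_deg_overlap = 15, pct_deg_overlap = 100 * 15 / 19,
    n_tad_coloc = 18, pct_tad_coloc = 100 * 18 / 19,
    n_loop_genes = 15)
  lines <- write_report(list(summary = summary))
  # 18 of 19 TAD co-localized prints as 94.7% at one decimal place
  expect_true(any(grepl("18 \\(94.7%\\)", lines)))
  expect_true(any(grepl("15 \\(78.9%\\)", lines)))
  # empty cascade yields an all-zero report without errors
  zero <- summary
  zero[1, ] <- 0
  expect_no_error(write_report(list(summary = zero)))
})
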