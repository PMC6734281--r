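write_catalog <- function(rows, path) {
  header <- "rsid\tchrom\tpos\ttrait\tpvalue\tconsequence\tmapped_gene"
  writeLines(c(header, rows), path)
  path
}

test_that("catalog filter applies trait, strict threshold and the
          confirmed include-list", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(c(
    "rs1\tchr1\t15000\tAlzheimer's disease\t5e-7\tintron_variant\tG1",
    "rs2\tchr1\t30000\tAlzheimer's disease\t1e-6\tintron_variant\tG1",
    "rs3\tchr1\t40000\tAlzheimer's disease\t1e-3\tintron_variant\tG1",
    "rs4\tchr1\t50000\tType 2 diabetes\t1e-9\tintron_variant\tG1"),
    path)
  snps <- load_snp_catalog(path, trait_pattern = "Alzheimer")
  expect_equal(snps$rsid, "rs1")          # 1e-6 exactly is excluded
  snps2 <- load_snp_catalog(path, trait_pattern = "Alzheimer",
                            include_list = "rs3")
  expect_setequal(snps2$rsid, c("rs1", "rs3"))
  # filter idempotence: the retained table passes its own filter
  again <- snps2[grepl("Alzheimer", snps2$trait) &
                   snps2$pvalue < 1e-6 | snps2$rsid %in% "rs3", ]
  expect_equal(again$rsid, snps2$rsid)
})

test_that("malformed rows, missing ids and duplicates are handled", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(c(
    "rs1\tchr1\t15000\tAlzheimer's disease\t5e-7\tintron_variant\tG1",
    "rs1\tchr1\t15000\tAlzheimer's disease\t5e-9\tintron_variant\tG1",
    "rsX\tchr1\t16000\tAlzheimer's disease\tnot_a_p\tintron_variant\tG1",
    "\tchr1\t17000\tAlzheimer's disease\t5e-8\tintron_variant\tG1"),
    path)
  expect_warning(snps <- load_snp_catalog(path), "malformed")
  expect_equal(nrow(snps), 2)
  expect_equal(snps$pvalue[snps$rsid == "rs1"], 5e-9)  # min-p collapse
  novel <- snps[startsWith(snps$rsid, "novel_"), ]
  expect_equal(nrow(novel), 1)
  expect_true(novel$curated)
  # missing required column is a hard error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchrom\tpos", "rs1\tchr1\t100"), bad)
  expect_error(load_snp_catalog(bad), "missing required column")
})

test_that("region classification honors consequence labels and feature
          precedence", {
  genes <- tiny_genes()
  snps <- data.frame(
    rsid = paste0("rs", 1:6), chrom = c(rep("chr1", 5), "chr9"),
    pos = c(15000,   # intron of G1
            40000,   # intergenic
            12000,   # cds of G1
            10500,   # utr of G1
            15500,   # intron, but labeled missense -> honored
            100),
    consequence = c("intron_variant", "intergenic_variant", "", "",
                    "missense_variant", ""))
  expect_warning(out <- classify_snp_region(snps, genes),
                 "absent from gene models")
  expect_equal(out$region_class,
               c("intronic", "intergenic", "other-coding", "utr",
                 "missense", "intergenic"))
  expect_equal(out$noncoding, c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE))
  # partition: exactly one class each, class counts sum to the total
  expect_false(anyNA(out$region_class))
  expect_equal(sum(table(out$region_class)), nrow(out))
})

test_that("gene models round-trip through GFF3", {
  genes <- tiny_genes()
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff(genes, path)
  back <- read_gene_models_gff(path)
  expect_equal(back$genes, genes$genes)
  expect_equal(back$chrom_lengths, genes$chrom_lengths)
  expect_equal(
    back$features[order(back$features$start, back$features$feature), ],
    genes$features[order(genes$features$start,
                         genes$features$feature), ],
    ignore_attr = TRUE)
})
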