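make_seg <- function(labels, breaks = NULL, L = 10000,
                     id = "E001", brain = FALSE) {
  if (is.null(breaks)) breaks <- seq(0, L, length.out = length(labels) + 1)
  structure(list(
    epigenome_id = id,
    intervals = data.frame(chrom = "chr1", start = breaks[-length(breaks)],
                           end = breaks[-1], label = labels),
    is_brain = brain), class = "state_segmentation")
}

test_that("segmentation loading validates vocabulary and partition", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = "chr1", start = c(0, 5000),
                       end = c(5000, 10000),
                       label = c("TssA", "EnhA1")), path)
  seg <- load_state_segmentation(path, "E003", brain_ids = c("E003"))
  expect_true(seg$is_brain)
  expect_equal(nrow(seg$intervals), 2)

  write_bed(data.frame(chrom = "chr1", start = 0, end = 100,
                       label = "Enh99"), path)
  expect_error(load_state_segmentation(path, "E001"), "Enh99")

  write_bed(data.frame(chrom = "chr1", start = c(0, 6000),
                       end = c(5000, 10000),
                       label = c("TssA", "Quies")), path)
  expect_error(load_state_segmentation(path, "E001"), "gap or overlap")
})

test_that("enhancer counts follow the state set and the half-open
          boundary rule", {
  snps <- data.frame(rsid = c("rsA", "rsB"), chrom = "chr1",
                     pos = c(2500, 5001))
  # rsB at pos 5001 = 0-based 5000, exactly on the segment boundary:
  # belongs to the second segment
  segs <- c(
    lapply(1:3, function(i) make_seg(c("EnhA1", "TssA"),
                                     id = sprintf("E%03d", i),
                                     brain = i == 1)),
    lapply(4:5, function(i) make_seg(c("Quies", "EnhW2"),
                                     id = sprintf("E%03d", i))))
  ann <- annotate_snp_enhancers(snps, segs)
  expect_equal(ann$enhancer_count, c(3, 2))
  expect_equal(ann$brain_enhancer_count, c(1, 0))

  # a SNP in TssA in every epigenome is not an enhancer SNP
  tss_only <- lapply(1:4, function(i)
    make_seg(c("TssA", "TssA"), id = sprintf("E%03d", i)))
  ann2 <- annotate_snp_enhancers(snps, tss_only)
  expect_equal(ann2$enhancer_count, c(0, 0))

  # enlarging the enhancer-state set never decreases counts
  ann3 <- annotate_snp_enhancers(snps, segs,
                                 enhancer_states = c("EnhA1", "EnhW2",
                                                     "TssA"))
  expect_true(all(ann3$enhancer_count >= ann$enhancer_count))

  # restricting to the brain subset makes total equal brain count
  brain_only <- Filter(function(s) s$is_brain, segs)
  ann4 <- annotate_snp_enhancers(snps, brain_only)
  expect_equal(ann4$enhancer_count, ann4$brain_enhancer_count)

  expect_error(annotate_snp_enhancers(snps, segs,
                                      enhancer_states = "Enh99"),
               "vocabulary")
})

test_that("the tissue summary partitions non-coding SNPs with exact
          percentages", {
  ann <- data.frame(rsid = paste0("rs", 1:10),
                    enhancer_count = c(3, 1, 0, 0, 2, 0, 0, 1, 0, 0),
                    brain_enhancer_count = c(1, 0, 0, 0, 2, 0, 0, 0, 0, 0))
  ann$in_enhancer <- ann$enhancer_count > 0
  ann$in_brain_enhancer <- ann$brain_enhancer_count > 0
  s <- summarize_enhancer_tissues(ann)
  expect_equal(s$n_enhancer, 4)
  expect_equal(s$n_brain_enhancer, 2)
  expect_equal(s$n_brain_enhancer + s$n_nonbrain_enhancer, s$n_enhancer)
  expect_equal(s$n_enhancer + s$n_non_enhancer, s$n_noncoding)
  expect_equal(s$pct_enhancer, 40)
  empty <- summarize_enhancer_tissues(ann[0, ])
  expect_equal(empty$pct_enhancer, 0)
})
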