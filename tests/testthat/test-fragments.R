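test_that("HindIII digestion cuts one base into the motif", {
  s <- paste(rep("C", 1000), collapse = "")
  substr(s, 501, 506) <- "AAGCTT"   # motif 0-based start 500
  fa <- Biostrings::DNAStringSet(s)
  names(fa) <- "chr1"
  fm <- digest_fragments(fasta = fa)
  expect_equal(fm$start, c(0, 501))
  expect_equal(fm$end, c(501, 1000))
  # no motif: one whole-chromosome fragment with a warning
  fa2 <- Biostrings::DNAStringSet(paste(rep("C", 800), collapse = ""))
  names(fa2) <- "chr1"
  expect_warning(fm2 <- digest_fragments(fasta = fa2), "no cut site")
  expect_equal(nrow(fm2), 1)
})

test_that("FASTA digestion equals the cut-site BED path", {
  set.seed(21)
  s <- paste(sample(c("A", "C", "G", "T"), 50000, replace = TRUE),
             collapse = "")
  fa <- Biostrings::DNAStringSet(s)
  names(fa) <- "chr1"
  fm_fa <- digest_fragments(fasta = fa)
  cuts <- fm_fa$end[-nrow(fm_fa)]
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(data.frame(chrom = "chr1", start = cuts, end = cuts + 1),
            bed)
  fm_bed <- digest_fragments(sites_bed = bed,
                             chrom_lengths = c(chr1 = 50000))
  expect_equal(as.data.frame(fm_fa), as.data.frame(fm_bed))
})

test_that("pair assignment maps ends to containing fragments with
          canonical ordering and conservation", {
  frag <- regular_frag(L = 20000, size = 5000)   # fragments of 5 kb
  pairs <- data.frame(
    read_id = c("r1", "r2", "r3"),
    chrom1 = c("chr1", "chr1", "chrUn"),
    pos1 = c(600, 17000, 5),
    chrom2 = "chr1", pos2 = c(12000, 2000, 10),
    strand1 = "+", strand2 = "-")
  res <- assign_pairs_to_fragments(pairs, frag)
  expect_equal(unname(res$qc),
               c(3, 1, 2))                      # input, unknown, kept
  # r1: 600 -> [0,5000); 12000 -> [10000,15000)
  expect_equal(res$records$frag1[1], 1)
  expect_equal(res$records$frag2[1], 3)
  # r2 arrives reversed and is canonicalized (frag1 <= frag2)
  expect_equal(res$records$frag1[2], 1)
  expect_equal(res$records$frag2[2], 4)
  expect_equal(res$records$strand1[2], "-")
})

test_that("pair filters remove duplicates, self-ligations and hot
          fragments, conserving counts", {
  rec <- data.frame(
    frag1 = c(1, 1, 2, 5, rep(7, 50), 1:40),
    frag2 = c(3, 3, 2, 5, rep(7 + (1:50) %% 9 + 1, 1), 60:99),
    chrom1 = "chr1", chrom2 = "chr1",
    pos1 = 1, pos2 = 2, strand1 = "+", strand2 = "-")
  rec$pos1 <- seq_len(nrow(rec)); rec$pos1[2] <- rec$pos1[1]
  res <- filter_pairs(rec, coverage_quantile = 0.95)
  qc <- res$qc
  expect_equal(unname(qc["input"]),
               unname(qc["kept"] + qc["duplicate"] + qc["same_fragment"] +
                        qc["high_coverage"]))
  expect_equal(unname(qc["duplicate"]), 1)
  expect_equal(unname(qc["same_fragment"]), 2)
  expect_gt(qc[["high_coverage"]], 0)   # fragment 7 is hot
  expect_false(any(res$records$frag1 == 7 | res$records$frag2 == 7))
  # switches
  res2 <- filter_pairs(rec, remove_duplicates = FALSE,
                       remove_same_fragment = FALSE,
                       remove_high_coverage = FALSE)
  expect_equal(nrow(res2$records), nrow(rec))
})

test_that("binning is invariant to record order after filtering", {
  frag <- regular_frag(L = 1e6, size = 4000)
  hic <- gen_hic_pairs(frag, NULL, 1e5, NULL, n_pairs = 5000,
                       seed = 3, dup_frac = 0.1, self_frac = 0.05)
  rec <- assign_pairs_to_fragments(hic$pairs, frag)$records
  a <- filter_pairs(rec)$records
  b <- filter_pairs(rec[sample.int(nrow(rec)), ])$records
  ma <- bin_contacts(a, frag, 1e5)[["chr1"]]$counts
  mb <- bin_contacts(b, frag, 1e5)[["chr1"]]$counts
  expect_equal(ma, mb)
})
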