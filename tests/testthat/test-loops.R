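test_that("the decay model recovers a planted power-law exponent", {
  frag <- regular_frag(L = 2e6, size = 4000)
  hic <- gen_hic_pairs(frag, NULL, 1e5, NULL, n_pairs = 40000,
                       decay_exponent = -1, dup_frac = 0, self_frac = 0,
                       seed = 61)
  rec <- assign_pairs_to_fragments(hic$pairs, frag)$records
  model <- fit_distance_decay(rec, frag)
  expect_lt(abs(decay_exponent(model) - (-1)), 0.1)
  ok <- !is.na(model$expected) & model$n_pairs > 0
  expect_true(all(model$expected[ok] >= 0))
  # isotonic contract: expectations never increase with distance
  expect_true(all(diff(model$expected[ok]) <= 1e-12))
})

test_that("viewpoint selection follows the flanking-site rule", {
  frag <- regular_frag(L = 40000, size = 10000)  # cuts at 10k,20k,30k
  # SNP inside fragment 2 ([10000,20000)): three fragments share its
  # flanking cut sites
  expect_equal(select_viewpoint(
    data.frame(chrom = "chr1", pos = 15000), frag), c(1, 2, 3))
  # SNP exactly on the cut at 20000 (0-based 20000 -> pos 20001):
  # the two fragments meeting there
  expect_equal(select_viewpoint(
    data.frame(chrom = "chr1", pos = 20001), frag), c(2, 3))
  # chromosome-terminal SNP
  expect_equal(select_viewpoint(
    data.frame(chrom = "chr1", pos = 500), frag), c(1, 2))
  expect_error(select_viewpoint(
    data.frame(chrom = "chr9", pos = 500), frag), "not in fragment map")
})

test_that("a strongly planted loop is called significant with the right
          extent", {
  rep10 <- vp_replicate(seed = 71, fold = 10)
  sig <- rep10$calls[rep10$calls$significant, ]
  expect_true(rep10$target %in% sig$target_frag)
  ext <- loops_extent(rep10$calls)
  expect_true(ext["max"] >= 3.4e5 && ext["max"] <= 3.6e5)
})

test_that("windowed observed counts equal the rolling sum exactly", {
  frag <- regular_frag(L = 100000, size = 10000)
  vp <- 5L
  rec <- data.frame(frag1 = vp, frag2 = c(1, 2, 2, 8, 9, 9, 9),
                    chrom1 = "chr1", chrom2 = "chr1", pos1 = 1, pos2 = 1,
                    strand1 = "+", strand2 = "+")
  decay <- structure(list(edges = c(1, 1e6), mid = 1e3,
                          expected = 0.5, n_pairs = 10L),
                     class = "decay_model")
  c1 <- call_viewpoint_interactions(vp, rec, frag, decay = decay,
                                    window = 1)
  c3 <- call_viewpoint_interactions(vp, rec, frag, decay = decay,
                                    window = 3)
  ord <- order(c1$start)
  obs1 <- c1$observed[ord]
  n <- length(obs1)
  roll <- vapply(seq_len(n), function(i)
    sum(obs1[max(1, i - 1):min(n, i + 1)]), numeric(1))
  expect_equal(c3$observed[order(c3$start)], roll)
})

test_that("empty and degenerate loop-calling inputs behave", {
  frag <- regular_frag(L = 100000, size = 10000)
  rec0 <- data.frame(frag1 = integer(), frag2 = integer(),
                     chrom1 = character(), chrom2 = character(),
                     pos1 = numeric(), pos2 = numeric(),
                     strand1 = character(), strand2 = character())
  expect_warning(calls <- call_viewpoint_interactions(5L, rec0, frag),
                 "no contacts")
  expect_equal(nrow(calls), 0)
  expect_length(loops_extent(calls), 0)
  # extent is invariant to call ordering
  calls2 <- data.frame(target_frag = 1:3, chrom = "chr1",
                       start = c(0, 1, 2) * 1e4, end = c(1, 2, 3) * 1e4,
                       distance = c(-2e4, 1e4, 3e4), observed = 1,
                       expected = 1, pvalue = 0.01, padj = 0.01,
                       significant = c(TRUE, FALSE, TRUE))
  expect_equal(loops_extent(calls2), loops_extent(calls2[3:1, ]))
  expect_equal(unname(loops_extent(calls2)), c(-2e4, 3e4))
})
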