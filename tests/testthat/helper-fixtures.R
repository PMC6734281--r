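# shared in-code fixtures; everything is generated at test time

# a minimal two-gene model set on one 100-kb chromosome, built by hand so
# feature coordinates are known exactly
tiny_genes <- function() {
  genes <- data.frame(
    gene_id = c("G1", "G2"),
    chrom = "chr1",
    start = c(10000, 60000), end = c(20000, 70000),
    strand = c("+", "-"),
    tss = c(10000, 69999),
    pseudogene = c(FALSE, FALSE))
  features <- data.frame(
    chrom = "chr1",
    start = c(10000, 11000, 14000, 16000, 19000, 60000, 64000, 66000),
    end   = c(11000, 14000, 16000, 19000, 20000, 64000, 66000, 70000),
    gene_id = c("G1", "G1", "G1", "G1", "G1", "G2", "G2", "G2"),
    feature = c("utr", "cds", "intron", "cds", "utr",
                "cds", "intron", "cds"))
  enhloop:::new_gene_models(genes, features, c(chr1 = 1e5))
}

# fragment map with regular 4-kb fragments on one chromosome
regular_frag <- function(L = 4e6, size = 4000) {
  cuts <- seq(size, L - 1, by = size)
  fm <- data.frame(chrom = "chr1", start = c(0, cuts), end = c(cuts, L),
                   frag_id = seq_len(length(cuts) + 1))
  attr(fm, "chrom_lengths") <- c(chr1 = L)
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

# block-constant contact matrix with distance decay and Poisson noise
sim_tad_matrix <- function(n_tads = 20, fold = 3, seed = 1, base = 20,
                           decay = -0.8, wrange = 10:30) {
  set.seed(seed)
  w <- sample(wrange, n_tads, replace = TRUE)
  b <- c(0, cumsum(w))
  n <- b[length(b)]
  block <- findInterval(0:(n - 1), b[-length(b)])
  d <- abs(outer(1:n, 1:n, "-"))
  mu <- base * (d + 1)^decay * ifelse(outer(block, block, "=="), fold, 1)
  x <- matrix(stats::rpois(n * n, mu), n)
  x[lower.tri(x)] <- t(x)[lower.tri(x)]
  list(m = x, boundaries = b, n = n)
}

# fraction of true interior boundaries recovered within +/- tol bins
boundary_recall <- function(est, truth, tol = 1) {
  inner_t <- setdiff(truth, range(truth))
  inner_e <- setdiff(est, c(0, max(truth)))
  if (!length(inner_t)) return(NA_real_)
  mean(vapply(inner_t, function(t) any(abs(inner_e - t) <= tol),
              logical(1)))
}

# exhaustive segmentation search for the DP oracle
brute_force_segment <- function(x, K, mu0) {
  n <- nrow(x)
  best <- Inf
  combs <- utils::combn(n - 1, K - 1)
  for (c in seq_len(ncol(combs))) {
    b <- c(0, combs[, c], n)
    cost <- sum((x - mu0)^2)
    for (k in seq_len(K)) {
      blk <- x[(b[k] + 1):b[k + 1], (b[k] + 1):b[k + 1], drop = FALSE]
      cost <- cost - length(blk) * (mean(blk) - mu0)^2
    }
    if (cost < best) best <- cost
  }
  best
}

# exact upper-tail hypergeometric p by enumerating all C(N, n) draws
enumerate_hyper_p <- function(x, m, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= m)   # items 1..m are the "DEG" set
  mean(hits >= x)
}

# one simulated 4C-style replicate: decay library with optional planted
# loop at ~350 kb from the viewpoint, capture-enriched at the viewpoint
vp_replicate <- function(seed, fold = 1, n_pairs = 60000) {
  frag <- regular_frag()
  snp <- data.frame(rsid = "rsV", chrom = "chr1", pos = 2e6)
  vp <- select_viewpoint(snp, frag)
  target <- frag$frag_id[findInterval(2.35e6, frag$start)]
  anchors <- if (fold > 1) {
    data.frame(viewpoint_frag = vp, target_frag = target, fold = fold)
  } else NULL
  hic <- gen_hic_pairs(frag, tad_boundaries = NULL, bin_size = 1e5,
                       loop_anchors = anchors, n_pairs = n_pairs,
                       decay_exponent = -1, intra_tad_fold = 1,
                       dup_frac = 0, self_frac = 0,
                       enriched_frags = vp, viewpoint_enrichment = 40,
                       seed = seed)
  rec <- assign_pairs_to_fragments(hic$pairs, frag)$records
  calls <- suppressWarnings(call_viewpoint_interactions(vp, rec, frag))
  list(calls = calls, target = target, frag = frag, vp = vp)
}

SCENARIO_SEED <- 20240901
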