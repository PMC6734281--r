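test_that("eQTL filtering drops cross-chromosome pairs and pseudogenes
          and unions genes per SNP", {
  genes <- enhloop:::new_gene_models(
    data.frame(gene_id = c("G1", "G2", "P1"),
               chrom = c("chr1", "chr2", "chr1"),
               start = c(0, 0, 5000), end = c(1000, 1000, 6000),
               strand = "+", tss = c(0, 0, 5000),
               pseudogene = c(FALSE, FALSE, TRUE)),
    data.frame(chrom = "chr1", start = 0, end = 1000, gene_id = "G1",
               feature = "cds"),
    c(chr1 = 1e4, chr2 = 1e4))
  snps <- data.frame(rsid = c("rsA", "rsB"), chrom = c("chr1", "chr2"),
                     pos = c(100, 100))
  eqtl <- data.frame(
    rsid   = c("rsA", "rsA", "rsA", "rsA", "rsB", "rsZ"),
    gene_id = c("G1", "G1", "G2", "P1", "G2", "G1"),
    tissue = c("t1", "t2", "t1", "t1", "t1", "t1"),
    pvalue = c(1e-9, 1e-8, 1e-9, 1e-9, 1e-8, 1e-9))
  expect_warning(res <- filter_eqtl_associations(eqtl, snps, genes),
                 "unknown")
  # rsA-G2 is cross-chromosome, rsA-P1 a pseudogene, rsZ unknown
  expect_setequal(res$associations$gene_id[res$associations$rsid == "rsA"],
                  "G1")
  expect_equal(res$snp_genes, list(rsA = "G1", rsB = "G2"))
  expect_true(all(res$associations$qvalue < 0.05))
  expect_equal(unname(res$dropped["cross_chrom"]), 1)
  expect_equal(unname(res$dropped["pseudogene"]), 1)
})

test_that("planted associations survive q-value control among clear
          decoys", {
  genes <- gen_genome_annotation(n_chrom = 2, chrom_len = 2e6,
                                 n_genes = 30, pseudogene_frac = 0.1,
                                 seed = 2)$genes
  snp <- gen_snp_catalog(genes, n_snps = 30, seed = 4)
  st <- snp$truth
  enh <- st[st$planted_enhancer, ][1:3, ]
  pairs <- do.call(rbind, lapply(seq_len(nrow(enh)), function(i) {
    pool <- genes$genes$gene_id[genes$genes$chrom == enh$chrom[i] &
                                  !genes$genes$pseudogene]
    data.frame(rsid = enh$rsid[i], gene_id = pool[seq_len(2)])
  }))
  ds <- gen_expression_and_eqtl(genes, st, eqtl_pairs = pairs, seed = 6)
  res <- filter_eqtl_associations(ds$eqtl, st, genes)
  expected <- lapply(split(pairs$gene_id, pairs$rsid), function(g)
    sort(unique(g)))
  expect_equal(res$snp_genes[order(names(res$snp_genes))],
               expected[order(names(expected))])
})

test_that("BH rejection equals the classical step-up rule", {
  set.seed(31)
  p <- c(stats::runif(80), stats::rbeta(20, 0.1, 10))
  alpha <- 0.05
  rej_bh <- stats::p.adjust(p, "BH") < alpha
  # direct step-up: largest k with p_(k) <= alpha k / m
  m <- length(p)
  ord <- order(p)
  k <- max(c(0, which(p[ord] <= alpha * seq_len(m) / m)))
  rej_direct <- logical(m)
  if (k > 0) rej_direct[ord[seq_len(k)]] <- TRUE
  expect_equal(rej_bh, rej_direct)
})

test_that("a 2-SD planted shift at n = 20 + 20 is detected under all
          three DEG models", {
  genes <- gen_genome_annotation(n_chrom = 1, chrom_len = 4e6,
                                 n_genes = 60, pseudogene_frac = 0,
                                 seed = 8)$genes
  ds <- gen_expression_and_eqtl(genes, snps = data.frame(
    rsid = character(), chrom = character(), pos = integer()),
    n_case = 20, n_control = 20, deg_effect = 2, seed = 9)
  planted <- ds$truth$deg_genes
  expect_gt(length(planted), 3)
  for (m in c("linear_covariates", "ttest", "logistic_covariates")) {
    deg <- call_degs(ds$expr, ds$labels, ds$covariates, model = m,
                     case_level = "AD")
    expect_true(all(planted %in% deg$gene_id[deg$is_deg]),
                label = paste("model", m))
    expect_true(all(deg$effect_direction[deg$gene_id %in% planted] == 1),
                label = paste("direction", m))
  }
})

test_that("a zero effect plants nothing and false positives stay at the
          FDR level", {
  genes <- gen_genome_annotation(n_chrom = 1, chrom_len = 4e6,
                                 n_genes = 60, pseudogene_frac = 0,
                                 seed = 10)$genes
  ds <- gen_expression_and_eqtl(genes, snps = data.frame(
    rsid = character(), chrom = character(), pos = integer()),
    deg_effect = 0, seed = 11)
  expect_length(ds$truth$deg_genes, 0)
  deg <- call_degs(ds$expr, ds$labels, ds$covariates,
                   model = "linear_covariates", case_level = "AD")
  # under the global null BH controls FWER at alpha; allow slack
  expect_lt(mean(deg$is_deg), 0.1)
})

test_that("label permutation gives a null DEG count distribution", {
  genes <- gen_genome_annotation(n_chrom = 1, chrom_len = 4e6,
                                 n_genes = 40, pseudogene_frac = 0,
                                 seed = 12)$genes
  ds <- gen_expression_and_eqtl(genes, snps = data.frame(
    rsid = character(), chrom = character(), pos = integer()),
    deg_effect = 2, seed = 13)
  set.seed(14)
  counts <- vapply(1:25, function(i) {
    perm <- sample(ds$labels)
    deg <- call_degs(ds$expr, perm, model = "ttest", case_level = "AD")
    sum(deg$is_deg)
  }, numeric(1))
  # permuting labels destroys the planted signal almost always
  expect_lt(mean(counts), 1.5)
})

test_that("degenerate DEG inputs are rejected or flagged", {
  expr <- matrix(stats::rnorm(200), 10,
                 dimnames = list(paste0("G", 1:10), NULL))
  labels <- rep(c("control", "AD"), each = 10)
  covs <- data.frame(age = stats::rnorm(20), twice_age = NA)
  covs$twice_age <- covs$age * 2
  expect_error(call_degs(expr, labels, covs, model = "linear_covariates",
                         case_level = "AD"),
               "collinear")
  expr[1, ] <- 5
  expect_warning(deg <- call_degs(expr, labels, model = "ttest",
                                  case_level = "AD"),
                 "constant")
  expect_equal(deg$pvalue[1], 1)
  expect_error(call_degs(expr, labels[c(1:3, 11:12)], model = "ttest"),
               "mismatch")
  expect_error(call_degs(expr[, 1:6], rep(c("a", "b"), c(2, 4)),
                         model = "ttest"), "3 samples")
})
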