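#' Generate a case/control expression matrix, covariates and an eQTL
#' table with planted effects
#'
#' Expression is baseline plus covariate effects plus a standardized
#' case shift for planted DEGs plus unit-variance Gaussian noise (a
#' log-scale-like matrix). The eQTL table contains the planted SNP-gene
#' pairs with very small p-values, decoy pairs with p-values uniform on
#' \[0.1, 1\] (clear of the significance region so planted truth is
#' identifiable), cross-chromosome decoys with small p-values (to
#' exercise the same-chromosome rule) and pseudogene decoys with small
#' p-values (to exercise the pseudogene filter).
#'
#' @param genes a `gene_models` object
#' @param snps SNP table (rsid, chrom, pos) the eQTL rows refer to
#' @param n_case,n_control group sizes (>= 3 each)
#' @param deg_effect standardized expression shift in cases for planted
#'   DEGs (0 plants none; negative allowed; NaN rejected)
#' @param eqtl_pairs `data.frame` rsid, gene_id of planted associations
#' @param seed generator stream seed
#' @param deg_genes planted DEG gene ids; when NULL, `deg_frac` of
#'   non-pseudogenes are sampled
#' @param deg_frac fraction of genes planted as DEGs when `deg_genes`
#'   is NULL
#' @param n_decoy decoy association count
#' @param tissues tissue labels cycled over eQTL rows
#' @param dataset dataset id stamped on outputs
#' @param exclude_genes gene ids absent from this expression platform
#'   (they still appear in the eQTL table, emulating platform coverage
#'   gaps)
#' @return list(expr, labels, covariates, eqtl, truth)
#' @export
gen_expression_and_eqtl <- function(genes, snps, n_case = 20,
                                    n_control = 20, deg_effect = 2,
                                    eqtl_pairs = NULL, seed = 1,
                                    deg_genes = NULL, deg_frac = 0.15,
                                    n_decoy = 120, exclude_genes = NULL,
                                    tissues = c("Brain_Hippocampus",
                                                "Brain_Cortex",
                                                "Adipose_Subcutaneous"),
                                    dataset = "ds1") {
  if (n_case < 3 || n_control < 3) stop("need >= 3 samples per group")
  if (is.nan(deg_effect) || is.na(deg_effect)) {
    stop("deg_effect must be a number")
  }
  g <- genes$genes
  if (!is.null(exclude_genes)) {
    g <- g[!g$gene_id %in% exclude_genes, , drop = FALSE]
  }
  with_seed(seed, {
    if (is.null(deg_genes)) {
      pool <- g$gene_id[!g$pseudogene]
      deg_genes <- sort(sample(pool, round(deg_frac * length(pool))))
    }
    if (deg_effect == 0) deg_genes <- character(0)
    n <- n_case + n_control
    labels <- factor(rep(c("control", "AD"), c(n_control, n_case)),
                     levels = c("control", "AD"))
    covariates <- data.frame(
      age = round(stats::rnorm(n, 75, 8), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      batch = factor(sample(c("b1", "b2"), n, replace = TRUE)))
    G <- nrow(g)
    baseline <- stats::rnorm(G, 7, 1)
    beta_age <- stats::rnorm(G, 0, 0.02)
    beta_sex <- stats::rnorm(G, 0, 0.3)
    beta_batch <- stats::rnorm(G, 0, 0.3)
    expr <- baseline +
      outer(beta_age, covariates$age - 75) +
      outer(beta_sex, as.numeric(covariates$sex == "M")) +
      outer(beta_batch, as.numeric(covariates$batch == "b2")) +
      matrix(stats::rnorm(G * n), G, n)
    is_deg <- g$gene_id %in% deg_genes
    expr[is_deg, labels == "AD"] <- expr[is_deg, labels == "AD"] +
      deg_effect
    rownames(expr) <- g$gene_id
    colnames(expr) <- sprintf("%s_S%03d", dataset, seq_len(n))

    eqtl <- gen_eqtl_table(g, snps, eqtl_pairs, n_decoy, tissues)
    truth <- list(deg_genes = deg_genes,
                  eqtl_pairs = if (is.null(eqtl_pairs))
                    data.frame(rsid = character(), gene_id = character())
                  else eqtl_pairs)
    list(expr = expr, labels = labels, covariates = covariates,
         eqtl = eqtl, truth = truth)
  })
}

gen_eqtl_table <- function(g, snps, eqtl_pairs, n_decoy, tissues) {
  rows <- list()
  if (nrow(snps) == 0) {
    return(data.frame(rsid = character(), gene_id = character(),
                      tissue = character(), pvalue = numeric()))
  }
  if (!is.null(eqtl_pairs) && nrow(eqtl_pairs)) {
    n_t <- sample(c(1, 2), nrow(eqtl_pairs), replace = TRUE)
    rows$planted <- do.call(rbind, lapply(seq_len(nrow(eqtl_pairs)),
      function(i) data.frame(
        rsid = eqtl_pairs$rsid[i], gene_id = eqtl_pairs$gene_id[i],
        tissue = sample(tissues, n_t[i]),
        pvalue = 10^stats::runif(n_t[i], -12, -9))))
  }
  snp_chrom <- stats::setNames(snps$chrom, snps$rsid)
  same_chrom_gene <- function(rsid, want_same, pseudo = FALSE) {
    ok <- (g$chrom == snp_chrom[[rsid]]) == want_same &
      g$pseudogene == pseudo
    if (!any(ok)) NA_character_ else sample(g$gene_id[ok], 1)
  }
  decoy_rsids <- sample(snps$rsid, n_decoy, replace = TRUE)
  rows$decoy <- data.frame(
    rsid = decoy_rsids,
    gene_id = vapply(decoy_rsids, same_chrom_gene, "", want_same = TRUE),
    tissue = sample(tissues, n_decoy, replace = TRUE),
    pvalue = stats::runif(n_decoy, 0.1, 1))
  n_cross <- max(2, round(n_decoy / 10))
  cross_rsids <- sample(snps$rsid, n_cross, replace = TRUE)
  cross_genes <- vapply(cross_rsids, same_chrom_gene, "",
                        want_same = FALSE)
  rows$cross <- data.frame(
    rsid = cross_rsids, gene_id = cross_genes,
    tissue = sample(tissues, n_cross, replace = TRUE),
    pvalue = 10^stats::runif(n_cross, -10, -8))
  if (any(g$pseudogene)) {
    n_ps <- max(2, round(n_decoy / 10))
    ps_rsids <- sample(snps$rsid, n_ps, replace = TRUE)
    rows$pseudo <- data.frame(
      rsid = ps_rsids,
      gene_id = vapply(ps_rsids, same_chrom_gene, "", want_same = TRUE,
                       pseudo = TRUE),
      tissue = sample(tissues, n_ps, replace = TRUE),
      pvalue = 10^stats::runif(n_ps, -10, -8))
  }
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write an expression dataset (matrix, sample metadata) as TSVs
#' @param ds output of [gen_expression_and_eqtl()]
#' @param dir output directory
#' @param dataset dataset id used in file names
#' @return named list of written paths
#' @export
write_expression_dataset <- function(ds, dir, dataset) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr_path <- file.path(dir, paste0(dataset, "_expr.tsv"))
  meta_path <- file.path(dir, paste0(dataset, "_samples.tsv"))
  expr_df <- data.frame(gene_id = rownames(ds$expr), ds$expr,
                        check.names = FALSE)
  write_tsv(expr_df, expr_path)
  meta <- data.frame(sample_id = colnames(ds$expr),
                     diagnosis = as.character(ds$labels),
                     ds$covariates)
  write_tsv(meta, meta_path)
  list(expr = expr_path, samples = meta_path)
}
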