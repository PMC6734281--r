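#' Hypergeometric over-representation test with fold enrichment ratio
#'
#' Tests whether an overlap of `x` genes between a set of `m` genes (e.g.
#' DEGs) and a set of `n` genes (e.g. eQTL genes) drawn from a universe of
#' `N` genes is larger than expected under independence. The upper-tail
#' p-value is
#' \deqn{P = \sum_{k=x}^{\min(m,n)} \binom{m}{k} \binom{N-m}{n-k} / \binom{N}{n},}
#' the expected overlap is \eqn{E = mn/N} and the fold enrichment ratio is
#' \eqn{FER = x/E}; FER > 1 indicates over-representation.
#'
#' The sum is evaluated directly on log binomial coefficients; `phyper`
#' serves only as an independent cross-check in the test-suite.
#'
#' @param x observed overlap count
#' @param m size of the first gene set (within the universe)
#' @param n size of the second gene set (within the universe)
#' @param N universe size
#' @return an object of class `enrichment_result`: list with fields
#'   `x`, `m`, `n`, `N`, `E`, `FER`, `pvalue`
#' @examples
#' hypergeometric_enrichment(x = 4, m = 5, n = 4, N = 10)
#' @export
hypergeometric_enrichment <- function(x, m, n, N) {
  stopifnot(length(x) == 1, length(m) == 1, length(n) == 1, length(N) == 1)
  if (N < 1) stop("universe size N must be >= 1")
  if (m > N || n > N) stop("set sizes m, n must not exceed N")
  if (x < 0 || x > min(m, n)) stop("need 0 <= x <= min(m, n)")
  E <- m * n / N
  if (E == 0) {
    res <- list(x = x, m = m, n = n, N = N, E = 0, FER = NA_real_, pvalue = 1)
    class(res) <- "enrichment_result"
    return(res)
  }
  k <- seq.int(x, min(m, n))
  logp <- lchoose(m, k) + lchoose(N - m, n - k) - lchoose(N, n)
  p <- min(1, sum(exp(logp)))
  res <- list(x = x, m = m, n = n, N = N, E = E, FER = x / E, pvalue = p)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "overlap x = %d of m = %d vs n = %d in N = %d; E = %.3f, FER = %s, p = %.3g\n",
    x$x, x$m, x$n, x$N, x$E,
    if (is.na(x$FER)) "NA" else sprintf("%.2f", x$FER), x$pvalue))
  invisible(x)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) {
  data.frame(x = x$x, m = x$m, n = x$n, N = x$N, E = x$E, FER = x$FER,
             pvalue = x$pvalue)
}

#' Enrichment of eQTL genes among DEGs, per dataset and brain region
#'
#' For each (dataset, brain_region) stratum of `degs`, restricts both gene
#' sets to that stratum's analyzed universe and runs
#' [hypergeometric_enrichment()]. The universe of a stratum is the set of
#' genes analyzed there (its rows in `degs`), so genes absent from a
#' platform drop out of m, n and N.
#'
#' @param snp_genes named list: per SNP, the character vector of its
#'   retained eQTL genes (from [filter_eqtl_associations()])
#' @param degs `data.frame` from [call_degs()] (may be several strata
#'   row-bound together)
#' @return list with `enrichment` (one row per stratum: dataset, region,
#'   x, m, n, N, E, FER, pvalue), `deg_overlap` (named logical per SNP:
#'   has at least one eQTL gene called DEG in at least one stratum), and
#'   `eqtl_deg_genes` (eQTL genes that are DEGs anywhere)
#' @export
overlap_eqtl_degs <- function(snp_genes, degs) {
  eqtl_genes <- unique(unlist(snp_genes, use.names = FALSE))
  strata <- unique(degs[, c("dataset", "brain_region")])
  if (nrow(strata) == 0 || nrow(degs) == 0) stop("empty DEG table")
  rows <- vector("list", nrow(strata))
  deg_any <- character(0)
  for (i in seq_len(nrow(strata))) {
    d <- degs[degs$dataset == strata$dataset[i] &
                degs$brain_region == strata$brain_region[i], ]
    universe <- unique(d$gene_id)
    if (length(universe) == 0) stop("empty universe for stratum ", i)
    deg_set <- unique(d$gene_id[d$is_deg])
    eqtl_here <- intersect(eqtl_genes, universe)
    x <- length(intersect(eqtl_here, deg_set))
    er <- hypergeometric_enrichment(x, m = length(deg_set),
                                    n = length(eqtl_here),
                                    N = length(universe))
    rows[[i]] <- data.frame(dataset = strata$dataset[i],
                            brain_region = strata$brain_region[i],
                            as.data.frame(er))
    deg_any <- union(deg_any, intersect(eqtl_here, deg_set))
  }
  flags <- vapply(snp_genes, function(g) any(g %in% deg_any), logical(1))
  list(enrichment = do.call(rbind, rows),
       deg_overlap = flags,
       eqtl_deg_genes = deg_any)
}
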