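#' Distance-decay background model for cis contacts
#'
#' Expected contact count per fragment pair as a function of genomic
#' distance: counts are pooled in log-spaced distance bins, divided by
#' the number of possible fragment pairs in each bin (the Poisson
#' maximum-likelihood mean per pair), then smoothed to be non-increasing
#' by weighted isotonic regression. With a `viewpoint`, the pair universe
#' is viewpoint-fragment x cis-fragment (the 4C-style one-vs-all
#' profile); otherwise all cis fragment pairs.
#'
#' @param records fragment-pair records (see
#'   [assign_pairs_to_fragments()])
#' @param frag a `fragment_map`
#' @param viewpoint optional integer vector of viewpoint fragment ids
#' @param n_bins number of log-spaced distance bins (default 25)
#' @return object of class `decay_model`: list(edges, mid, expected,
#'   n_pairs)
#' @export
fit_distance_decay <- function(records, frag, viewpoint = NULL,
                               n_bins = 25) {
  mid <- (frag$start + frag$end) / 2
  cis <- records[records$chrom1 == records$chrom2, , drop = FALSE]
  if (nrow(cis) == 0 || sum(table(cis$frag1)) == 0) {
    stop("no cis contacts to fit a decay model")
  }
  if (!is.null(viewpoint)) {
    chrom <- unique(frag$chrom[frag$frag_id %in% viewpoint])
    others <- frag$frag_id[frag$chrom %in% chrom &
                             !(frag$frag_id %in% viewpoint)]
    pair_d <- as.vector(abs(outer(mid[viewpoint], mid[others], "-")))
    touch <- (cis$frag1 %in% viewpoint) != (cis$frag2 %in% viewpoint)
    cis <- cis[touch, , drop = FALSE]
    obs_d <- abs(mid[cis$frag1] - mid[cis$frag2])
  } else {
    pair_d <- unlist(lapply(split(frag$frag_id, frag$chrom), function(ids) {
      if (length(ids) < 2) return(numeric(0))
      d <- stats::dist(mid[ids])
      as.vector(d)
    }), use.names = FALSE)
    obs_d <- abs(mid[cis$frag1] - mid[cis$frag2])
  }
  pair_d <- pair_d[pair_d > 0]
  if (length(pair_d) == 0) stop("no testable fragment pairs")
  rng <- range(pair_d)
  edges <- exp(seq(log(max(rng[1], 1)), log(rng[2]), length.out = n_bins + 1))
  edges[1] <- edges[1] * (1 - 1e-9)
  edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-9)
  bin_of <- function(d) pmin(pmax(findInterval(d, edges), 1L), n_bins)
  n_pairs <- tabulate(bin_of(pair_d), n_bins)
  counts <- tabulate(bin_of(obs_d[obs_d > 0]), n_bins)
  keep <- n_pairs > 0
  rate <- ifelse(keep, counts / pmax(n_pairs, 1), NA_real_)
  rate[keep] <- pava_decreasing(rate[keep], n_pairs[keep])
  structure(list(edges = edges,
                 mid = sqrt(edges[-1] * edges[-(n_bins + 1)]),
                 expected = rate, n_pairs = n_pairs),
            class = "decay_model")
}

# weighted pool-adjacent-violators, non-increasing fit
pava_decreasing <- function(y, w) {
  fit <- -pava_increasing(-y, w)
  fit
}

pava_increasing <- function(y, w) {
  n <- length(y)
  vals <- y; wts <- w; sizes <- rep(1L, n); k <- 0L
  for (i in seq_len(n)) {
    k <- k + 1L
    vals[k] <- y[i]; wts[k] <- w[i]; sizes[k] <- 1L
    while (k > 1L && vals[k - 1L] > vals[k]) {
      vals[k - 1L] <- (vals[k - 1L] * wts[k - 1L] + vals[k] * wts[k]) /
        (wts[k - 1L] + wts[k])
      wts[k - 1L] <- wts[k - 1L] + wts[k]
      sizes[k - 1L] <- sizes[k - 1L] + sizes[k]
      k <- k - 1L
    }
  }
  rep(vals[seq_len(k)], sizes[seq_len(k)])
}

#' Expected contact count at given distances under a decay model
#' @param model a `decay_model`
#' @param distance genomic distances in bp
#' @return expected counts (per fragment pair)
#' @export
predict_decay <- function(model, distance) {
  n_bins <- length(model$expected)
  b <- pmin(pmax(findInterval(distance, model$edges), 1L), n_bins)
  out <- model$expected[b]
  # fall back to the nearest informative bin for empty ones
  if (anyNA(out)) {
    ok <- which(!is.na(model$expected))
    nearest <- ok[pmax(1, findInterval(b[is.na(out)], ok))]
    out[is.na(out)] <- model$expected[nearest]
  }
  out
}

#' Fitted log-log slope of a decay model
#' @param model a `decay_model`
#' @return the power-law exponent (slope of log expected vs log distance)
#' @export
decay_exponent <- function(model) {
  ok <- !is.na(model$expected) & model$expected > 0 & model$n_pairs > 0
  stats::coef(stats::lm(log(model$expected[ok]) ~ log(model$mid[ok]),
                        weights = model$n_pairs[ok]))[[2]]
}

#' Select viewpoint fragments for a SNP
#'
#' The viewpoint is anchored at the restriction sites flanking the SNP:
#' the fragment containing the SNP plus the two neighbours sharing those
#' flanking cut sites. A SNP exactly on a cut site yields the two
#' fragments meeting there; chromosome-terminal SNPs return whatever
#' neighbours exist.
#'
#' @param snp one-row SNP `data.frame` (chrom, pos 1-based)
#' @param frag a `fragment_map`
#' @return integer vector of viewpoint fragment ids
#' @export
select_viewpoint <- function(snp, frag) {
  stopifnot(nrow(snp) == 1)
  if (!snp$chrom %in% frag$chrom) stop("SNP chromosome not in fragment map")
  p0 <- snp$pos - 1
  f <- frag_of(frag, snp$chrom, p0)
  if (is.na(f)) stop("SNP position outside chromosome bounds")
  chrom_frags <- frag$frag_id[frag$chrom == snp$chrom]
  on_cut <- frag$start[frag$frag_id == f] == p0 && f != min(chrom_frags)
  ids <- if (on_cut) c(f - 1L, f) else c(f - 1L, f, f + 1L)
  sort(unique(ids[ids %in% chrom_frags]))
}

#' Call significant viewpoint interactions against the decay background
#'
#' For every cis fragment outside the viewpoint, the observed count is
#' the number of contacts with any viewpoint fragment, aggregated over a
#' rolling window of `window` fragments (1 = no aggregation); the
#' expected count is the decay-model prediction summed over viewpoint
#' fragments and the same window. The p-value is the upper-tail Poisson
#' probability of the observed count, BH-adjusted over tested fragments;
#' calls are significant at adjusted p < `alpha`.
#'
#' @param viewpoint integer vector of viewpoint fragment ids
#' @param records fragment-pair records (filtered)
#' @param frag a `fragment_map`
#' @param decay optional `decay_model`; fitted from the viewpoint's own
#'   profile when NULL
#' @param window number of fragments aggregated (default 1, i.e. none)
#' @param alpha FDR level (default 0.05)
#' @return `data.frame` of interaction calls: target_frag, chrom, start,
#'   end, distance, observed, expected, pvalue, padj, significant
#' @export
call_viewpoint_interactions <- function(viewpoint, records, frag,
                                        decay = NULL, window = 1,
                                        alpha = 0.05) {
  mid <- (frag$start + frag$end) / 2
  chrom <- unique(frag$chrom[frag$frag_id %in% viewpoint])
  stopifnot(length(chrom) == 1)
  cis <- records[records$chrom1 == chrom & records$chrom2 == chrom, ,
                 drop = FALSE]
  touch <- (cis$frag1 %in% viewpoint) != (cis$frag2 %in% viewpoint)
  vp_rec <- cis[touch, , drop = FALSE]
  if (nrow(vp_rec) == 0) {
    warning("viewpoint has no contacts; empty call list")
    return(empty_calls())
  }
  partner <- ifelse(vp_rec$frag1 %in% viewpoint, vp_rec$frag2, vp_rec$frag1)
  targets <- frag[frag$chrom == chrom & !(frag$frag_id %in% viewpoint), ,
                  drop = FALSE]
  targets <- targets[order(targets$start), ]
  obs <- tabulate(match(partner, targets$frag_id), nrow(targets))
  if (is.null(decay)) {
    decay <- fit_distance_decay(records, frag, viewpoint = viewpoint)
  }
  vp_mid <- mid[viewpoint]
  exp_mat <- vapply(vp_mid, function(vm)
    predict_decay(decay, abs(mid[targets$frag_id] - vm)),
    numeric(nrow(targets)))
  expected <- rowSums(as.matrix(exp_mat))
  if (window > 1) {
    obs <- roll_sum(obs, window)
    expected <- roll_sum(expected, window)
  }
  vp_center <- mean(range(frag$start[frag$frag_id %in% viewpoint],
                          frag$end[frag$frag_id %in% viewpoint]))
  ok <- expected > 0
  pv <- rep(NA_real_, nrow(targets))
  pv[ok] <- stats::ppois(obs[ok] - 1, expected[ok], lower.tail = FALSE)
  padj <- rep(NA_real_, nrow(targets))
  padj[ok] <- stats::p.adjust(pv[ok], method = "BH")
  data.frame(target_frag = targets$frag_id, chrom = chrom,
             start = targets$start, end = targets$end,
             distance = mid[targets$frag_id] - vp_center,
             observed = obs, expected = expected,
             pvalue = pv, padj = padj,
             significant = !is.na(padj) & padj < alpha,
             stringsAsFactors = FALSE)
}

empty_calls <- function() {
  data.frame(target_frag = integer(), chrom = character(),
             start = numeric(), end = numeric(), distance = numeric(),
             observed = numeric(), expected = numeric(),
             pvalue = numeric(), padj = numeric(), significant = logical())
}

roll_sum <- function(x, w) {
  # centered rolling sum; edge windows truncated to available fragments
  n <- length(x)
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  cs[hi + 1] - cs[lo]
}

#' Signed extent of significant viewpoint interactions
#' @param calls output of [call_viewpoint_interactions()]
#' @return named numeric `c(min, max)` of signed distances from the
#'   viewpoint, or an empty numeric vector when nothing is significant
#' @export
loops_extent <- function(calls) {
  d <- calls$distance[calls$significant]
  if (length(d) == 0) return(numeric(0))
  c(min = min(d), max = max(d))
}
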