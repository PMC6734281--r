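#' Generate Hi-C-style read pairs from a distance-decay contact model
#' with planted TADs and viewpoint loops
#'
#' Cis fragment pairs are sampled with probability proportional to
#' \eqn{d^{\alpha} \cdot f_{tad}^{[same\ TAD]} \cdot f_{loop}^{[anchor]}}
#' (\eqn{d} = midpoint distance, \eqn{\alpha} = `decay_exponent` < 0),
#' optionally multiplied by a capture-enrichment factor for pairs
#' touching `enriched_frags` (emulating targeted viewpoint capture).
#' Read positions are jittered uniformly within each fragment. A
#' configurable fraction of exact duplicates and of same-fragment pairs
#' is appended to exercise the pair filters.
#'
#' @param frag a `fragment_map`
#' @param tad_boundaries named list per chromosome of boundary bin
#'   indices (starting 0, ending at the bin count) at `bin_size`
#'   resolution
#' @param bin_size bin size the boundaries refer to
#' @param loop_anchors `data.frame` with viewpoint_frag, target_frag,
#'   fold (>= 1); both fragments must exist and be cis
#' @param n_pairs number of model-drawn pairs (a warning is logged below
#'   10 x fragment count)
#' @param decay_exponent power-law exponent, must be negative
#' @param intra_tad_fold contact enrichment within planted TADs (>= 1)
#' @param dup_frac fraction of extra exact-duplicate rows
#' @param self_frac fraction of extra same-fragment rows
#' @param enriched_frags fragment ids with capture enrichment
#' @param viewpoint_enrichment multiplicative capture factor (>= 1)
#' @param seed generator stream seed
#' @return list(pairs = read-pair `data.frame`, truth = list with the
#'   planted model settings and the planted duplicate/self counts)
#' @export
gen_hic_pairs <- function(frag, tad_boundaries, bin_size, loop_anchors,
                          n_pairs, decay_exponent = -1,
                          intra_tad_fold = 3, dup_frac = 0.05,
                          self_frac = 0.02, enriched_frags = integer(),
                          viewpoint_enrichment = 1, seed = 1) {
  if (decay_exponent >= 0) stop("decay_exponent must be negative")
  if (intra_tad_fold < 1) stop("intra_tad_fold must be >= 1")
  if (!is.null(loop_anchors) && nrow(loop_anchors)) {
    if (any(loop_anchors$fold < 1)) stop("loop folds must be >= 1")
    if (!all(c(loop_anchors$viewpoint_frag, loop_anchors$target_frag)
             %in% frag$frag_id)) {
      stop("loop anchor fragment(s) not in fragment map")
    }
  }
  if (n_pairs < 10 * nrow(frag)) {
    warning("n_pairs below 10 x fragment count; library will be sparse")
  }
  mid <- (frag$start + frag$end) / 2
  chroms <- unique(frag$chrom)
  with_seed(seed, {
    per_chrom <- lapply(chroms, function(chrom) {
      ids <- frag$frag_id[frag$chrom == chrom]
      F <- length(ids)
      if (F < 2) return(NULL)
      m <- mid[ids]
      d <- abs(outer(m, m, "-"))
      w <- pmax(d, 1000)^decay_exponent
      if (intra_tad_fold > 1 && !is.null(tad_boundaries[[chrom]])) {
        block <- findInterval(floor(m / bin_size),
                              tad_boundaries[[chrom]][-length(
                                tad_boundaries[[chrom]])])
        w <- w * intra_tad_fold^outer(block, block, "==")
      }
      if (!is.null(loop_anchors) && nrow(loop_anchors)) {
        for (a in seq_len(nrow(loop_anchors))) {
          i <- match(loop_anchors$viewpoint_frag[a], ids)
          j <- match(loop_anchors$target_frag[a], ids)
          if (!is.na(i) && !is.na(j)) {
            w[i, j] <- w[i, j] * loop_anchors$fold[a]
            w[j, i] <- w[j, i] * loop_anchors$fold[a]
          }
        }
      }
      if (viewpoint_enrichment > 1 && length(enriched_frags)) {
        enr <- ids %in% enriched_frags
        boost <- ifelse(enr, viewpoint_enrichment, 1)
        w <- w * outer(boost, boost, pmax)
      }
      ut <- upper.tri(w)
      list(ids = ids, i = row(w)[ut], j = col(w)[ut], w = w[ut])
    })
    per_chrom <- per_chrom[!vapply(per_chrom, is.null, TRUE)]
    tot_w <- vapply(per_chrom, function(x) sum(x$w), numeric(1))
    n_chrom_pairs <- as.vector(stats::rmultinom(1, n_pairs,
                                                tot_w / sum(tot_w)))
    sampled <- do.call(rbind, lapply(seq_along(per_chrom), function(c) {
      pc <- per_chrom[[c]]
      k <- n_chrom_pairs[c]
      if (k == 0) return(NULL)
      pick <- sample.int(length(pc$w), k, replace = TRUE, prob = pc$w)
      data.frame(f1 = pc$ids[pc$i[pick]], f2 = pc$ids[pc$j[pick]])
    }))
    n_self <- round(self_frac * n_pairs)
    if (n_self > 0) {
      sf <- sample(frag$frag_id, n_self, replace = TRUE)
      sampled <- rbind(sampled, data.frame(f1 = sf, f2 = sf))
    }
    jitter_in <- function(f) {
      lo <- frag$start[f] + 1
      span <- frag$end[f] - frag$start[f]
      lo + floor(stats::runif(length(f)) * span)
    }
    pairs <- data.frame(
      read_id = sprintf("read%07d", seq_len(nrow(sampled))),
      chrom1 = frag$chrom[sampled$f1], pos1 = jitter_in(sampled$f1),
      chrom2 = frag$chrom[sampled$f2], pos2 = jitter_in(sampled$f2),
      strand1 = sample(c("+", "-"), nrow(sampled), replace = TRUE),
      strand2 = sample(c("+", "-"), nrow(sampled), replace = TRUE),
      stringsAsFactors = FALSE)
    n_dup <- round(dup_frac * n_pairs)
    if (n_dup > 0) {
      dup <- pairs[sample.int(nrow(pairs), n_dup, replace = FALSE), ]
      dup$read_id <- sprintf("dup%07d", seq_len(n_dup))
      pairs <- rbind(pairs, dup)
    }
    pairs <- pairs[sample.int(nrow(pairs)), ]
    rownames(pairs) <- NULL
    list(pairs = pairs,
         truth = list(n_model_pairs = n_pairs, n_duplicates = n_dup,
                      n_self = n_self, decay_exponent = decay_exponent,
                      intra_tad_fold = intra_tad_fold,
                      loop_anchors = loop_anchors,
                      tad_boundaries = tad_boundaries))
  })
}

#' Write read pairs in the 7-column pairs TSV dialect
#' @param pairs pair `data.frame`
#' @param path output path
#' @export
write_pairs <- function(pairs, path) {
  con <- file(path, "w")
  writeLines("# columns: readID chr1 pos1 chr2 pos2 strand1 strand2", con)
  close(con)
  data.table::fwrite(pairs, path, sep = "\t", col.names = FALSE,
                     append = TRUE, quote = FALSE)
  invisible(path)
}
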