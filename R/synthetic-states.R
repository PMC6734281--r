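#' Generate per-epigenome chromatin-state segmentations with planted
#' enhancer SNPs
#'
#' Each epigenome's segmentation is a gap-free, overlap-free partition of
#' every chromosome into intervals labeled with the 25-state vocabulary.
#' The background tiling uses only non-enhancer states; every planted SNP
#' then gets a small enhancer-state window carved around its position in
#' a random subset of epigenomes (at least one), so the planted per-SNP
#' epigenome counts are exact ground truth. Positions in `keep_clear`
#' never receive an enhancer state in any epigenome. Extra enhancer
#' segments are scattered away from all SNPs for realism.
#'
#' @param chrom_lengths named vector of chromosome lengths
#' @param n_epigenomes epigenome count
#' @param brain_ids ids designated brain (must be a subset of the
#'   generated ids E001..E<n>)
#' @param plant `data.frame` of planted enhancer SNPs: rsid, chrom, pos
#' @param keep_clear `data.frame` of positions kept enhancer-free:
#'   chrom, pos
#' @param seed generator stream seed
#' @param enhancer_states mnemonics usable for planted windows (validated
#'   against the vocabulary)
#' @param window_bp width of each planted enhancer window
#' @param n_extra extra decoy enhancer segments per epigenome
#' @return list(segmentations = named list of interval `data.frame`s,
#'   metadata = data.frame(epigenome_id, is_brain), truth = per-SNP
#'   enhancer_count / brain_enhancer_count)
#' @export
gen_chromatin_states <- function(chrom_lengths, n_epigenomes = 8,
                                 brain_ids = NULL, plant = NULL,
                                 keep_clear = NULL, seed = 1,
                                 enhancer_states = ENHANCER_STATES,
                                 window_bp = 500, n_extra = 20) {
  epi_ids <- sprintf("E%03d", seq_len(n_epigenomes))
  if (is.null(brain_ids)) brain_ids <- epi_ids[seq_len(min(3, n_epigenomes))]
  if (!all(brain_ids %in% epi_ids)) {
    stop("brain_ids outside generated epigenome ids")
  }
  bad <- setdiff(enhancer_states, STATE_MNEMONICS_25)
  if (length(bad)) stop("unknown state mnemonic(s): ",
                        paste(bad, collapse = ", "))
  background_states <- setdiff(STATE_MNEMONICS_25, ENHANCER_STATES)
  avoid <- rbind(
    if (!is.null(plant)) plant[, c("chrom", "pos")],
    if (!is.null(keep_clear)) keep_clear[, c("chrom", "pos")])
  with_seed(seed, {
    n_plant <- if (is.null(plant)) 0 else nrow(plant)
    # planted membership: each SNP in >= 1 epigenome
    member <- matrix(FALSE, n_plant, n_epigenomes,
                     dimnames = list(plant$rsid, epi_ids))
    if (n_plant > 0) {
      for (i in seq_len(n_plant)) {
        k <- sample.int(n_epigenomes, 1)
        member[i, sample.int(n_epigenomes, k)] <- TRUE
      }
    }
    segmentations <- lapply(seq_len(n_epigenomes), function(j) {
      segs <- do.call(rbind, lapply(names(chrom_lengths), function(chrom) {
        tile_chromosome(chrom, chrom_lengths[[chrom]], background_states)
      }))
      if (n_plant > 0) {
        for (i in which(member[, j])) {
          s <- max(0, plant$pos[i] - 1 - floor(window_bp / 2))
          e <- min(chrom_lengths[[plant$chrom[i]]], s + window_bp)
          segs <- carve_interval(segs, plant$chrom[i], s, e,
                                 sample(enhancer_states, 1))
        }
      }
      # decoy enhancers away from every SNP position
      for (k in seq_len(n_extra)) {
        chrom <- sample(names(chrom_lengths), 1)
        for (try in 1:50) {
          s <- sample.int(chrom_lengths[[chrom]] - window_bp, 1)
          near <- avoid$pos[avoid$chrom == chrom]
          if (!length(near) ||
              min(abs(near - s)) > window_bp + 2000) break
          s <- NA
        }
        if (!is.na(s)) {
          segs <- carve_interval(segs, chrom, s, s + window_bp,
                                 sample(enhancer_states, 1))
        }
      }
      rownames(segs) <- NULL
      segs
    })
    names(segmentations) <- epi_ids
    is_brain <- epi_ids %in% brain_ids
    truth <- if (n_plant > 0) {
      data.frame(rsid = plant$rsid,
                 enhancer_count = as.integer(rowSums(member)),
                 brain_enhancer_count =
                   as.integer(rowSums(member[, is_brain, drop = FALSE])),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(rsid = character(), enhancer_count = integer(),
                 brain_enhancer_count = integer())
    }
    list(segmentations = segmentations,
         metadata = data.frame(epigenome_id = epi_ids,
                               is_brain = is_brain),
         truth = truth)
  })
}

tile_chromosome <- function(chrom, L, labels, mean_len = 3000) {
  n <- ceiling(L / mean_len) + 10
  lens <- pmax(200, round(stats::rexp(n, 1 / mean_len)))
  ends <- cumsum(lens)
  ends <- c(ends[ends < L], L)
  starts <- c(0, ends[-length(ends)])
  data.frame(chrom = chrom, start = starts, end = ends,
             label = sample(labels, length(ends), replace = TRUE),
             stringsAsFactors = FALSE)
}

# replace [s, e) on chrom with `label`, keeping the partition property
carve_interval <- function(segs, chrom, s, e, label) {
  on_chr <- segs$chrom == chrom
  iv <- segs[on_chr, , drop = FALSE]
  rest <- segs[!on_chr, , drop = FALSE]
  hit <- iv$start < e & iv$end > s
  left <- iv[hit & iv$start < s, , drop = FALSE]
  if (nrow(left)) left$end <- s
  right <- iv[hit & iv$end > e, , drop = FALSE]
  if (nrow(right)) right$start <- e
  new <- data.frame(chrom = chrom, start = s, end = e, label = label,
                    stringsAsFactors = FALSE)
  out <- rbind(rest, iv[!hit, , drop = FALSE],
               utils::head(left, 1), new, utils::tail(right, 1))
  out <- out[out$end > out$start, , drop = FALSE]
  out[order(out$chrom, out$start), ]
}

#' Write chromatin-state segmentations as one BED per epigenome plus a
#' metadata TSV
#' @param states output of [gen_chromatin_states()]
#' @param dir output directory
#' @return data.frame of written paths (epigenome_id, path, is_brain)
#' @export
write_chromatin_states <- function(states, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(states$segmentations), function(id) {
    p <- file.path(dir, paste0(id, "_25state.bed"))
    write_bed(states$segmentations[[id]], p)
    p
  }, character(1))
  meta <- states$metadata
  meta$path <- unname(paths)
  write_tsv(meta, file.path(dir, "epigenomes.tsv"))
  meta
}
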