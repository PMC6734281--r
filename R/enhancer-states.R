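#' Chromatin-state vocabulary and enhancer states
#'
#' The 25 mnemonics of the imputation-based chromatin-state model
#' (ChromHMM over 12 marks), and the six states treated as enhancers:
#' active enhancers EnhA1/EnhA2, their flank EnhAF, weak enhancers
#' EnhW1/EnhW2, and the H3K27ac-only EnhAc. Both sets are configurable in
#' every function that consumes them.
#' @export
STATE_MNEMONICS_25 <- c(
  "TssA", "PromU", "PromD1", "PromD2", "Tx5'", "Tx", "Tx3'", "TxWk",
  "TxReg", "TxEnh5'", "TxEnh3'", "TxEnhW", "EnhA1", "EnhA2", "EnhAF",
  "EnhW1", "EnhW2", "EnhAc", "DNase", "ZNF/Rpts", "Het", "PromP",
  "PromBiv", "ReprPC", "Quies")

#' @rdname STATE_MNEMONICS_25
#' @export
ENHANCER_STATES <- c("EnhA1", "EnhA2", "EnhAF", "EnhW1", "EnhW2", "EnhAc")

#' Load one epigenome's chromatin-state segmentation
#'
#' Validates that labels come from the 25-mnemonic vocabulary and that the
#' intervals partition each chromosome: sorted, starting at 0, with no
#' internal gap or overlap (a terminal gap before the chromosome end is
#' tolerated, as segmentations are often truncated at the last informative
#' bin).
#'
#' @param path BED4 path (chrom, start, end, state mnemonic)
#' @param epigenome_id identifier, e.g. "E071"
#' @param brain_ids character vector of epigenome ids designated brain
#' @param vocabulary allowed state labels
#' @return object of class `state_segmentation`: list(epigenome_id,
#'   intervals, is_brain)
#' @export
load_state_segmentation <- function(path, epigenome_id,
                                    brain_ids = character(),
                                    vocabulary = STATE_MNEMONICS_25) {
  intervals <- read_bed(path)
  if (!"label" %in% names(intervals)) stop("state BED needs a label column")
  unknown <- setdiff(unique(intervals$label), vocabulary)
  if (length(unknown)) {
    stop("unknown state mnemonic(s): ", paste(unknown, collapse = ", "))
  }
  for (chrom in unique(intervals$chrom)) {
    iv <- intervals[intervals$chrom == chrom, ]
    iv <- iv[order(iv$start), ]
    if (iv$start[1] != 0) stop("segmentation of ", chrom,
                               " does not start at 0")
    if (nrow(iv) > 1 && any(iv$start[-1] != iv$end[-nrow(iv)])) {
      stop("gap or overlap in segmentation of ", chrom)
    }
  }
  structure(list(epigenome_id = epigenome_id, intervals = intervals,
                 is_brain = epigenome_id %in% brain_ids),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat(sprintf("state_segmentation %s (%s): %d intervals, %d states\n",
              x$epigenome_id, if (x$is_brain) "brain" else "non-brain",
              nrow(x$intervals), length(unique(x$intervals$label))))
  invisible(x)
}

#' Annotate SNPs with chromatin states and enhancer epigenome counts
#'
#' A SNP is "in an enhancer" iff its position falls inside an interval
#' labeled with one of `enhancer_states` in at least one epigenome.
#' Positions exactly on a segment boundary belong to the segment
#' containing the 0-based position (half-open convention).
#'
#' @param snps SNP `data.frame` (needs rsid, chrom, pos)
#' @param segs list of `state_segmentation` objects
#' @param enhancer_states mnemonics counted as enhancer
#' @return `data.frame`: rsid, enhancer_count, brain_enhancer_count,
#'   in_enhancer, in_brain_enhancer; the per-epigenome state labels are
#'   attached as attribute `state_matrix` (SNPs x epigenomes)
#' @export
annotate_snp_enhancers <- function(snps, segs,
                                   enhancer_states = ENHANCER_STATES) {
  vocab <- unique(unlist(lapply(segs, function(s) s$intervals$label)))
  bad <- setdiff(enhancer_states, STATE_MNEMONICS_25)
  if (length(bad)) stop("enhancer states outside vocabulary: ",
                        paste(bad, collapse = ", "))
  pts <- point_interval(snps$chrom, snps$pos)
  states <- matrix(NA_character_, nrow = nrow(snps), ncol = length(segs),
                   dimnames = list(snps$rsid,
                                   vapply(segs, `[[`, "", "epigenome_id")))
  for (j in seq_along(segs)) {
    hits <- interval_overlap(pts, segs[[j]]$intervals)
    states[hits$query, j] <- segs[[j]]$intervals$label[hits$subject]
  }
  is_enh <- !is.na(states) & matrix(states %in% enhancer_states,
                                    nrow = nrow(states))
  brain <- vapply(segs, `[[`, logical(1), "is_brain")
  ann <- data.frame(
    rsid = snps$rsid,
    enhancer_count = as.integer(rowSums(is_enh)),
    brain_enhancer_count = as.integer(rowSums(is_enh[, brain, drop = FALSE])),
    stringsAsFactors = FALSE)
  ann$in_enhancer <- ann$enhancer_count > 0
  ann$in_brain_enhancer <- ann$brain_enhancer_count > 0
  attr(ann, "state_matrix") <- states
  ann
}

#' Summarize enhancer annotation over non-coding SNPs
#'
#' Reports how many non-coding SNPs fall in enhancers overall and in
#' brain epigenomes, with percentages against the non-coding denominator.
#' The three-way split \{brain enhancer, non-brain enhancer,
#' non-enhancer\} lets "brain" take precedence: a SNP in both brain and
#' non-brain enhancers counts as brain.
#'
#' @param annotations output of [annotate_snp_enhancers()] (already
#'   restricted to non-coding SNPs)
#' @return one-row `data.frame` with counts and percentages
#' @export
summarize_enhancer_tissues <- function(annotations) {
  n <- nrow(annotations)
  n_enh <- sum(annotations$in_enhancer)
  n_brain <- sum(annotations$in_brain_enhancer)
  pct <- function(x) if (n == 0) 0 else 100 * x / n
  data.frame(
    n_noncoding = n,
    n_enhancer = n_enh,
    n_brain_enhancer = n_brain,
    n_nonbrain_enhancer = n_enh - n_brain,
    n_non_enhancer = n - n_enh,
    pct_enhancer = pct(n_enh),
    pct_brain_enhancer = pct(n_brain),
    pct_nonbrain_enhancer = pct(n_enh - n_brain))
}
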