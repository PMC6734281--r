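#' Restriction-fragment map from a genome or a cut-site BED
#'
#' The FASTA path scans each chromosome for the HindIII recognition motif
#' `AAGCTT` and cuts one base into the motif (A^AGCTT), so a motif whose
#' 0-based start is `s` yields a cut at `s + 1`. The BED path takes cut
#' positions verbatim (`start` column of a BED3 of zero- or one-width
#' site records). Terminal fragments are always included; a chromosome
#' with no site becomes a single whole-chromosome fragment with a
#' warning.
#'
#' @param fasta path to a genome FASTA, or a `Biostrings::DNAStringSet`
#' @param sites_bed path to a cut-site BED (alternative to `fasta`)
#' @param chrom_lengths named vector of chromosome lengths; required with
#'   `sites_bed`, derived from the sequences otherwise
#' @param motif recognition motif (default HindIII `AAGCTT`)
#' @param cut_offset offset of the cut into the motif (default 1)
#' @return object of class `fragment_map`: data.frame(chrom, start, end,
#'   frag_id) with dense ids sorted by coordinate, plus `chrom_lengths`
#'   attribute
#' @export
digest_fragments <- function(fasta = NULL, sites_bed = NULL,
                             chrom_lengths = NULL, motif = "AAGCTT",
                             cut_offset = 1) {
  if (!is.null(fasta)) {
    seqs <- if (inherits(fasta, "DNAStringSet")) fasta else
      Biostrings::readDNAStringSet(fasta)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    chrom_lengths <- stats::setNames(Biostrings::width(seqs), names(seqs))
    cuts <- lapply(names(seqs), function(chrom) {
      m <- Biostrings::matchPattern(motif, seqs[[chrom]])
      BiocGenerics::start(m) - 1 + cut_offset   # 0-based cut positions
    })
    names(cuts) <- names(seqs)
  } else if (!is.null(sites_bed)) {
    if (is.null(chrom_lengths)) stop("chrom_lengths required with sites_bed")
    sites <- read_bed(sites_bed)
    cuts <- lapply(names(chrom_lengths), function(chrom)
      sort(sites$start[sites$chrom == chrom]))
    names(cuts) <- names(chrom_lengths)
  } else {
    stop("provide fasta or sites_bed")
  }
  frags <- lapply(names(chrom_lengths), function(chrom) {
    L <- as.numeric(chrom_lengths[[chrom]])
    cs <- cuts[[chrom]]
    cs <- cs[cs > 0 & cs < L]
    if (length(cs) == 0) {
      warning("no cut site on ", chrom, ": single whole-chromosome fragment")
    }
    bounds <- c(0, cs, L)
    data.frame(chrom = chrom, start = bounds[-length(bounds)],
               end = bounds[-1], stringsAsFactors = FALSE)
  })
  fm <- do.call(rbind, frags)
  fm$frag_id <- seq_len(nrow(fm))
  attr(fm, "chrom_lengths") <- chrom_lengths
  class(fm) <- c("fragment_map", "data.frame")
  fm
}

frag_of <- function(fm, chrom, pos0) {
  # fragment id containing each 0-based position; NA for unknown chrom
  out <- rep(NA_integer_, length(pos0))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    f <- fm[fm$chrom == ch, ]
    if (nrow(f) == 0) next
    k <- findInterval(pos0[idx], f$start)
    ok <- k >= 1 & pos0[idx] < f$end[pmax(k, 1)]
    out[idx[ok]] <- f$frag_id[k[ok]]
  }
  out
}

#' Read a pairs-format TSV of aligned read pairs
#'
#' Dialect: 7 tab-separated columns `readID chr1 pos1 chr2 pos2 strand1
#' strand2` (positions 1-based), comment lines starting with `#`.
#' @param path pairs TSV path
#' @return `data.frame` of read pairs
#' @export
read_pairs <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", skip = "#",
                          col.names = c("read_id", "chrom1", "pos1",
                                        "chrom2", "pos2", "strand1",
                                        "strand2"))
  as.data.frame(dt)
}

#' Assign read-pair ends to restriction fragments
#'
#' Each end maps to the fragment containing it; the record is stored with
#' `frag1 <= frag2` (canonical ordering, swapping positions and strands
#' along). Pairs on chromosomes absent from the fragment map are dropped
#' and counted in the QC tally.
#'
#' @param pairs `data.frame` from [read_pairs()]
#' @param frag a `fragment_map`
#' @return list(records, qc): records has frag1, frag2, pos1, pos2,
#'   strand1, strand2, chrom1, chrom2; qc counts input / unknown_chrom /
#'   kept
#' @export
assign_pairs_to_fragments <- function(pairs, frag) {
  f1 <- frag_of(frag, pairs$chrom1, pairs$pos1 - 1)
  f2 <- frag_of(frag, pairs$chrom2, pairs$pos2 - 1)
  ok <- !is.na(f1) & !is.na(f2)
  rec <- data.frame(frag1 = f1[ok], frag2 = f2[ok],
                    chrom1 = pairs$chrom1[ok], chrom2 = pairs$chrom2[ok],
                    pos1 = pairs$pos1[ok], pos2 = pairs$pos2[ok],
                    strand1 = pairs$strand1[ok], strand2 = pairs$strand2[ok],
                    stringsAsFactors = FALSE)
  swap <- rec$frag1 > rec$frag2
  if (any(swap)) {
    rec[swap, c("frag1", "frag2", "chrom1", "chrom2", "pos1", "pos2",
                "strand1", "strand2")] <-
      rec[swap, c("frag2", "frag1", "chrom2", "chrom1", "pos2", "pos1",
                  "strand2", "strand1")]
  }
  list(records = rec,
       qc = c(input = nrow(pairs), unknown_chrom = sum(!ok),
              kept = nrow(rec)))
}

#' Filter non-informative fragment-pair records
#'
#' Applies, in order: (1) exact-duplicate removal (same fragments,
#' positions and strands — PCR duplicates), (2) same-fragment pairs
#' (self-ligation and dangling ends), (3) pairs touching fragments in the
#' top coverage quantile (default top 0.5%). Each rule is individually
#' switchable. The QC report gives counts removed per rule; input equals
#' kept plus the per-rule removals.
#'
#' @param records `data.frame` from [assign_pairs_to_fragments()]
#' @param remove_duplicates,remove_same_fragment,remove_high_coverage
#'   rule switches
#' @param coverage_quantile fragments above this coverage quantile are
#'   discarded (default 0.995)
#' @return list(records, qc)
#' @export
filter_pairs <- function(records, remove_duplicates = TRUE,
                         remove_same_fragment = TRUE,
                         remove_high_coverage = TRUE,
                         coverage_quantile = 0.995) {
  n_in <- nrow(records)
  qc <- c(input = n_in, duplicate = 0L, same_fragment = 0L,
          high_coverage = 0L)
  if (remove_duplicates && n_in > 0) {
    key <- paste(records$frag1, records$frag2, records$pos1, records$pos2,
                 records$strand1, records$strand2)
    dup <- duplicated(key)
    qc["duplicate"] <- sum(dup)
    records <- records[!dup, , drop = FALSE]
  }
  if (remove_same_fragment && nrow(records) > 0) {
    self <- records$frag1 == records$frag2
    qc["same_fragment"] <- sum(self)
    records <- records[!self, , drop = FALSE]
  }
  if (remove_high_coverage && nrow(records) > 0) {
    cov <- table(c(records$frag1, records$frag2))
    cutoff <- stats::quantile(cov, coverage_quantile, names = FALSE)
    hot <- as.integer(names(cov)[cov > cutoff])
    drop <- records$frag1 %in% hot | records$frag2 %in% hot
    qc["high_coverage"] <- sum(drop)
    records <- records[!drop, , drop = FALSE]
  }
  rownames(records) <- NULL
  qc <- c(qc, kept = nrow(records))
  list(records = records, qc = qc)
}
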