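#' Bin fragment-level contacts into per-chromosome contact matrices
#'
#' Each record is assigned by the midpoints of its two fragments; cis
#' records increment the symmetric count matrix at the two bin indices
#' (off-diagonal entries on both triangles, diagonal entries stored
#' once). Conservation convention: `sum(counts) + sum(diag(counts))`
#' equals twice the cis record count, i.e. diagonal contacts count twice
#' in marginals. Trans records are tallied but not binned.
#'
#' @param records filtered records (see [filter_pairs()])
#' @param frag a `fragment_map`
#' @param bin_size bin size in bp (the conventional TAD scale is 100 kb)
#' @return named list of `contact_matrix` objects, one per chromosome,
#'   with attribute `trans_pairs`
#' @export
bin_contacts <- function(records, frag, bin_size = 1e5) {
  stopifnot(bin_size > 0)
  chrom_lengths <- attr(frag, "chrom_lengths")
  mid <- (frag$start + frag$end) / 2
  cis <- records$chrom1 == records$chrom2
  out <- list()
  for (chrom in names(chrom_lengths)) {
    n_bins <- ceiling(as.numeric(chrom_lengths[[chrom]]) / bin_size)
    counts <- matrix(0, n_bins, n_bins)
    sel <- which(cis & records$chrom1 == chrom)
    if (length(sel)) {
      b1 <- floor(mid[records$frag1[sel]] / bin_size) + 1
      b2 <- floor(mid[records$frag2[sel]] / bin_size) + 1
      tab <- table(factor(pmin(b1, b2), levels = seq_len(n_bins)),
                   factor(pmax(b1, b2), levels = seq_len(n_bins)))
      upper <- matrix(as.numeric(tab), n_bins, n_bins)
      counts <- upper + t(upper)
      diag(counts) <- diag(upper)
    }
    out[[chrom]] <- new_contact_matrix(chrom, bin_size, counts)
  }
  attr(out, "trans_pairs") <- sum(!cis)
  out
}

#' Construct a contact matrix object
#' @param chrom chromosome name
#' @param bin_size bin size in bp
#' @param counts symmetric nonnegative count matrix
#' @param normalized whether the counts are already balanced
#' @param bias optional per-bin bias vector
#' @return a `contact_matrix`
#' @export
contact_matrix <- function(chrom, bin_size, counts, normalized = FALSE,
                           bias = NULL) {
  new_contact_matrix(chrom, bin_size, counts, normalized, bias)
}

new_contact_matrix <- function(chrom, bin_size, counts,
                               normalized = FALSE, bias = NULL) {
  if (max(abs(counts - t(counts))) > 1e-9) {
    stop("contact matrix must be symmetric")
  }
  if (any(counts < 0)) stop("contact matrix must be nonnegative")
  structure(list(chrom = chrom, bin_size = bin_size, counts = counts,
                 normalized = normalized, bias = bias),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix %s: %d bins of %g bp, %s, total %g\n",
              x$chrom, nrow(x$counts), x$bin_size,
              if (x$normalized) "normalized" else "raw",
              sum(x$counts)))
  invisible(x)
}

cm_marginals <- function(counts) {
  # diagonal counts twice, matching the storage convention
  rowSums(counts) + diag(counts)
}

#' Iterative correction (matrix balancing) of a contact matrix
#'
#' Classical equal-visibility iterative correction: repeatedly divides
#' rows and columns by their relative marginals until the maximum
#' relative deviation of unmasked marginals from their mean is below
#' `tol`. All-zero rows are masked and excluded from the convergence
#' check. The returned bias vector satisfies
#' `counts_raw[i,j] / (bias[i] * bias[j]) = counts_normalized[i,j]` up to
#' the final global rescaling that keeps the total signal constant.
#'
#' @param cm a `contact_matrix` (raw counts)
#' @param max_iter maximum sweeps (default 2000)
#' @param tol convergence tolerance on relative marginal deviation
#'   (default 1e-7)
#' @return a normalized `contact_matrix` with `bias` filled; masked bins
#'   have bias NA
#' @export
ice_normalize <- function(cm, max_iter = 2000, tol = 1e-7) {
  counts <- cm$counts
  if (max(abs(counts - t(counts))) > 1e-9) stop("matrix not symmetric")
  n <- nrow(counts)
  mask <- cm_marginals(counts) == 0
  bias <- rep(1, n)
  total0 <- sum(counts)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- cm_marginals(counts)
    s_u <- s[!mask]
    if (length(s_u) == 0) break
    dev <- max(abs(s_u / mean(s_u) - 1))
    if (dev < tol) { converged <- TRUE; break }
    delta <- s / mean(s_u)
    delta[mask | delta == 0] <- 1
    counts <- counts / outer(delta, delta)
    bias <- bias * delta
  }
  if (!converged && max_iter > 0) {
    warning("iterative correction stopped at max_iter = ", max_iter)
  }
  if (sum(counts) > 0) counts <- counts * (total0 / sum(counts))
  bias[mask] <- NA_real_
  new_contact_matrix(cm$chrom, cm$bin_size, counts,
                     normalized = TRUE, bias = bias)
}

#' Write a contact matrix as a dense TSV (bins as rows/columns)
#' @param cm a `contact_matrix`
#' @param path output path
#' @export
write_contact_matrix <- function(cm, path) {
  data.table::fwrite(as.data.frame(cm$counts), path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}
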