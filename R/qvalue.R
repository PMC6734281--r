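#' Storey q-values (single-lambda variant)
#'
#' Estimates the null proportion as
#' \eqn{\hat\pi_0 = \min(1, \#\{p_i > \lambda\} / (G(1-\lambda)))}
#' and assigns the i-th order statistic the q-value
#' \eqn{q_{(i)} = \min_{j \ge i} \hat\pi_0 \, G \, p_{(j)} / j},
#' capped at 1. Output is returned in the input order. The single-lambda
#' estimator (default \eqn{\lambda = 0.5}) is the classical plug-in; no
#' spline smoothing over a lambda grid is attempted.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\]
#' @param lambda tuning parameter in (0, 1); default 0.5
#' @return numeric vector of q-values, same order as `pvalues`
#' @examples
#' storey_qvalue(c(0.01, 0.2, 0.6, 0.8))
#' @export
storey_qvalue <- function(pvalues, lambda = 0.5) {
  if (length(pvalues) == 0) stop("empty p-value list")
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (length(lambda) != 1 || lambda <= 0 || lambda >= 1) {
    stop("lambda must be a single value in (0, 1)")
  }
  G <- length(pvalues)
  pi0 <- min(1, sum(pvalues > lambda) / (G * (1 - lambda)))
  ord <- order(pvalues)
  p_sorted <- pvalues[ord]
  raw <- pi0 * G * p_sorted / seq_len(G)
  q_sorted <- rev(cummin(rev(raw)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(G)
  q[ord] <- q_sorted
  q
}

#' Estimate the null proportion pi0 used by [storey_qvalue()]
#' @inheritParams storey_qvalue
#' @return scalar \eqn{\hat\pi_0} in \[0, 1\]
#' @export
storey_pi0 <- function(pvalues, lambda = 0.5) {
  if (length(pvalues) == 0) stop("empty p-value list")
  min(1, sum(pvalues > lambda) / (length(pvalues) * (1 - lambda)))
}
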