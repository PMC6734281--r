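#' Call differentially expressed genes between cases and controls
#'
#' Three model types mirror common reanalyses of public expression data:
#' \describe{
#'   \item{linear_covariates}{per-gene multivariate linear regression of
#'     expression on diagnosis plus covariates; p-value of the diagnosis
#'     coefficient (t-test).}
#'   \item{ttest}{per-gene Welch two-sample t-test, no covariates.}
#'   \item{logistic_covariates}{per-gene logistic regression of diagnosis
#'     on expression plus covariates; likelihood-ratio p-value for the
#'     expression term.}
#' }
#' Raw p-values are Benjamini-Hochberg adjusted across genes; a gene is a
#' DEG when the adjusted p is strictly below `alpha`. Direction is the
#' sign of the case-vs-control effect. Expression is assumed already on a
#' log-like scale; no normalization is applied.
#'
#' @param expr numeric matrix, genes x samples, rownames = gene ids
#' @param labels diagnosis per sample; coerced to factor
#' @param covariates optional `data.frame` of per-sample covariates
#' @param model one of "linear_covariates", "ttest", "logistic_covariates"
#' @param alpha FDR cutoff (default 0.05)
#' @param case_level which label level is the case group; default the
#'   last factor level
#' @param dataset,brain_region identifiers stamped on the result rows
#' @return `data.frame`: gene_id, dataset, brain_region,
#'   effect_direction, pvalue, padj, is_deg
#' @export
call_degs <- function(expr, labels, covariates = NULL,
                      model = c("linear_covariates", "ttest",
                                "logistic_covariates"),
                      alpha = 0.05, case_level = NULL,
                      dataset = "dataset", brain_region = "region") {
  model <- match.arg(model)
  if (ncol(expr) != length(labels)) stop("expr/labels dimension mismatch")
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("labels must have exactly two levels")
  if (is.null(case_level)) case_level <- levels(labels)[2]
  labels <- stats::relevel(labels, ref = setdiff(levels(labels), case_level))
  if (min(table(labels)) < 3) stop("need at least 3 samples per group")

  if (!is.null(covariates)) {
    cov_mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    X <- cbind(cov_mm, case = as.numeric(labels == case_level))
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient covariate design; collinear column(s): ",
           paste(drop_cols, collapse = ", "))
    }
  } else {
    X <- cbind("(Intercept)" = 1, case = as.numeric(labels == case_level))
  }

  constant <- apply(expr, 1, function(y) stats::var(y) == 0)
  if (any(constant)) {
    warning(sum(constant), " constant gene(s): p set to 1")
  }

  res <- switch(model,
    linear_covariates = deg_linear(expr, X),
    ttest = deg_ttest(expr, labels == case_level),
    logistic_covariates = deg_logistic(expr, labels == case_level,
                                       covariates))
  res$pvalue[constant] <- 1
  res$effect[constant] <- 0
  padj <- stats::p.adjust(res$pvalue, method = "BH")
  data.frame(gene_id = rownames(expr),
             dataset = dataset, brain_region = brain_region,
             effect_direction = sign(res$effect),
             pvalue = res$pvalue, padj = padj,
             is_deg = padj < alpha,
             stringsAsFactors = FALSE)
}

# vectorized OLS across genes with a shared design; t-test on the case
# coefficient
deg_linear <- function(expr, X) {
  n <- ncol(expr)
  p <- ncol(X)
  qrX <- qr(X)
  coefs <- t(qr.coef(qrX, t(expr)))          # genes x p
  fitted <- coefs %*% t(X)
  rss <- rowSums((expr - fitted)^2)
  sigma2 <- rss / (n - p)
  xtx_inv <- chol2inv(qr.R(qrX))
  j <- which(colnames(X) == "case")
  se <- sqrt(sigma2 * xtx_inv[j, j])
  tstat <- coefs[, j] / se
  pv <- 2 * stats::pt(-abs(tstat), df = n - p)
  pv[se == 0 | !is.finite(tstat)] <- 1
  list(pvalue = pv, effect = coefs[, j])
}

deg_ttest <- function(expr, is_case) {
  x <- expr[, is_case, drop = FALSE]
  y <- expr[, !is_case, drop = FALSE]
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (nx - 1)
  vy <- rowSums((y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  tstat <- (mx - my) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  pv <- 2 * stats::pt(-abs(tstat), df = df)
  pv[!is.finite(tstat)] <- 1
  list(pvalue = pv, effect = mx - my)
}

deg_logistic <- function(expr, is_case, covariates) {
  y <- as.numeric(is_case)
  base <- if (is.null(covariates)) {
    data.frame(y = y)
  } else {
    data.frame(y = y, as.data.frame(covariates))
  }
  pv <- numeric(nrow(expr))
  eff <- numeric(nrow(expr))
  fit0 <- stats::glm(y ~ ., data = base, family = stats::binomial())
  for (g in seq_len(nrow(expr))) {
    dat <- base
    dat$expr_g <- expr[g, ]
    fit1 <- suppressWarnings(
      stats::glm(y ~ ., data = dat, family = stats::binomial()))
    # LRT is robust where Wald collapses under quasi-separation
    pv[g] <- stats::pchisq(fit0$deviance - fit1$deviance, df = 1,
                           lower.tail = FALSE)
    eff[g] <- stats::coef(fit1)[["expr_g"]]
  }
  pv[!is.finite(pv)] <- 1
  list(pvalue = pv, effect = eff)
}
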