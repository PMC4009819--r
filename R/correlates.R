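# Assembly of the per-gene correlate table and partial correlations.

#' Assemble the per-gene table of protein-evolution correlates
#'
#' Inner-joins the per-gene outputs of the upstream stages and applies the
#' inclusion rules: genes are retained only when both dN and dS are
#' positive (so log(dN/dS) is defined and estimated with confidence) and
#' mean normalized expression reaches \code{minExpression}; genes missing
#' any variable are dropped by the join. Natural logs are used for
#' log(dN/dS) and log(expression); the base only shifts scales and does not
#' affect correlations.
#'
#' @param dnds data.frame with gene, dN, dS, ratio.
#' @param fst data.frame with gene, fst (per-gene mean FST).
#' @param pi data.frame with gene, pi.
#' @param specificity data.frame with gene, specificity.
#' @param exprLevel data.frame with gene, meanExpr (mean normalized
#'   expression over the pair's individuals).
#' @param divergence data.frame with gene, divergence (absolute log2
#'   expression ratio).
#' @param minExpression minimum mean normalized expression (default 14).
#' @return data.frame with gene, logDnds, fst, pi, specificity, logExpr,
#'   exprDivergence; errors when no gene survives.
#' @export
buildGeneTable <- function(dnds, fst, pi, specificity, exprLevel,
                           divergence, minExpression = 14) {
  d <- dnds[!is.na(dnds$dN) & !is.na(dnds$dS) &
              dnds$dN > 0 & dnds$dS > 0, c("gene", "ratio")]
  tab <- merge(d, fst[, c("gene", "fst")], by = "gene")
  tab <- merge(tab, pi[, c("gene", "pi")], by = "gene")
  tab <- merge(tab, specificity[, c("gene", "specificity")], by = "gene")
  tab <- merge(tab, exprLevel[, c("gene", "meanExpr")], by = "gene")
  tab <- merge(tab, divergence[, c("gene", "divergence")], by = "gene")
  tab <- tab[stats::complete.cases(tab) & tab$meanExpr >= minExpression, ]
  if (nrow(tab) == 0L) stop("no gene passes the correlate filters")
  data.frame(gene = tab$gene, logDnds = log(tab$ratio), fst = tab$fst,
             pi = tab$pi, specificity = tab$specificity,
             logExpr = log(tab$meanExpr), exprDivergence = tab$divergence,
             stringsAsFactors = FALSE)
}

#' Partial correlation matrix with p-values
#'
#' For every pair of variables, the correlation controlling for all
#' remaining k - 2 variables, via the precision matrix:
#' \code{r_ij = -Omega_ij / sqrt(Omega_ii Omega_jj)} with Omega the inverse
#' of the Pearson correlation matrix. Two-sided p-values come from
#' \code{t = r sqrt((n - 2 - g) / (1 - r^2))} with g = k - 2 controlled
#' variables and n - 2 - g degrees of freedom. With k = 2 this reduces to
#' the ordinary Pearson correlation and test.
#'
#' @param x numeric matrix or data.frame of observations x variables
#'   (non-numeric columns such as gene ids are dropped).
#' @param variables optional character vector selecting/ordering columns.
#' @return A \linkS4class{PartialCorrMatrix}.
#' @export
partialCorr <- function(x, variables = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x[vapply(x, is.numeric, TRUE)])
  if (!is.null(variables)) x <- x[, variables, drop = FALSE]
  k <- ncol(x); n <- nrow(x)
  if (k < 2L) stop("need at least two variables")
  if (n <= k + 2L) stop("need more observations than variables + 2")
  R <- cor(x)
  Omega <- tryCatch(solve(R), error = function(e) {
    off <- abs(R); diag(off) <- 0
    ij <- which(off == max(off), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "correlation matrix is singular (collinear pair: %s, %s)",
      colnames(R)[ij[1L]], colnames(R)[ij[2L]]), call. = FALSE)
  })
  dg <- diag(Omega)
  pr <- -Omega / sqrt(outer(dg, dg))
  diag(pr) <- 1
  g <- k - 2L
  df <- n - 2L - g
  tstat <- pr * sqrt(df / pmax(1 - pr^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  diag(p) <- NA_real_
  methods::new("PartialCorrMatrix", estimate = pr, p.value = p,
               n = as.integer(n), gp = as.integer(g))
}
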