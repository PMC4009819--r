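# Expression normalization, between-species divergence and tissue
# specificity.

#' Normalize an expression count matrix
#'
#' Each library (column) is divided by its median count over genes with at
#' least one read — a median over all genes could be zero for sparse
#' libraries — then each gene (row) is divided by its length in kb. The
#' result is scale-invariant per library: doubling every count of a library
#' leaves its normalized values unchanged.
#'
#' @param counts numeric matrix, genes x samples, raw read counts.
#' @param geneLengths numeric vector of gene lengths in bp, named by gene or
#'   aligned with the rows of \code{counts}.
#' @return numeric matrix of normalized expression values.
#' @export
normalizeExpression <- function(counts, geneLengths) {
  if (!is.null(names(geneLengths)) && !is.null(rownames(counts)))
    geneLengths <- geneLengths[rownames(counts)]
  if (length(geneLengths) != nrow(counts))
    stop("geneLengths must cover every gene")
  if (any(is.na(geneLengths)) || any(geneLengths <= 0))
    stop("gene lengths must be positive")
  med <- apply(counts, 2L, function(x) median(x[x > 0]))
  if (any(is.na(med))) {
    bad <- colnames(counts)[is.na(med)]
    stop("library with no positive counts: ", paste(bad, collapse = ", "))
  }
  sweep(counts, 2L, med, "/") / (geneLengths / 1000)
}

#' Between-group expression divergence per gene
#'
#' \code{|log2((mean1 + eps) / (mean2 + eps))|} with group means of
#' normalized expression and a pseudo-count \code{eps} guarding zero means.
#' With \code{eps = 0}, genes expressed in only one group yield \code{Inf},
#' flagged in the \code{infinite} column.
#'
#' @param normalized numeric matrix of normalized expression values
#'   (genes x samples).
#' @param groups character/factor vector of group labels per sample, or a
#'   named vector matched against the column names.
#' @param pair the two group labels to contrast (defaults to the first two
#'   levels present).
#' @param eps pseudo-count (default 0.5).
#' @return data.frame with gene, mean1, mean2, divergence, infinite.
#' @export
expressionDivergence <- function(normalized, groups,
                                 pair = unique(as.character(groups))[1:2],
                                 eps = 0.5) {
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[colnames(normalized)]
  m1 <- rowMeans(normalized[, groups == pair[1L], drop = FALSE])
  m2 <- rowMeans(normalized[, groups == pair[2L], drop = FALSE])
  v <- abs(log2((m1 + eps) / (m2 + eps)))
  data.frame(gene = rownames(normalized), mean1 = m1, mean2 = m2,
             divergence = v, infinite = is.infinite(v),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Tissue-specificity score per gene
#'
#' The number of tissue libraries in which a gene shows no evidence of
#' expression: the library count S minus the number of libraries with at
#' least one hit (range 0..S; 0 = expressed everywhere). Note that shallow
#' library sampling inflates specificity: lowly expressed genes may miss
#' hits in libraries where they are in fact expressed.
#'
#' @param hits numeric matrix, genes x libraries, of hit counts.
#' @return data.frame with gene and specificity.
#' @export
expressionSpecificity <- function(hits) {
  S <- ncol(hits)
  data.frame(gene = rownames(hits),
             specificity = S - as.integer(rowSums(hits >= 1)),
             stringsAsFactors = FALSE, row.names = NULL)
}
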