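#' Select the two site alleles from pooled base counts
#'
#' The two bases with the highest read counts pooled over all individuals
#' become the site alleles; ties are broken toward the alphabetically
#' smaller base. The site is rejected (returns \code{NULL}) when no reads
#' were observed, when only one base was observed (monomorphic), or when the
#' third-ranked base exceeds \code{thirdAlleleMaxFrac} of all reads
#' (likely multi-allelic artifact or collapsed paralog).
#'
#' @param pooled numeric vector of length 4 (A, C, G, T pooled counts).
#' @param thirdAlleleMaxFrac maximum tolerated pooled fraction of the
#'   third-ranked base.
#' @return character vector \code{c(alleleA, alleleB)} or \code{NULL}.
#' @export
selectSiteAlleles <- function(pooled, thirdAlleleMaxFrac = 0.05) {
  if (any(pooled < 0)) stop("negative base counts")
  tot <- sum(pooled)
  if (tot == 0) return(NULL)
  ord <- order(-pooled, BASES)  # count desc, base asc on ties
  if (pooled[ord[2L]] == 0) return(NULL)
  if (pooled[ord[3L]] > thirdAlleleMaxFrac * tot) return(NULL)
  BASES[ord[1:2]]
}

#' Call one genotype from a base-count quadruple
#'
#' Depth is counted over the two site alleles only; reads supporting other
#' bases are treated as sequencing error. A call is missing below
#' \code{minDepth}; heterozygous when the minor allele has at least
#' \code{minMinorReads} reads and a read fraction of at least \code{minMaf};
#' otherwise homozygous for the individual's major allele (allele A on an
#' exact tie).
#'
#' @param counts numeric vector of length 4 (A, C, G, T read counts).
#' @param alleles character vector \code{c(alleleA, alleleB)}.
#' @param config a \linkS4class{CallingConfig}.
#' @return integer B-allele count (0/1/2) or \code{NA} for missing.
#' @export
callGenotype <- function(counts, alleles, config = callingConfig()) {
  if (any(counts < 0)) stop("negative base counts")
  nA <- counts[match(alleles[1L], BASES)]
  nB <- counts[match(alleles[2L], BASES)]
  depth <- nA + nB
  if (depth < config@minDepth) return(NA_integer_)
  minor <- min(nA, nB)
  if (minor >= config@minMinorReads && minor / depth >= config@minMaf)
    return(1L)
  if (nB > nA) 2L else 0L
}

#' Per-site summaries of a genotype matrix
#'
#' @param geno integer matrix of B-allele counts (sites x individuals),
#'   values 0/1/2/NA.
#' @return data.frame with He (expected heterozygosity from the pooled
#'   allele frequency), Ho (observed heterozygote fraction among non-missing
#'   individuals) and missingFrac per site.
#' @export
siteSummary <- function(geno) {
  nonmiss <- rowSums(!is.na(geno))
  nInd <- ncol(geno)
  p <- 1 - rowSums(geno, na.rm = TRUE) / (2 * nonmiss)  # allele A frequency
  He <- 2 * p * (1 - p)
  Ho <- rowSums(geno == 1L, na.rm = TRUE) / nonmiss
  data.frame(He = He, Ho = Ho,
             missingFrac = 1 - nonmiss / nInd,
             row.names = rownames(geno))
}

#' Apply the per-site retention filters
#'
#' Retains sites with missing fraction at most \code{maxMissingFrac},
#' expected heterozygosity strictly above \code{minHe} and observed
#' heterozygosity strictly below \code{maxHo}. Monomorphic sites have
#' He = 0 and are dropped by the He rule. Idempotent; an empty input yields
#' an empty output.
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @param config a \linkS4class{CallingConfig}.
#' @return the filtered \linkS4class{GenotypeCalls}.
#' @export
filterSites <- function(x, config = callingConfig()) {
  if (nrow(x) == 0L) return(x)
  s <- siteSummary(genotypes(x))
  keep <- s$missingFrac <= config@maxMissingFrac &
    !is.na(s$He) & s$He > config@minHe &
    !is.na(s$Ho) & s$Ho < config@maxHo
  x[keep, ]
}

#' Genotype a site table
#'
#' Composes the full calling stage: per-site allele selection from pooled
#' counts, per-individual genotype calling, and site filtering. Sites
#' rejected at allele selection (no reads, monomorphic pools, excess third
#' allele) are dropped before calling. Deterministic.
#'
#' @param x a \linkS4class{SiteCounts} object.
#' @param config a \linkS4class{CallingConfig}.
#' @return A filtered \linkS4class{GenotypeCalls} object.
#' @export
genotypeSiteTable <- function(x, config = callingConfig()) {
  cnt <- lapply(BASES, function(b) SummarizedExperiment::assay(x, b))
  names(cnt) <- BASES
  nSite <- nrow(x)
  nInd <- ncol(x)
  pooled <- vapply(cnt, rowSums, numeric(nSite))
  if (nSite == 1L) pooled <- matrix(pooled, 1L, 4L, dimnames = list(NULL, BASES))
  alleles <- matrix(NA_character_, nSite, 2L)
  for (i in seq_len(nSite)) {
    al <- selectSiteAlleles(pooled[i, ], config@thirdAlleleMaxFrac)
    if (!is.null(al)) alleles[i, ] <- al
  }
  keep <- !is.na(alleles[, 1L])
  rr <- SummarizedExperiment::rowRanges(x)[keep]
  alleles <- alleles[keep, , drop = FALSE]
  idxA <- match(alleles[, 1L], BASES)
  idxB <- match(alleles[, 2L], BASES)
  ns <- sum(keep)
  nAmat <- matrix(0L, ns, nInd)
  nBmat <- matrix(0L, ns, nInd)
  whichKeep <- which(keep)
  for (b in 1:4) {
    rows <- idxA == b
    if (any(rows)) nAmat[rows, ] <- cnt[[b]][whichKeep[rows], , drop = FALSE]
    rows <- idxB == b
    if (any(rows)) nBmat[rows, ] <- cnt[[b]][whichKeep[rows], , drop = FALSE]
  }
  depth <- nAmat + nBmat
  minor <- pmin(nAmat, nBmat)
  geno <- ifelse(nBmat > nAmat, 2L, 0L)
  het <- minor >= config@minMinorReads & minor >= config@minMaf * depth
  geno[het] <- 1L
  geno[depth < config@minDepth] <- NA_integer_
  colnames(geno) <- colnames(x)
  gc <- GenotypeCalls(contig = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      alleleA = alleles[, 1L], alleleB = alleles[, 2L],
                      geno = geno, populations = .pops(x))
  filterSites(gc, config)
}
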