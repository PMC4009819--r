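# Weir & Cockerham (1984) variance components for diploid biallelic SNPs,
# plus per-gene diversity statistics and the Evanno deltaK.

# Vectorized W&C components over sites for one population pair.
# geno: matrix sites x individuals (0/1/2/NA); pop: per-individual labels;
# pair: two population names. Returns data.frame a, b, c, theta.
.wcComponents <- function(geno, pop, pair) {
  r <- 2
  g1 <- geno[, pop == pair[1L], drop = FALSE]
  g2 <- geno[, pop == pair[2L], drop = FALSE]
  n1 <- rowSums(!is.na(g1)); n2 <- rowSums(!is.na(g2))
  p1 <- 1 - rowSums(g1, na.rm = TRUE) / (2 * n1)
  p2 <- 1 - rowSums(g2, na.rm = TRUE) / (2 * n2)
  h1 <- rowSums(g1 == 1L, na.rm = TRUE) / n1
  h2 <- rowSums(g2 == 1L, na.rm = TRUE) / n2
  nsum <- n1 + n2
  nbar <- nsum / r
  nc <- (nsum - (n1^2 + n2^2) / nsum) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / nsum
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / nsum
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  tot <- a + b + cc
  theta <- ifelse(tot == 0, NA_real_, a / tot)
  bad <- n1 < 2 | n2 < 2
  theta[bad] <- NA_real_
  data.frame(a = a, b = b, c = cc, theta = theta,
             defined = !bad & tot != 0, row.names = rownames(geno))
}

#' Weir-Cockerham FST components at one SNP
#'
#' Computes the Weir & Cockerham (1984) variance components for a biallelic
#' SNP between two populations of diploids: \code{a} (among populations),
#' \code{b} (among individuals within populations), \code{c} (within
#' individuals), and the per-SNP estimator \code{theta = a/(a+b+c)}. The
#' estimator may be negative; it is undefined (NA, \code{defined = FALSE})
#' when the site is monomorphic in the pair or fewer than two individuals
#' per population are called.
#'
#' @param geno integer vector of B-allele counts (0/1/2/NA), one per
#'   individual.
#' @param pop character vector of population labels aligned with
#'   \code{geno}.
#' @param pair character vector of the two population labels to contrast.
#' @return one-row data.frame with a, b, c, theta, defined.
#' @export
wcFstSite <- function(geno, pop, pair = unique(pop)[1:2]) {
  .wcComponents(matrix(as.integer(geno), 1L), pop, pair)
}

#' Per-SNP FST for all sites of a genotype set
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @param pair two population labels present in \code{populations(x)}.
#' @return data.frame (one row per SNP) with contig, pos, a, b, c, theta,
#'   defined.
#' @export
snpFst <- function(x, pair) {
  pop <- .pops(x)
  if (!all(pair %in% pop)) stop("pair labels not found in populations")
  comp <- .wcComponents(genotypes(x), pop[colnames(x)], pair)
  cbind(siteAlleles(x)[, c("contig", "pos")], comp)
}

#' Per-gene mean FST
#'
#' The per-gene summary statistic: the arithmetic mean of defined
#' per-SNP theta values of the contig (undefined SNPs skipped). Genes with
#' no defined SNP get \code{NA}.
#'
#' @param fst data.frame from \code{\link{snpFst}}.
#' @return data.frame with gene, nSnps (defined SNPs) and fst.
#' @export
geneFst <- function(fst) {
  sp <- split(fst$theta[fst$defined], fst$contig[fst$defined])
  genes <- unique(fst$contig)
  mns <- vapply(sp, mean, numeric(1))
  data.frame(gene = genes,
             nSnps = as.integer(lengths(sp)[genes]),
             fst = unname(mns[genes]),
             stringsAsFactors = FALSE)
}

#' Multi-SNP ratio-of-sums FST
#'
#' The standard Weir-Cockerham multi-locus estimate
#' \code{sum(a) / sum(a + b + c)} over defined SNPs. Less biased than the
#' mean of per-SNP values and used for estimator-recovery checks.
#'
#' @param fst data.frame from \code{\link{snpFst}} (or any frame with
#'   columns a, b, c, defined).
#' @return single numeric FST estimate.
#' @export
fstRatioOfSums <- function(fst) {
  f <- fst[fst$defined, ]
  sum(f$a) / sum(f$a + f$b + f$c)
}

#' Nucleotide diversity of one gene
#'
#' Per-site unbiased heterozygosity summed over the gene's SNPs and divided
#' by gene length: \code{pi = sum_s [n_s/(n_s - 1)] 2 p_s (1 - p_s) / L},
#' where n_s is the number of non-missing allele copies at site s. This
#' equals the mean pairwise difference per site. Sites with fewer than two
#' called allele copies are skipped.
#'
#' @param geno integer matrix of B-allele counts (SNPs of one gene x
#'   individuals).
#' @param L gene length in bp.
#' @return list with pi, thetaW (see \code{\link{wattersonTheta}}; n is the
#'   median non-missing allele-copy count), S (SNPs used) and L.
#' @export
piGene <- function(geno, L) {
  if (L <= 0) stop("gene length must be positive")
  if (is.null(dim(geno))) geno <- matrix(as.integer(geno), 1L)
  n <- 2 * rowSums(!is.na(geno))
  ok <- n >= 2
  p <- 1 - rowSums(geno, na.rm = TRUE)[ok] / n[ok]
  pi <- sum(n[ok] / (n[ok] - 1) * 2 * p * (1 - p)) / L
  S <- sum(p > 0 & p < 1)
  nmed <- if (any(ok)) median(n[ok]) else 0
  list(pi = pi,
       thetaW = if (nmed >= 2) wattersonTheta(S, nmed, L) else NA_real_,
       S = as.integer(S), L = L)
}

#' Watterson's theta
#'
#' \code{theta_w = S / (a_{n-1} L)} with \code{a_{n-1} = sum_{i<n} 1/i},
#' the segregating-sites diversity estimator per site.
#'
#' @param S number of segregating sites.
#' @param n number of sampled allele copies (>= 2).
#' @param L sequence length in bp.
#' @return single numeric value.
#' @export
wattersonTheta <- function(S, n, L) {
  if (n < 2) stop("need at least two allele copies")
  if (L <= 0) stop("length must be positive")
  S / (sum(1 / seq_len(n - 1)) * L)
}

#' Per-gene diversity and differentiation table
#'
#' Convenience wrapper computing, for every contig with SNPs, the per-gene
#' mean FST for a population pair together with pi and Watterson's theta
#' over the pair's individuals.
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @param pair two population labels.
#' @param lengths named numeric vector of contig lengths (bp).
#' @return data.frame with gene, nSnps, fst, pi, thetaW.
#' @export
geneDiversity <- function(x, pair, lengths) {
  fst <- snpFst(x, pair)
  gf <- geneFst(fst)
  pop <- .pops(x)[colnames(x)]
  g <- genotypes(x)[, pop %in% pair, drop = FALSE]
  contig <- fst$contig
  div <- lapply(unique(contig), function(ct) {
    L <- lengths[[ct]]
    if (is.null(L) || is.na(L)) return(c(pi = NA_real_, thetaW = NA_real_))
    d <- piGene(g[contig == ct, , drop = FALSE], L)
    c(pi = d$pi, thetaW = d$thetaW)
  })
  div <- do.call(rbind, div)
  out <- data.frame(gene = unique(contig), div, stringsAsFactors = FALSE)
  merge(gf, out, by = "gene", sort = TRUE)
}

#' Evanno deltaK from replicate clustering log-likelihoods
#'
#' For each interior K, \code{deltaK = mean(|L''(K)|) / sd(L(K))} where the
#' second difference \code{L''(K) = L(K+1) - 2 L(K) + L(K-1)} is taken per
#' replicate run and L(K) are the replicate log-likelihoods at K. Endpoints
#' are undefined, as is any K whose replicate standard deviation is zero
#' (flagged NA).
#'
#' @param lnp data.frame with columns \code{K} (integer) and \code{lnP}
#'   (replicate log-likelihood); equal replicate counts per K, consecutive
#'   K values, at least 3 K values and 2 replicates.
#' @return data.frame with K, meanLnP, sdLnP, deltaK (NA at endpoints and
#'   degenerate K).
#' @export
deltaK <- function(lnp) {
  names(lnp)[1:2] <- c("K", "lnP")
  ks <- sort(unique(lnp$K))
  if (length(ks) < 3L) stop("need at least three consecutive K values")
  if (!all(diff(ks) == 1L)) stop("K values must be consecutive")
  reps <- split(lnp$lnP, lnp$K)
  nrep <- lengths(reps)
  if (any(nrep < 2L)) stop("need at least two replicates per K")
  if (length(unique(nrep)) != 1L)
    stop("replicate counts must be equal across K")
  M <- do.call(cbind, reps)             # replicates x K
  mn <- colMeans(M)
  sdv <- apply(M, 2L, sd)
  dK <- rep(NA_real_, length(ks))
  for (j in seq(2L, length(ks) - 1L)) {
    if (sdv[j] > 0)
      dK[j] <- mean(abs(M[, j + 1L] - 2 * M[, j] + M[, j - 1L])) / sdv[j]
  }
  data.frame(K = ks, meanLnP = unname(mn), sdLnP = unname(sdv), deltaK = dK)
}

#' SNP density per 100 bp
#'
#' @param nSnps number of polymorphic sites.
#' @param totalBp total length surveyed in bp.
#' @return SNPs per 100 bp.
#' @export
snpDensityPer100bp <- function(nSnps, totalBp) 100 * nSnps / totalBp
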