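# Independent oracles and small fixture builders shared across tests.

# Brute-force nucleotide diversity: mean pairwise difference per site over
# all pairs of allele copies, enumerated explicitly.
bruteForcePi <- function(geno, L) {
  total <- 0
  for (i in seq_len(nrow(geno))) {
    g <- geno[i, ]
    copies <- integer(0)
    for (d in g[!is.na(g)]) copies <- c(copies, switch(d + 1L, c(0L, 0L),
                                                       c(0L, 1L), c(1L, 1L)))
    n <- length(copies)
    if (n < 2) next
    diffs <- 0
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      diffs <- diffs + (copies[a] != copies[b])
    total <- total + diffs / choose(n, 2)
  }
  total / L
}

# Independent likelihood-ratio G via the entropy decomposition
# G = 2 (sum O log O - sum rowsums log rowsums - sum colsums log colsums
#        + N log N), zero cells contributing zero.
entropyG <- function(Pn, Ps, Dn, Ds) {
  O <- matrix(c(Pn, Ps, Dn, Ds), 2, 2, byrow = TRUE)
  xlx <- function(x) sum(ifelse(x > 0, x * log(x), 0))
  2 * (xlx(O) - xlx(rowSums(O)) - xlx(colSums(O)) + xlx(sum(O)))
}

# First-order recursive partial correlation for three variables:
# r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))
recursivePartial <- function(x, y, z) {
  rxy <- cor(x, y); rxz <- cor(x, z); ryz <- cor(y, z)
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

# Data matrix whose sample correlation matrix is exactly R (n rows).
exactCorrData <- function(n, R, seed = 1) {
  set.seed(seed)
  k <- ncol(R)
  Z <- matrix(rnorm(n * k), n, k)
  Z <- scale(Z, center = TRUE, scale = FALSE)
  Z <- Z %*% solve(chol(cov(Z)))          # exactly whitened
  X <- Z %*% chol(R)
  colnames(X) <- colnames(R) %||% paste0("v", seq_len(k))
  X
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent NG86 synonymous-site count for one sequence, using
# Biostrings translation over all nine single-base mutations per codon
# (stop-producing mutations nonsynonymous).
oracleSynSites <- function(s) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(s) %/% 3
  tot <- 0
  aaOf <- function(cod)   # no.init.codon: never read as an initiator
    as.character(Biostrings::translate(Biostrings::DNAString(cod),
                                       no.init.codon = TRUE))
  for (i in seq_len(n)) {
    cod <- substr(s, 3 * i - 2, 3 * i)
    if (cod %in% stops) next
    aa0 <- aaOf(cod)
    for (p in 1:3) for (b in setdiff(c("A", "C", "G", "T"),
                                     substr(cod, p, p))) {
      mut <- cod
      substr(mut, p, p) <- b
      if (mut %in% stops) next
      if (aaOf(mut) == aa0) tot <- tot + 1 / 3
    }
  }
  tot
}

# Independent 2x2 likelihood-ratio statistic via iterative proportional
# fitting of the independence log-linear model.
loglmG <- function(Pn, Ps, Dn, Ds) {
  O <- matrix(c(Pn, Ps, Dn, Ds), 2, 2, byrow = TRUE,
              dimnames = list(c("poly", "fixed"), c("nonsyn", "syn")))
  as.numeric(MASS::loglm(~ 1 + 2, O)$lrt)
}

# Small GenotypeCalls built from an explicit dose matrix.
makeCalls <- function(geno, pops, contig = "c1",
                      pos = seq_len(nrow(geno)) * 10L,
                      alleleA = "A", alleleB = "G") {
  if (is.null(colnames(geno)))
    colnames(geno) <- sprintf("i%02d", seq_len(ncol(geno)))
  if (is.null(names(pops))) names(pops) <- colnames(geno)
  n <- nrow(geno)
  GenotypeCalls(contig = rep(contig, length.out = n),
                pos = pos,
                alleleA = rep(alleleA, length.out = n),
                alleleB = rep(alleleB, length.out = n),
                geno = geno, populations = pops)
}

# Site-count container for one site from per-individual quadruples.
makeSiteCounts <- function(quads, pops, contig = "c1", pos = 1L,
                           ref = "A") {
  nInd <- length(quads)
  ind <- sprintf("i%02d", seq_len(nInd))
  if (is.null(names(pops))) names(pops) <- ind
  counts <- lapply(1:4, function(b)
    matrix(vapply(quads, `[`, 0L, b), 1L, nInd, dimnames = list(NULL, ind)))
  names(counts) <- c("A", "C", "G", "T")
  SiteCounts(contig = contig, pos = pos, ref = ref, counts = counts,
             populations = pops)
}

# Random coding sequence (stop-free in frame 0) of nCodons.
randomCds <- function(nCodons) {
  stops <- c("TAA", "TAG", "TGA")
  pool <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                            c("A","C","G","T"), stringsAsFactors = FALSE),
                1, paste0, collapse = "")
  pool <- setdiff(pool, stops)
  paste(sample(pool, nCodons, replace = TRUE), collapse = "")
}
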