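# Seeded generators reproducing the statistical structure of every pipeline
# input: Balding-Nichols genotypes, pileup-like base counts, MK count
# tables with a planted adaptive fraction, negative-binomial expression and
# transcriptomes with planted open reading frames.

#' Simulate diploid genotypes under the Balding-Nichols model
#'
#' Ancestral minor-allele frequencies are Uniform(0.05, 0.5); each
#' population draws its frequency from
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so the expected differentiation equals the
#' target FST; diploid genotypes are binomial in the population frequency.
#' Sites are organised into genes (contigs \code{gene_0001}, ...), SNPs
#' spaced \code{spacing} bp apart.
#'
#' @param nPops number of populations.
#' @param nPerPop diploid individuals per population.
#' @param nGenes number of genes (contigs).
#' @param snpsPerGene SNPs per gene.
#' @param targetFst target differentiation F in (0, 1).
#' @param seed RNG seed.
#' @param spacing bp between consecutive SNPs of a gene (default 30).
#' @return A \linkS4class{GenotypeCalls} object; the simulation truth
#'   (population allele frequencies, ancestral frequencies, target FST) is
#'   stored in \code{metadata(x)$truth}.
#' @export
simulateGenotypes <- function(nPops = 2L, nPerPop = 15L, nGenes = 100L,
                              snpsPerGene = 50L, targetFst = 0.25,
                              seed = 1L, spacing = 30L) {
  if (targetFst <= 0 || targetFst >= 1) stop("targetFst must be in (0,1)")
  set.seed(seed)
  nSnp <- nGenes * snpsPerGene
  nInd <- nPops * nPerPop
  p <- runif(nSnp, 0.05, 0.5)                     # ancestral B-allele freq
  Fst <- targetFst
  shape <- (1 - Fst) / Fst
  pf <- matrix(rbeta(nSnp * nPops, rep(p * shape, nPops),
                     rep((1 - p) * shape, nPops)), nSnp, nPops)
  geno <- matrix(NA_integer_, nSnp, nInd)
  pops <- rep(paste0("pop", seq_len(nPops)), each = nPerPop)
  for (k in seq_len(nPops)) {
    cols <- which(pops == paste0("pop", k))
    geno[, cols] <- rbinom(nSnp * nPerPop, 2L, rep(pf[, k], nPerPop))
  }
  ind <- sprintf("ind_%02d", seq_len(nInd))
  colnames(geno) <- ind
  alleles <- t(vapply(seq_len(nSnp),
                      function(i) sample(BASES, 2L), character(2L)))
  contig <- rep(sprintf("gene_%04d", seq_len(nGenes)), each = snpsPerGene)
  pos <- rep(spacing * (seq_len(snpsPerGene) - 1L) + 1L, nGenes)
  gc <- GenotypeCalls(contig = contig, pos = pos,
                      alleleA = alleles[, 1L], alleleB = alleles[, 2L],
                      geno = geno, populations = setNames(pops, ind))
  S4Vectors::metadata(gc)$truth <-
    list(ancestralFreq = p, popFreq = pf, targetFst = targetFst,
         seed = seed)
  gc
}

#' Simulate pileup-like base counts from genotypes
#'
#' Per individual and site, read depth is Poisson(\code{meanDepth}); reads
#' draw the B allele binomially with probability dose/2; each read is
#' miscalled with probability \code{errorRate}, substituting one of the
#' other three bases uniformly.
#'
#' @param x a \linkS4class{GenotypeCalls} object (missing genotypes produce
#'   zero-depth cells).
#' @param meanDepth mean read depth per site and individual.
#' @param errorRate per-read miscall probability (0 to 0.1).
#' @param seed RNG seed.
#' @return A \linkS4class{SiteCounts} object.
#' @export
simulatePileups <- function(x, meanDepth = 25, errorRate = 0.005,
                            seed = 1L) {
  if (meanDepth <= 0) stop("meanDepth must be positive")
  if (errorRate < 0 || errorRate > 0.1) stop("errorRate must be in [0, 0.1]")
  set.seed(seed)
  g <- genotypes(x)
  al <- siteAlleles(x)
  nS <- nrow(g); nI <- ncol(g)
  cnt <- lapply(BASES, function(b) matrix(0L, nS, nI))
  names(cnt) <- BASES
  depth <- matrix(rpois(nS * nI, meanDepth), nS, nI)
  depth[is.na(g)] <- 0L
  dose <- g; dose[is.na(dose)] <- 0L
  nB <- matrix(rbinom(nS * nI, depth, dose / 2), nS, nI)
  nA <- depth - nB
  idxA <- match(al$alleleA, BASES)
  idxB <- match(al$alleleB, BASES)
  addReads <- function(cnt, nReads, baseIdx) {
    # correct reads stay on their base; errors go uniformly to the others
    err <- matrix(rbinom(nS * nI, nReads, errorRate), nS, nI)
    keep <- nReads - err
    for (b in 1:4) {
      rows <- baseIdx == b
      if (any(rows)) cnt[[b]][rows, ] <- cnt[[b]][rows, ] +
          keep[rows, , drop = FALSE]
    }
    if (errorRate > 0) {
      # split err reads across the three other bases
      e1 <- matrix(rbinom(nS * nI, err, 1 / 3), nS, nI)
      e2 <- matrix(rbinom(nS * nI, err - e1, 1 / 2), nS, nI)
      e3 <- err - e1 - e2
      others <- lapply(1:4, function(b) setdiff(1:4, b))
      for (b in 1:4) {
        rows <- baseIdx == b
        if (!any(rows)) next
        ob <- others[[b]]
        cnt[[ob[1L]]][rows, ] <- cnt[[ob[1L]]][rows, ] + e1[rows, , drop = FALSE]
        cnt[[ob[2L]]][rows, ] <- cnt[[ob[2L]]][rows, ] + e2[rows, , drop = FALSE]
        cnt[[ob[3L]]][rows, ] <- cnt[[ob[3L]]][rows, ] + e3[rows, , drop = FALSE]
      }
    }
    cnt
  }
  cnt <- addReads(cnt, nA, idxA)
  cnt <- addReads(cnt, nB, idxB)
  for (b in 1:4) colnames(cnt[[b]]) <- colnames(g)
  SiteCounts(contig = al$contig, pos = al$pos,
             ref = al$alleleA, counts = cnt, populations = .pops(x))
}

#' Simulate per-gene McDonald-Kreitman counts with a planted alpha
#'
#' Per gene: \code{Ps ~ Pois(lambdaP)}, \code{Pn ~ Pois(r lambdaP)},
#' \code{Ds ~ Pois(muD)} and
#' \code{Dn ~ Pois(r muD) + Pois(r muD a/(1-a))} where \code{a} is the
#' adaptive fraction; the expected genome-wide alpha equals \code{a}.
#' Polymorphism defaults echo the per-gene scale of a deep two-species
#' transcriptome comparison (about 12 synonymous polymorphisms per gene,
#' Pn/Ps near 0.7); the divergence mean is set so that a 2,000-gene sample
#' determines alpha to about +/- 0.02 (one standard error) — divergence
#' counts are the binding constraint on the estimator's precision.
#'
#' @param nGenes number of genes.
#' @param lambdaP mean synonymous polymorphism count per gene.
#' @param ratioR nonsynonymous/synonymous rate ratio.
#' @param muD mean synonymous substitution count per gene.
#' @param adaptiveFrac planted adaptive fraction in [0, 1).
#' @param seed RNG seed.
#' @return list with \code{counts} (data.frame gene, Pn, Ps, Dn, Ds) and
#'   \code{truth} (the parameters).
#' @export
simulateMkGenes <- function(nGenes = 2000L, lambdaP = 12, ratioR = 0.7,
                            muD = 3, adaptiveFrac = 0, seed = 1L) {
  if (adaptiveFrac < 0 || adaptiveFrac >= 1)
    stop("adaptiveFrac must be in [0, 1)")
  set.seed(seed)
  counts <- data.frame(
    gene = sprintf("gene_%04d", seq_len(nGenes)),
    Pn = rpois(nGenes, ratioR * lambdaP),
    Ps = rpois(nGenes, lambdaP),
    Dn = rpois(nGenes, ratioR * muD) +
      rpois(nGenes, ratioR * muD * adaptiveFrac / (1 - adaptiveFrac)),
    Ds = rpois(nGenes, muD),
    stringsAsFactors = FALSE)
  list(counts = counts,
       truth = list(alpha = adaptiveFrac, lambdaP = lambdaP,
                    ratioR = ratioR, muD = muD, seed = seed))
}

#' Simulate an overdispersed expression count matrix
#'
#' Negative-binomial counts with lognormal baseline means, uniform library
#' size factors and per-gene, per-group log2 offsets with standard
#' deviation \code{lfcSd} (the pairwise log2 fold change between two groups
#' then has standard deviation \code{sqrt(2) lfcSd}; the first group is the
#' reference with offset 0).
#'
#' @param nGenes number of genes.
#' @param groups character/factor of group labels, one per sample; sample
#'   names are taken from its names when present.
#' @param sizeFactorRange range of the uniform library size factors.
#' @param dispersion negative-binomial dispersion (size = 1/dispersion).
#' @param lfcSd standard deviation of the per-group log2 offsets.
#' @param seed RNG seed.
#' @param meanLog,sdLog lognormal parameters of the baseline means.
#' @return list with \code{counts} (genes x samples matrix),
#'   \code{geneLengths} (bp) and \code{truth} (baseMean, per-group log2
#'   offsets, size factors).
#' @export
simulateExpression <- function(nGenes = 1000L, groups, sizeFactorRange = c(0.5, 2),
                               dispersion = 0.1, lfcSd = 0, seed = 1L,
                               meanLog = log(50), sdLog = 1.2) {
  set.seed(seed)
  nS <- length(groups)
  samples <- if (!is.null(names(groups))) names(groups)
             else sprintf("s%02d", seq_len(nS))
  groups <- as.character(groups)
  glev <- unique(groups)
  base <- rlnorm(nGenes, meanLog, sdLog)
  offs <- matrix(0, nGenes, length(glev), dimnames = list(NULL, glev))
  if (length(glev) > 1L && lfcSd > 0)
    offs[, -1L] <- rnorm(nGenes * (length(glev) - 1L), 0, lfcSd)
  sf <- runif(nS, sizeFactorRange[1L], sizeFactorRange[2L])
  lens <- round(runif(nGenes, 500, 2500))
  mu <- base * 2^offs[, groups, drop = FALSE] *
    rep(sf, each = nGenes) * (lens / 1000)
  counts <- matrix(rnbinom(nGenes * nS, mu = mu, size = 1 / dispersion),
                   nGenes, nS,
                   dimnames = list(sprintf("gene_%04d", seq_len(nGenes)),
                                   samples))
  names(lens) <- rownames(counts)
  list(counts = counts, geneLengths = lens,
       truth = list(baseMean = base, log2Offsets = offs, sizeFactors = sf,
                    dispersion = dispersion, seed = seed))
}

.randomCodons <- function(n, stopFree = TRUE) {
  pool <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                1L, paste0, collapse = "")
  if (stopFree) pool <- setdiff(pool, STOP_CODONS)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

.randomBases <- function(n) paste(sample(BASES, n, replace = TRUE),
                                  collapse = "")

# Inject stop codons until no stop-free run >= minLen would displace the
# protected forward-frame interval [ps, pe] from the top of the finder's
# ordering (with ps = NA: until no qualifying run remains at all). Returns
# the repaired string, or NULL when an offending run cannot be disrupted
# without touching the protected interval.
.disruptOrfs <- function(s, minLen, ps = NA, pe = NA) {
  plen <- if (!is.na(ps)) pe - ps + 1L else NA
  for (iter in 1:100) {
    runs <- .allRuns(s, minLen)
    if (is.na(ps)) {
      if (nrow(runs) == 0L) return(s)
      off <- runs[1L, ]
    } else {
      isPlanted <- runs$start == ps & runs$end == pe & runs$strand == "+"
      # a run beats the planted one (+ strand, frame 0, start ps) when it
      # is longer, or equal length with frame 0 on + and an earlier start
      beats <- (runs$length > plen) |
        (runs$length == plen & runs$strand == "+" & runs$frame == 0L &
           runs$start < ps)
      beats[isPlanted] <- FALSE
      if (!any(beats)) return(s)
      off <- runs[which(beats)[1L], ]
    }
    starts <- seq(off$start, off$end - 2L, by = 3L)
    if (!is.na(ps)) starts <- starts[starts + 2L < ps | starts > pe]
    if (!length(starts)) return(NULL)
    at <- starts[ceiling(length(starts) / 2)]
    substr(s, at, at + 2L) <- if (off$strand == "+") "TAA" else "TTA"
  }
  NULL
}

#' Simulate a reference transcriptome with planted ORFs
#'
#' A fraction \code{orfFrac} of contigs carries a planted stop-free reading
#' frame of at least \code{minLen} nucleotides at recorded coordinates
#' (frame 0, forward strand, flanked by in-frame stop codons); all other
#' stop-free runs of qualifying length, in any of the six frames, are
#' disrupted, so the ORF finder recovers the planted coordinates exactly.
#' The remaining contigs are repaired so that no frame holds a qualifying
#' run at all.
#'
#' @param nGenes number of contigs.
#' @param orfFrac fraction of contigs with a planted ORF.
#' @param lengthRange contig length range in bp.
#' @param seed RNG seed.
#' @param minLen minimum ORF length (default 300).
#' @return list with \code{sequences} (named
#'   \link[Biostrings]{DNAStringSet}) and \code{orfs} (data.frame gene,
#'   start, end, strand, frame for planted ORFs; contigs without one are
#'   absent).
#' @export
simulateTranscriptome <- function(nGenes = 100L, orfFrac = 0.75,
                                  lengthRange = c(500, 1600), seed = 1L,
                                  minLen = 300L) {
  set.seed(seed)
  hasOrf <- seq_len(nGenes) <= round(orfFrac * nGenes)
  seqs <- character(nGenes)
  planted <- vector("list", nGenes)
  for (i in seq_len(nGenes)) {
    repeat {
      L <- round(runif(1L, lengthRange[1L], lengthRange[2L]))
      if (hasOrf[i]) {
        maxCod <- (L - 6L) %/% 3L - 2L
        nCod <- minLen %/% 3L +
          sample.int(max(1L, maxCod - minLen %/% 3L), 1L) - 1L
        nCod <- min(nCod, maxCod)
        orfLen <- 3L * nCod
        slack <- L - orfLen - 6L
        lead <- sample.int(slack + 1L, 1L) - 1L
        lead <- lead - lead %% 3L  # keep planted run in frame 0
        s <- paste0(.randomBases(lead), "TAA", .randomCodons(nCod),
                    "TAA", .randomBases(L - lead - orfLen - 6L))
        ps <- lead + 4L
        pe <- lead + 3L + orfLen
        s2 <- .disruptOrfs(s, minLen, ps, pe)
        if (!is.null(s2)) {
          o <- findOrf(s2, minLen)
          if (!is.null(o) && o$start == ps && o$end == pe &&
              o$strand == "+") {
            seqs[i] <- s2
            planted[[i]] <- data.frame(
              gene = sprintf("gene_%04d", i), start = ps, end = pe,
              strand = "+", frame = (ps - 1L) %% 3L,
              length = orfLen, stringsAsFactors = FALSE)
            break
          }
        }
      } else {
        s <- .randomBases(L)
        s2 <- .disruptOrfs(s, minLen)
        if (!is.null(s2)) { seqs[i] <- s2; break }
      }
    }
  }
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- sprintf("gene_%04d", seq_len(nGenes))
  orfs <- do.call(rbind, planted)
  list(sequences = dss, orfs = orfs)
}

#' Configuration of the bundled small study fixture
#'
#' Study conditions mirroring the scale of the transcriptome study the
#' pipeline models, shrunk to desk size: three diverged populations of
#' eight diploids, 200 contigs with about 3 candidate SNPs per 100 bp,
#' pairwise differentiation near 0.25 and median read depth near 25.
#'
#' @param nGenes number of contigs (default 200).
#' @return named list of generator and pipeline parameters.
#' @export
smallFixtureConfig <- function(nGenes = 200L) {
  list(nPops = 3L, nPerPop = 8L, nGenes = as.integer(nGenes),
       snpRate = 0.03, targetFst = 0.25, meanDepth = 25, errorRate = 0.005,
       orfFrac = 0.8, lengthRange = c(500, 1600), minOrfLen = 300L,
       expressionMeanLog = log(80), expressionSdLog = 1.6,
       dispersion = 0.15, lfcSd = 0.4, nLibraries = 11L,
       fstThreshold = 0.9, minGenes = 50L, B = 1000L,
       minExpression = 0.5, epsilon = 0.5)
}

#' Simulate a complete study input bundle on disk
#'
#' Generates every on-disk artifact the pipeline consumes — reference
#' transcriptome FASTA, per-site base-count table, population map,
#' expression count matrix, tissue-library hit matrix, gene-to-GO map and a
#' clustering log-likelihood table — from one seed, and records the
#' simulation truth. Candidate SNP sites are placed uniformly along each
#' contig at \code{snpRate} per bp with Balding-Nichols population
#' frequencies at the configured differentiation; base counts follow the
#' pileup model of \code{\link{simulatePileups}}.
#'
#' @param dir output directory (created if needed).
#' @param config list from \code{\link{smallFixtureConfig}} (or a modified
#'   copy).
#' @param seed RNG seed; every generated file is a pure function of
#'   (config, seed).
#' @return invisibly, a named list of the file paths plus the truth list.
#' @export
simulateStudy <- function(dir, config = smallFixtureConfig(), seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tx <- simulateTranscriptome(config$nGenes, config$orfFrac,
                              config$lengthRange, seed = seed + 1L,
                              minLen = config$minOrfLen)
  lens <- Biostrings::width(tx$sequences)
  names(lens) <- names(tx$sequences)
  nInd <- config$nPops * config$nPerPop
  ind <- sprintf("ind_%02d", seq_len(nInd))
  pops <- setNames(rep(sprintf("species%d", seq_len(config$nPops)),
                       each = config$nPerPop), ind)
  # SNP sites along each contig
  set.seed(seed + 2L)
  contig <- character(0); pos <- integer(0)
  for (g in names(tx$sequences)) {
    nSnp <- max(1L, rpois(1L, config$snpRate * lens[[g]]))
    pos <- c(pos, sort(sample.int(lens[[g]], min(nSnp, lens[[g]]))))
    contig <- c(contig, rep(g, min(nSnp, lens[[g]])))
  }
  nSnp <- length(pos)
  refBase <- substring(as.character(tx$sequences[contig]), pos, pos)
  altBase <- vapply(refBase, function(b) sample(setdiff(BASES, b), 1L), "")
  shape <- (1 - config$targetFst) / config$targetFst
  p <- runif(nSnp, 0.05, 0.5)
  pf <- matrix(rbeta(nSnp * config$nPops, rep(p * shape, config$nPops),
                     rep((1 - p) * shape, config$nPops)),
               nSnp, config$nPops)
  geno <- matrix(NA_integer_, nSnp, nInd, dimnames = list(NULL, ind))
  for (k in seq_len(config$nPops)) {
    cols <- which(pops == sprintf("species%d", k))
    geno[, cols] <- rbinom(nSnp * config$nPerPop, 2L,
                           rep(pf[, k], config$nPerPop))
  }
  gcTruth <- GenotypeCalls(contig = contig, pos = pos, alleleA = refBase,
                           alleleB = altBase, geno = geno,
                           populations = pops)
  sc <- simulatePileups(gcTruth, config$meanDepth, config$errorRate,
                        seed = seed + 3L)
  # overwrite ref metadata with the actual reference base
  SummarizedExperiment::rowRanges(sc)$ref <- refBase
  # expression counts over the same genes and individuals
  expr <- simulateExpression(config$nGenes, groups = pops,
                             dispersion = config$dispersion,
                             lfcSd = config$lfcSd, seed = seed + 4L,
                             meanLog = config$expressionMeanLog,
                             sdLog = config$expressionSdLog)
  rownames(expr$counts) <- names(tx$sequences)
  # tissue-library hits scale with baseline expression
  set.seed(seed + 5L)
  lam <- outer(expr$truth$baseMean / mean(expr$truth$baseMean),
               runif(config$nLibraries, 0.3, 1.5))
  hits <- matrix(rpois(length(lam), lam), nrow(lam),
                 dimnames = list(names(tx$sequences),
                                 sprintf("lib%02d", seq_len(config$nLibraries))))
  # GO map: categories large enough for the category scan
  set.seed(seed + 6L)
  goIds <- sprintf("GO:%07d", 1:6)
  goDesc <- c("defense response", "flower development", "glycolysis",
              "lipid metabolic process", "translation", "transport")
  goRows <- do.call(rbind, lapply(seq_along(goIds), function(j) {
    members <- sample(names(tx$sequences),
                      min(config$nGenes,
                          max(config$minGenes + 10L, config$nGenes %/% 3L)))
    data.frame(gene = members, go = goIds[j], description = goDesc[j],
               stringsAsFactors = FALSE)
  }))
  # clustering log-likelihood replicates peaking at the true K
  set.seed(seed + 7L)
  kTrue <- config$nPops
  ks <- 1:(kTrue + 2L)
  base <- -5000 + 900 * pmin(ks, kTrue) + 15 * pmax(ks - kTrue, 0)
  lnp <- do.call(rbind, lapply(seq_along(ks), function(j)
    data.frame(K = ks[j], replicate = 1:10,
               lnP = base[j] + rnorm(10, 0, 5))))
  paths <- list(
    fasta = file.path(dir, "transcriptome.fasta"),
    sites = file.path(dir, "sites.tsv"),
    pops = file.path(dir, "pops.tsv"),
    expression = file.path(dir, "expression_counts.tsv"),
    libhits = file.path(dir, "est_hits.tsv"),
    goMap = file.path(dir, "go_map.tsv"),
    lnp = file.path(dir, "lnp.tsv"))
  Biostrings::writeXStringSet(tx$sequences, paths$fasta)
  writeSiteTable(sc, paths$sites)
  write.table(data.frame(individual = ind, population = unname(pops)),
              paths$pops, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  write.table(cbind(gene = rownames(expr$counts), as.data.frame(expr$counts)),
              paths$expression, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(gene = rownames(hits), as.data.frame(hits)),
              paths$libhits, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(goRows, paths$goMap, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(lnp, paths$lnp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, list(truth = list(
    genotypes = gcTruth, popFreq = pf, plantedOrfs = tx$orfs,
    expression = expr$truth, seed = seed, config = config))))
}
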