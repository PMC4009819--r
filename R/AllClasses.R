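#' @import methods
#' @importFrom stats cor median pchisq pnorm pt quantile rbeta rbinom rlnorm
#'   rmultinom rnbinom rnorm rpois runif sd setNames var
#' @importFrom utils read.delim write.table packageVersion head
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowRanges
#' @importFrom S4Vectors DataFrame metadata mcols
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
NULL

BASES <- c("A", "C", "G", "T")

#' Per-site, per-individual base counts
#'
#' \code{SiteCounts} holds the pileup-like substrate of the pipeline: for every
#' candidate site (a position on a reference contig) and every sequenced
#' individual, the number of reads supporting each of the four nucleotides.
#' It extends \link[SummarizedExperiment]{RangedSummarizedExperiment} with one
#' integer assay per base (\code{"A"}, \code{"C"}, \code{"G"}, \code{"T"}),
#' row ranges giving contig and 1-based position (with a \code{ref} metadata
#' column for the reference base), and a \code{population} column in
#' \code{colData}.
#'
#' @slot ... see \link[SummarizedExperiment]{RangedSummarizedExperiment}.
#' @export
setClass("SiteCounts", contains = "RangedSummarizedExperiment")

setValidity("SiteCounts", function(object) {
  msg <- NULL
  if (!all(BASES %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assays 'A','C','G','T' are required")
  else {
    for (b in BASES) {
      a <- SummarizedExperiment::assay(object, b)
      if (any(a < 0, na.rm = TRUE))
        msg <- c(msg, sprintf("negative counts in assay '%s'", b))
    }
  }
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  if (is.null(msg)) TRUE else msg
})

#' Construct a SiteCounts object
#'
#' @param contig character vector of contig identifiers, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference bases (may include \code{"N"}).
#' @param counts named list with elements \code{A}, \code{C}, \code{G},
#'   \code{T}, each an integer matrix of sites x individuals.
#' @param populations named character vector mapping individual id to
#'   population label; names must match the column names of the count
#'   matrices.
#' @return A \linkS4class{SiteCounts} object.
#' @export
SiteCounts <- function(contig, pos, ref, counts, populations) {
  stopifnot(all(BASES %in% names(counts)))
  ind <- colnames(counts[[1]])
  if (is.null(ind)) stop("count matrices must have individual column names")
  if (!all(ind %in% names(populations)))
    stop("individuals absent from the population map: ",
         paste(setdiff(ind, names(populations)), collapse = ", "))
  key <- paste(contig, pos)
  if (anyDuplicated(key))
    stop("duplicated (contig, pos) pair: ", key[duplicated(key)][1L])
  rr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1L),
                               ref = as.character(ref))
  names(rr) <- if (length(contig)) paste0(contig, ":", pos) else character(0)
  cd <- S4Vectors::DataFrame(individual = ind,
                             population = unname(populations[ind]),
                             row.names = ind)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = lapply(counts[BASES], function(m) {
      storage.mode(m) <- "integer"
      dimnames(m) <- list(names(rr), ind)
      m
    }),
    rowRanges = rr, colData = cd)
  methods::new("SiteCounts", se)
}

#' Called biallelic genotypes
#'
#' \code{GenotypeCalls} stores called genotypes at biallelic SNPs as the count
#' of the B allele per individual: 0 (homozygous A), 1 (heterozygous),
#' 2 (homozygous B), \code{NA} (missing). Row ranges carry \code{alleleA} and
#' \code{alleleB} metadata columns; \code{colData} carries the population
#' label per individual.
#'
#' @slot ... see \link[SummarizedExperiment]{RangedSummarizedExperiment}.
#' @export
setClass("GenotypeCalls", contains = "RangedSummarizedExperiment")

setValidity("GenotypeCalls", function(object) {
  msg <- NULL
  if (!"geno" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'geno' is required")
  else {
    g <- SummarizedExperiment::assay(object, "geno")
    if (!all(g %in% c(0L, 1L, 2L, NA)))
      msg <- c(msg, "genotype codes must be 0, 1, 2 or NA")
  }
  mc <- S4Vectors::mcols(SummarizedExperiment::rowRanges(object))
  if (!all(c("alleleA", "alleleB") %in% colnames(mc)))
    msg <- c(msg, "rowRanges must carry 'alleleA' and 'alleleB'")
  else if (length(object) && any(mc$alleleA == mc$alleleB))
    msg <- c(msg, "alleleA must differ from alleleB at every site")
  if (!"population" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'population' column")
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeCalls object
#'
#' @param contig,pos,populations as in \code{\link{SiteCounts}}.
#' @param alleleA,alleleB character vectors of the two alleles per site.
#' @param geno integer matrix (sites x individuals) of B-allele counts
#'   (0/1/2) with \code{NA} for missing calls.
#' @return A \linkS4class{GenotypeCalls} object.
#' @export
GenotypeCalls <- function(contig, pos, alleleA, alleleB, geno, populations) {
  ind <- colnames(geno)
  if (is.null(ind)) stop("genotype matrix must have individual column names")
  if (!all(ind %in% names(populations)))
    stop("individuals absent from the population map: ",
         paste(setdiff(ind, names(populations)), collapse = ", "))
  rr <- GenomicRanges::GRanges(contig, IRanges::IRanges(pos, width = 1L),
                               alleleA = as.character(alleleA),
                               alleleB = as.character(alleleB))
  names(rr) <- if (length(contig)) paste0(contig, ":", pos) else character(0)
  storage.mode(geno) <- "integer"
  dimnames(geno) <- list(names(rr), ind)
  cd <- S4Vectors::DataFrame(individual = ind,
                             population = unname(populations[ind]),
                             row.names = ind)
  methods::new("GenotypeCalls",
               SummarizedExperiment::SummarizedExperiment(
                 assays = list(geno = geno), rowRanges = rr, colData = cd))
}

#' Genotype-calling and site-filtering thresholds
#'
#' Container for the thresholds applied when calling genotypes from base
#' counts and when filtering sites. Defaults mirror the screening rules of
#' the RNA-seq study the pipeline models: calls at read depth below 3 are
#' missing; a heterozygote requires more than two minor-allele reads and a
#' minor-allele read fraction of at least 10\%; retained sites have at most
#' 20\% missing individuals, expected heterozygosity strictly above 0.2 and
#' observed heterozygosity strictly below 0.6 (sites above that likely
#' collapse paralogous loci).
#'
#' @slot minDepth integer, minimum read depth (over the two site alleles)
#'   for a non-missing call.
#' @slot minMinorReads integer, minimum minor-allele read count for a
#'   heterozygous call ("more than two" = 3).
#' @slot minMaf numeric, minimum minor-allele read fraction for a
#'   heterozygous call.
#' @slot maxMissingFrac numeric, maximum fraction of missing individuals per
#'   retained site (inclusive).
#' @slot minHe numeric, expected-heterozygosity lower bound (strict).
#' @slot maxHo numeric, observed-heterozygosity upper bound (strict).
#' @slot thirdAlleleMaxFrac numeric, maximum pooled read fraction tolerated
#'   for the third-ranked base before the site is rejected as multi-allelic.
#' @export
setClass("CallingConfig",
  representation(minDepth = "integer", minMinorReads = "integer",
                 minMaf = "numeric", maxMissingFrac = "numeric",
                 minHe = "numeric", maxHo = "numeric",
                 thirdAlleleMaxFrac = "numeric"))

setValidity("CallingConfig", function(object) {
  msg <- NULL
  if (object@minDepth < 1L) msg <- c(msg, "minDepth must be >= 1")
  fr <- c(object@minMaf, object@maxMissingFrac, object@minHe, object@maxHo,
          object@thirdAlleleMaxFrac)
  if (any(fr < 0) || any(fr > 1)) msg <- c(msg, "fractions must lie in [0,1]")
  if (is.null(msg)) TRUE else msg
})

#' @param minDepth,minMinorReads,minMaf,maxMissingFrac,minHe,maxHo,thirdAlleleMaxFrac
#'   see the class slots.
#' @return A validated \linkS4class{CallingConfig}.
#' @rdname CallingConfig-class
#' @export
callingConfig <- function(minDepth = 3L, minMinorReads = 3L, minMaf = 0.10,
                          maxMissingFrac = 0.20, minHe = 0.2, maxHo = 0.6,
                          thirdAlleleMaxFrac = 0.05) {
  methods::new("CallingConfig", minDepth = as.integer(minDepth),
               minMinorReads = as.integer(minMinorReads), minMaf = minMaf,
               maxMissingFrac = maxMissingFrac, minHe = minHe, maxHo = maxHo,
               thirdAlleleMaxFrac = thirdAlleleMaxFrac)
}

#' Estimate of the adaptive substitution fraction (alpha)
#'
#' Point estimate, percentile-bootstrap confidence bounds and bookkeeping for
#' the McDonald-Kreitman alpha: the proportion of amino-acid substitutions
#' fixed by positive selection, estimated from cross-gene averages of
#' synonymous/nonsynonymous polymorphism and substitution counts.
#'
#' @slot alpha numeric point estimate.
#' @slot ciLow,ciHigh numeric percentile bootstrap bounds (NA when no
#'   bootstrap was run).
#' @slot nGenes integer number of genes contributing.
#' @slot variant character, estimator variant ("means" or "sew_ps1").
#' @slot B integer number of bootstrap resamples (0 = none).
#' @slot nUndefined integer number of resamples with undefined alpha.
#' @slot unreliable logical, TRUE when more than half the resamples were
#'   undefined.
#' @slot seed integer RNG seed used for the bootstrap (NA when none).
#' @export
setClass("AlphaEstimate",
  representation(alpha = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 nGenes = "integer", variant = "character", B = "integer",
                 nUndefined = "integer", unreliable = "logical",
                 seed = "integer"))

setMethod("show", "AlphaEstimate", function(object) {
  cat(sprintf("AlphaEstimate (variant '%s', %d genes)\n",
              object@variant, object@nGenes))
  cat(sprintf("  alpha = %.4f", object@alpha))
  if (object@B > 0L)
    cat(sprintf("  95%% CI [%.4f, %.4f]  (B = %d, %d undefined%s)",
                object@ciLow, object@ciHigh, object@B, object@nUndefined,
                if (object@unreliable) ", UNRELIABLE" else ""))
  cat("\n")
})

#' Partial-correlation matrix with p-values
#'
#' Result of \code{\link{partialCorr}}: for every pair of variables the
#' correlation controlling for all remaining variables, with two-sided
#' p-values from the t distribution.
#'
#' @slot estimate numeric k x k matrix of partial correlation coefficients
#'   (diagonal 1).
#' @slot p.value numeric k x k matrix of two-sided p-values (diagonal NA).
#' @slot n integer number of observations.
#' @slot gp integer number of controlled variables per pair (k - 2).
#' @export
setClass("PartialCorrMatrix",
  representation(estimate = "matrix", p.value = "matrix", n = "integer",
                 gp = "integer"))

setMethod("show", "PartialCorrMatrix", function(object) {
  cat(sprintf("PartialCorrMatrix: %d variables, n = %d, controlling %d\n",
              ncol(object@estimate), object@n, object@gp))
  print(round(object@estimate, 3))
})

#' Population labels of a genotype or count container
#'
#' @param x a \linkS4class{SiteCounts} or \linkS4class{GenotypeCalls} object.
#' @return named character vector, individual id -> population label.
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

.pops <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  setNames(as.character(cd$population), rownames(cd))
}

#' @rdname populations
#' @export
setMethod("populations", "SiteCounts", .pops)

#' @rdname populations
#' @export
setMethod("populations", "GenotypeCalls", .pops)

#' B-allele count matrix of called genotypes
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @return integer matrix sites x individuals with values 0/1/2/NA.
#' @export
genotypes <- function(x) SummarizedExperiment::assay(x, "geno")

#' Site alleles of called genotypes
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @return data.frame with contig, pos, alleleA, alleleB.
#' @export
siteAlleles <- function(x) {
  rr <- SummarizedExperiment::rowRanges(x)
  data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
             pos = GenomicRanges::start(rr),
             alleleA = rr$alleleA, alleleB = rr$alleleB,
             row.names = names(rr), stringsAsFactors = FALSE)
}

setMethod("show", "SiteCounts", function(object) {
  cat(sprintf("SiteCounts: %d sites x %d individuals (%d populations)\n",
              nrow(object), ncol(object),
              length(unique(.pops(object)))))
})

setMethod("show", "GenotypeCalls", function(object) {
  g <- genotypes(object)
  cat(sprintf(
    "GenotypeCalls: %d SNPs x %d individuals (%d populations), %.1f%% missing\n",
    nrow(object), ncol(object), length(unique(.pops(object))),
    if (length(g)) 100 * mean(is.na(g)) else 0))
})
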