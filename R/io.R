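#' Read a reference transcriptome from FASTA
#'
#' Thin wrapper around \code{\link[Biostrings]{readDNAStringSet}} that
#' enforces the invariants the pipeline relies on: unique contig identifiers
#' (the first whitespace-delimited token of each header), non-empty
#' sequences, uppercase canonical form.
#'
#' @param path path to a FASTA file.
#' @return A \link[Biostrings]{DNAStringSet} named by contig id.
#' @export
readTranscriptome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate contig id in FASTA: ", ids[duplicated(ids)][1L])
  names(seqs) <- ids
  if (any(Biostrings::width(seqs) == 0L))
    stop("empty sequence for contig: ",
         ids[Biostrings::width(seqs) == 0L][1L])
  Biostrings::DNAStringSet(toupper(as.character(seqs)), use.names = TRUE)
}

#' Read a population map
#'
#' Two-column tab-separated file (\code{individual}, \code{population}),
#' with or without a header line.
#'
#' @param path path to the TSV file.
#' @return named character vector, individual id -> population label.
#' @export
readPopulationMap <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                  colClasses = "character", comment.char = "#")
  if (ncol(d) < 2L) stop("population map needs two columns: ", path)
  if (tolower(d[1L, 1L]) %in% c("individual", "sample", "id"))
    d <- d[-1L, , drop = FALSE]
  if (anyDuplicated(d[[1L]]))
    stop("duplicated individual in population map: ",
         d[[1L]][duplicated(d[[1L]])][1L])
  setNames(d[[2L]], d[[1L]])
}

#' Read a per-site base-count table
#'
#' The site table is a TSV with columns \code{contig}, \code{pos},
#' \code{ref}, then one column per individual whose cells are
#' \code{"a,c,g,t"} integer quadruples of read counts. The header row names
#' the individuals; every individual must be present in the population map,
#' and the returned object aligns individuals to the map's order.
#'
#' @param path path to the TSV file.
#' @param populations named character vector as returned by
#'   \code{\link{readPopulationMap}}.
#' @return A \linkS4class{SiteCounts} object.
#' @export
readSiteTable <- function(path, populations) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = "character")
  if (ncol(d) < 4L) stop("site table needs contig, pos, ref + individuals")
  ind <- colnames(d)[-(1:3)]
  unknown <- setdiff(ind, names(populations))
  if (length(unknown))
    stop("individual(s) not in population map: ",
         paste(unknown, collapse = ", "))
  ind <- intersect(names(populations), ind)  # map order
  n <- nrow(d)
  counts <- lapply(BASES, function(b)
    matrix(0L, n, length(ind), dimnames = list(NULL, ind)))
  names(counts) <- BASES
  for (j in seq_along(ind)) {
    cells <- strsplit(d[[ind[j]]], ",", fixed = TRUE)
    len <- lengths(cells)
    if (any(len != 4L))
      stop(sprintf("malformed count quadruple at line %d, individual '%s'",
                   which(len != 4L)[1L] + 1L, ind[j]))
    m <- matrix(suppressWarnings(as.integer(unlist(cells))), ncol = 4L,
                byrow = TRUE)
    if (anyNA(m))
      stop(sprintf("non-integer count at line %d, individual '%s'",
                   which(rowSums(is.na(m)) > 0)[1L] + 1L, ind[j]))
    for (k in 1:4) counts[[k]][, j] <- m[, k]
  }
  pos <- suppressWarnings(as.integer(d[[2L]]))
  if (anyNA(pos))
    stop("non-integer position at line ", which(is.na(pos))[1L] + 1L)
  SiteCounts(contig = d[[1L]], pos = pos, ref = toupper(d[[3L]]),
             counts = counts, populations = populations)
}

#' Write a site table
#'
#' Inverse of \code{\link{readSiteTable}}.
#'
#' @param x a \linkS4class{SiteCounts} object.
#' @param path output path.
#' @export
writeSiteTable <- function(x, path) {
  rr <- SummarizedExperiment::rowRanges(x)
  cnt <- lapply(BASES, function(b) SummarizedExperiment::assay(x, b))
  ind <- colnames(x)
  cols <- lapply(seq_along(ind), function(j)
    paste(cnt[[1]][, j], cnt[[2]][, j], cnt[[3]][, j], cnt[[4]][, j],
          sep = ","))
  d <- data.frame(contig = as.character(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr), ref = rr$ref,
                  stringsAsFactors = FALSE)
  d[ind] <- cols
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write called genotypes as minimal VCF v4.2
#'
#' Emits CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO/FORMAT plus one GT column per
#' individual. Allele A is written as REF and allele B as ALT, so genotype
#' codes 0/1/2 map to \code{0/0}, \code{0/1}, \code{1/1}; missing calls are
#' \code{./.}. Population labels are preserved in a \code{##population} header
#' line per individual so that \code{\link{readVcfGenotypes}} round-trips.
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @param path output path.
#' @export
writeVcf <- function(x, path) {
  rr <- SummarizedExperiment::rowRanges(x)
  g <- genotypes(x)
  pops <- .pops(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=rnaPopGen",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               sprintf("##population=<ID=%s,Population=%s>",
                       names(pops)[names(pops) %in% colnames(g)],
                       pops[names(pops) %in% colnames(g)]),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", colnames(g)), collapse = "\t")), con)
  if (nrow(x)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
    gt[is.na(g)] <- "./."
    body <- cbind(as.character(GenomicRanges::seqnames(rr)),
                  GenomicRanges::start(rr), names(rr), rr$alleleA,
                  rr$alleleB, ".", "PASS", ".", "GT", gt)
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a minimal VCF
#'
#' Reads VCF files written by \code{\link{writeVcf}} (and any single-allele
#' ALT, GT-only VCF body). Population labels are taken from
#' \code{##population} header lines when present, else from the
#' \code{populations} argument.
#'
#' @param path path to a VCF file.
#' @param populations optional named character vector overriding/supplying
#'   population labels.
#' @return A \linkS4class{GenotypeCalls} object.
#' @export
readVcfGenotypes <- function(path, populations = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- grep("^##", lines, value = TRUE)
  poplines <- grep("^##population=", hdr, value = TRUE)
  if (length(poplines) && is.null(populations)) {
    ids <- sub('^##population=<ID=([^,]+),.*$', "\\1", poplines)
    pp <- sub('^##population=<ID=[^,]+,Population=([^>]+)>$', "\\1", poplines)
    populations <- setNames(pp, ids)
  }
  chrom <- grep("^#CHROM", lines)
  if (!length(chrom)) stop("no #CHROM header line in ", path)
  cols <- strsplit(lines[chrom], "\t", fixed = TRUE)[[1L]]
  ind <- cols[-(1:9)]
  if (is.null(populations))
    populations <- setNames(rep("pop1", length(ind)), ind)
  body <- lines[-seq_len(chrom)]
  body <- body[nzchar(body)]
  if (!length(body)) {
    geno <- matrix(NA_integer_, 0L, length(ind),
                   dimnames = list(NULL, ind))
    return(GenotypeCalls(character(), integer(), character(), character(),
                         geno, populations))
  }
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  gtf <- f[, -(1:9), drop = FALSE]
  gt <- sub(":.*$", "", gtf)
  geno <- matrix(NA_integer_, nrow(f), length(ind),
                 dimnames = list(NULL, ind))
  geno[gt %in% c("0/0", "0|0")] <- 0L
  geno[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  geno[gt %in% c("1/1", "1|1")] <- 2L
  GenotypeCalls(contig = f[, 1L], pos = as.integer(f[, 2L]),
                alleleA = f[, 4L], alleleB = f[, 5L], geno = geno,
                populations = populations)
}

#' Read a gene-to-GO map
#'
#' TSV with columns \code{gene}, \code{go} and optionally
#' \code{description}; one row per (gene, category) pair, genes may appear
#' under several categories.
#'
#' @param path path to the TSV file.
#' @return data.frame with columns gene, go, description.
#' @export
readGoMap <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(d)[1:2] <- c("gene", "go")
  if (!"description" %in% names(d)) d$description <- d$go
  d[, c("gene", "go", "description")]
}

#' Read a gene x sample count matrix
#'
#' TSV whose first column is the gene id and remaining columns are samples.
#'
#' @param path path to the TSV file.
#' @return numeric matrix with gene rownames.
#' @export
readCountMatrix <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  storage.mode(m) <- "double"
  m
}
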