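# ORF detection, consensus coding sequences, syn/nonsyn classification and
# Nei-Gojobori (1986) dN/dS with Jukes-Cantor correction.

STOP_CODONS <- c("TAA", "TAG", "TGA")

.codonEnv <- new.env(parent = emptyenv())

.aa <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  unname(gc[codon])
}

# Per-codon synonymous site count by the 1/3-fraction rule. Mutations to stop
# codons count as nonsynonymous, so syn + nonsyn == 3 for every sense codon.
.codonSynSites <- function() {
  if (!is.null(.codonEnv$syn)) return(.codonEnv$syn)
  codons <- apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE),
                  1L, function(x) paste0(x[1], x[2], x[3]))
  syn <- setNames(rep(NA_real_, 64L), codons)
  for (cod in codons) {
    if (cod %in% STOP_CODONS) next
    s <- 0
    for (p in 1:3) for (b in setdiff(BASES, substr(cod, p, p))) {
      mut <- cod
      substr(mut, p, p) <- b
      if (!(mut %in% STOP_CODONS) && .aa(mut) == .aa(cod)) s <- s + 1 / 3
    }
    syn[cod] <- s
  }
  .codonEnv$syn <- syn
  syn
}

#' Synonymous and nonsynonymous site fractions of a codon
#'
#' By the Nei-Gojobori 1/3-fraction rule: at each codon position, the
#' fraction of the three possible single-base changes that leave the amino
#' acid unchanged is the synonymous fraction of that site. Changes creating
#' a stop codon are counted as nonsynonymous, so the two fractions always
#' sum to 3 for a sense codon. Stop codons and codons containing \code{N}
#' return \code{NA}.
#'
#' @param codon a 3-character codon string.
#' @return named numeric vector \code{c(syn = ..., nonsyn = ...)}.
#' @export
codonSiteFractions <- function(codon) {
  codon <- toupper(codon)
  if (grepl("[^ACGT]", codon) || codon %in% STOP_CODONS)
    return(c(syn = NA_real_, nonsyn = NA_real_))
  s <- .codonSynSites()[[codon]]
  c(syn = s, nonsyn = 3 - s)
}

#' Classify a single-base change within a codon
#'
#' @param codon reference 3-character codon.
#' @param posInCodon position of the change (1, 2 or 3).
#' @param altBase replacement base.
#' @return \code{"synonymous"} or \code{"nonsynonymous"}; a change creating
#'   a stop codon is nonsynonymous with attribute \code{stop = TRUE}.
#' @export
classifySnp <- function(codon, posInCodon, altBase) {
  codon <- toupper(codon)
  if (codon %in% STOP_CODONS) stop("reference codon is a stop codon")
  mut <- codon
  substr(mut, posInCodon, posInCodon) <- toupper(altBase)
  if (mut %in% STOP_CODONS) {
    out <- "nonsynonymous"
    attr(out, "stop") <- TRUE
    return(out)
  }
  if (.aa(mut) == .aa(codon)) "synonymous" else "nonsynonymous"
}

# Maximal stop-free codon runs of one frame of a forward-oriented sequence.
# Returns matrix with local start/end (nt, 1-based on that orientation).
.frameRuns <- function(seqchars, frame) {
  L <- length(seqchars)
  ncod <- (L - frame) %/% 3L
  if (ncod == 0L) return(NULL)
  starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
  cods <- paste0(seqchars[starts], seqchars[starts + 1L], seqchars[starts + 2L])
  isStop <- cods %in% STOP_CODONS
  r <- rle(!isStop)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  ok <- r$values
  if (!any(ok)) return(NULL)
  cbind(start = starts[begs[ok]], end = starts[ends[ok]] + 2L)
}

# All maximal stop-free runs >= minLen across the six frames, in the
# tie-break order used by findOrf (length desc, + strand first, frame asc,
# forward start asc).
.allRuns <- function(s, minLen) {
  L <- nchar(s)
  fwd <- strsplit(s, "", fixed = TRUE)[[1L]]
  rev <- strsplit(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s))),
    "", fixed = TRUE)[[1L]]
  cand <- list()
  for (strand in c("+", "-")) {
    chars <- if (strand == "+") fwd else rev
    for (frame in 0:2) {
      runs <- .frameRuns(chars, frame)
      if (is.null(runs)) next
      for (i in seq_len(nrow(runs))) {
        len <- runs[i, "end"] - runs[i, "start"] + 1L
        if (len < minLen) next
        if (strand == "+") {
          st <- runs[i, "start"]; en <- runs[i, "end"]
        } else {
          st <- L - runs[i, "end"] + 1L; en <- L - runs[i, "start"] + 1L
        }
        cand[[length(cand) + 1L]] <-
          data.frame(start = st, end = en, strand = strand, frame = frame,
                     length = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length = integer(), stringsAsFactors = FALSE))
  cand <- do.call(rbind, cand)
  cand[order(-cand$length, cand$strand != "+", cand$frame, cand$start), ,
       drop = FALSE]
}

#' Find the longest open-ended ORF of a sequence
#'
#' Scans all six reading frames (three per strand) for maximal stop-free
#' runs of codons. Runs are open-ended: no start codon is required and they
#' may abut the sequence ends. The longest run of at least \code{minLen}
#' nucleotides is returned, with coordinates on the forward strand; ties are
#' broken by strand (+ first), then frame (lowest), then start (lowest).
#'
#' @param sequence a character string, \link[Biostrings]{DNAString} or
#'   single-element DNAStringSet.
#' @param minLen minimum ORF length in nucleotides (default 300).
#' @return one-row data.frame with start, end (1-based inclusive, forward
#'   coordinates), strand, frame and length; or \code{NULL} when no run
#'   qualifies.
#' @export
findOrf <- function(sequence, minLen = 300L) {
  s <- toupper(as.character(sequence)[1L])
  if (nchar(s) < minLen) return(NULL)
  cand <- .allRuns(s, minLen)
  if (nrow(cand) == 0L) return(NULL)
  out <- cand[1L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find ORFs for every contig of a transcriptome
#'
#' @param seqs a named \link[Biostrings]{DNAStringSet}.
#' @param minLen minimum ORF length in nucleotides.
#' @return data.frame with one row per contig holding a qualifying ORF:
#'   gene, start, end, strand, frame, length.
#' @export
findOrfs <- function(seqs, minLen = 300L) {
  res <- lapply(names(seqs), function(id) {
    o <- findOrf(seqs[[id]], minLen)
    if (is.null(o)) return(NULL)
    cbind(gene = id, o, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(gene = character(), start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      length = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Extract the coding-oriented ORF sequence (character) given forward contig
# sequence and an ORF annotation row.
.orfSequence <- function(contigSeq, orf) {
  sub <- substr(toupper(as.character(contigSeq)), orf$start, orf$end)
  if (orf$strand == "-")
    sub <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(sub)))
  sub
}

.complement <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Per-species consensus coding sequence
#'
#' Substitutes, at every SNP inside the ORF, the major allele among the
#' species' called allele copies into the reference ORF sequence. Ties and
#' all-missing SNPs keep the reference base (the latter with a warning).
#' Returned in coding orientation.
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @param orf one-row ORF annotation (from \code{\link{findOrfs}}) with a
#'   \code{gene} column naming the contig.
#' @param reference a named \link[Biostrings]{DNAStringSet}.
#' @param species population label.
#' @return character string: the consensus coding sequence.
#' @export
speciesConsensus <- function(x, orf, reference, species) {
  seqchars <- strsplit(.orfSequence(reference[[orf$gene]], orf), "",
                       fixed = TRUE)[[1L]]
  pop <- .pops(x)[colnames(x)]
  al <- siteAlleles(x)
  inOrf <- al$contig == orf$gene & al$pos >= orf$start & al$pos <= orf$end
  if (any(inOrf)) {
    g <- genotypes(x)[inOrf, pop == species, drop = FALSE]
    al <- al[inOrf, , drop = FALSE]
    copies <- 2 * rowSums(!is.na(g))
    doseB <- rowSums(g, na.rm = TRUE)
    doseA <- copies - doseB
    for (i in seq_len(nrow(al))) {
      if (copies[i] == 0L) {
        warning("all individuals missing at ", al$contig[i], ":", al$pos[i],
                "; reference base retained")
        next
      }
      if (doseA[i] == doseB[i]) next  # tie -> reference base
      major <- if (doseA[i] > doseB[i]) al$alleleA[i] else al$alleleB[i]
      loc <- if (orf$strand == "+") al$pos[i] - orf$start + 1L
             else orf$end - al$pos[i] + 1L
      base <- if (orf$strand == "+") major else .complement[[major]]
      seqchars[loc] <- base
    }
  }
  paste(seqchars, collapse = "")
}

# Pathway-averaged synonymous/nonsynonymous difference counts for one codon
# pair. All orderings of the differing positions are averaged; a step
# producing a stop codon counts as nonsynonymous.
.codonDiff <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd, list(pos),
                  list(pos, pos[2:1]),
                  list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
                       pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)]))
  sdv <- 0; ndv <- 0
  for (ord in perms) {
    cur <- c1
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (!(nxt %in% STOP_CODONS) && !(cur %in% STOP_CODONS) &&
          .aa(nxt) == .aa(cur)) sdv <- sdv + 1 else ndv <- ndv + 1
      cur <- nxt
    }
  }
  c(sd = sdv / length(perms), nd = ndv / length(perms))
}

#' Nei-Gojobori dN/dS between two aligned coding sequences
#'
#' Counting-method estimate: synonymous site totals come from the
#' 1/3-fraction rule averaged over both sequences; observed differences are
#' pathway-averaged over all substitution orders in multi-hit codons; the
#' per-site proportions pN and pS are Jukes-Cantor corrected,
#' \code{d = -3/4 log(1 - 4p/3)}. Codons containing \code{N} or an in-frame
#' stop in either sequence are skipped and counted in \code{nSkipped}.
#' The ratio is defined only when both dN and dS are positive.
#'
#' @param seq1,seq2 equal-length coding sequences (character/DNAString),
#'   length a multiple of 3.
#' @return list with dN, dS, ratio, pN, pS, Nd, Sd, Nsites, Ssites,
#'   nCodons, nSkipped and a character \code{flag} ("" when clean;
#'   "saturated" when a JC correction was undefined).
#' @export
ng86DnDs <- function(seq1, seq2) {
  s1 <- toupper(as.character(seq1)[1L]); s2 <- toupper(as.character(seq2)[1L])
  if (nchar(s1) != nchar(s2)) stop("sequences must be of equal length")
  if (nchar(s1) %% 3L != 0L) stop("length must be a multiple of 3")
  n <- nchar(s1) %/% 3L
  st <- 3L * (seq_len(n) - 1L) + 1L
  c1 <- substring(s1, st, st + 2L)
  c2 <- substring(s2, st, st + 2L)
  synTab <- .codonSynSites()
  usable <- !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2) &
    !(c1 %in% STOP_CODONS) & !(c2 %in% STOP_CODONS)
  Ss <- (synTab[c1[usable]] + synTab[c2[usable]]) / 2
  Ssites <- sum(Ss)
  Nsites <- 3 * sum(usable) - Ssites
  Sd <- 0; Nd <- 0
  for (i in which(usable & c1 != c2)) {
    d <- .codonDiff(c1[i], c2[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  pS <- if (Ssites > 0) Sd / Ssites else 0
  pN <- if (Nsites > 0) Nd / Nsites else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS); dN <- jc(pN)
  flag <- if (is.na(dS) || is.na(dN)) "saturated" else ""
  ratio <- if (!is.na(dN) && !is.na(dS) && dN > 0 && dS > 0) dN / dS
           else NA_real_
  list(dN = dN, dS = dS, ratio = ratio, pN = pN, pS = pS, Nd = Nd, Sd = Sd,
       Nsites = Nsites, Ssites = Ssites, nCodons = sum(usable),
       nSkipped = n - sum(usable), flag = flag)
}

#' Classify coding SNPs against the reference ORF context
#'
#' For every SNP falling inside a detected ORF, builds the reference codon
#' context, substitutes each of the two site alleles at the SNP position and
#' classifies the A-to-B change as synonymous or nonsynonymous (coding
#' orientation; alleles are complemented for minus-strand ORFs). SNPs whose
#' codon context contains \code{N} or where either allele codon is a stop
#' are classified against the standard code with stops counted
#' nonsynonymous.
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @param orfs ORF annotation data.frame from \code{\link{findOrfs}}.
#' @param reference named \link[Biostrings]{DNAStringSet}.
#' @return data.frame with gene, pos, class ("synonymous"/"nonsynonymous"),
#'   one row per SNP inside an ORF.
#' @export
classifyCodingSnps <- function(x, orfs, reference) {
  al <- siteAlleles(x)
  out <- list()
  for (k in seq_len(nrow(orfs))) {
    orf <- orfs[k, ]
    sel <- al$contig == orf$gene & al$pos >= orf$start & al$pos <= orf$end
    if (!any(sel)) next
    oseq <- .orfSequence(reference[[orf$gene]], orf)
    sub <- al[sel, , drop = FALSE]
    loc <- if (orf$strand == "+") sub$pos - orf$start + 1L
           else orf$end - sub$pos + 1L
    aA <- if (orf$strand == "+") sub$alleleA else .complement[sub$alleleA]
    aB <- if (orf$strand == "+") sub$alleleB else .complement[sub$alleleB]
    codIdx <- (loc - 1L) %/% 3L
    codPos <- (loc - 1L) %% 3L + 1L
    cls <- character(nrow(sub))
    for (i in seq_len(nrow(sub))) {
      cod <- substr(oseq, 3L * codIdx[i] + 1L, 3L * codIdx[i] + 3L)
      codA <- cod; substr(codA, codPos[i], codPos[i]) <- aA[i]
      codB <- cod; substr(codB, codPos[i], codPos[i]) <- aB[i]
      if (grepl("[^ACGT]", codA) || grepl("[^ACGT]", codB)) {
        cls[i] <- NA_character_
      } else if (codA %in% STOP_CODONS || codB %in% STOP_CODONS) {
        cls[i] <- "nonsynonymous"
      } else {
        cls[i] <- if (.aa(codA) == .aa(codB)) "synonymous" else "nonsynonymous"
      }
    }
    out[[length(out) + 1L]] <-
      data.frame(gene = orf$gene, pos = sub$pos, class = cls,
                 stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(gene = character(), pos = integer(),
                      class = character(), stringsAsFactors = FALSE)
  res[!is.na(res$class), , drop = FALSE]
}

#' dN/dS for every gene of a species pair
#'
#' Builds the two species consensus coding sequences per ORF and applies
#' \code{\link{ng86DnDs}}.
#'
#' @param x a \linkS4class{GenotypeCalls} object.
#' @param orfs ORF annotations from \code{\link{findOrfs}}.
#' @param reference named \link[Biostrings]{DNAStringSet}.
#' @param pair two population labels.
#' @return data.frame with gene, dN, dS, ratio, nCodons, flag.
#' @export
pairDnDs <- function(x, orfs, reference, pair) {
  rows <- lapply(seq_len(nrow(orfs)), function(k) {
    orf <- orfs[k, ]
    cs1 <- suppressWarnings(speciesConsensus(x, orf, reference, pair[1L]))
    cs2 <- suppressWarnings(speciesConsensus(x, orf, reference, pair[2L]))
    r <- ng86DnDs(cs1, cs2)
    data.frame(gene = orf$gene, dN = r$dN, dS = r$dS, ratio = r$ratio,
               nCodons = r$nCodons, flag = r$flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene = character(), dN = numeric(), dS = numeric(),
                      ratio = numeric(), nCodons = integer(),
                      flag = character(), stringsAsFactors = FALSE)
  out
}
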