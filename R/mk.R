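# McDonald-Kreitman machinery: per-gene counts with FST-threshold
# substitutions, G-test of independence, alpha estimation with bootstrap
# confidence intervals, and GO-category scans.

#' Per-gene McDonald-Kreitman counts
#'
#' Splits a gene's coding SNPs into the four MK cells. SNPs whose pairwise
#' FST is at least \code{fstThreshold} are counted as substitutions (Dn/Ds);
#' the rest are polymorphisms (Pn/Ps). Each SNP contributes to exactly one
#' cell; SNPs with undefined FST are dropped.
#'
#' @param snps data.frame with columns \code{gene}, \code{class}
#'   ("synonymous"/"nonsynonymous") and \code{fst} (per-SNP theta for the
#'   pair; NA = undefined).
#' @param fstThreshold FST at or above which a SNP counts as fixed
#'   (default 0.9).
#' @return data.frame with gene, Pn, Ps, Dn, Ds (one row per gene, all
#'   genes present in \code{snps}; genes whose SNPs all had undefined FST
#'   get zero rows of counts).
#' @export
mkCounts <- function(snps, fstThreshold = 0.9) {
  genes <- unique(snps$gene)
  ok <- !is.na(snps$fst)
  s <- snps[ok, , drop = FALSE]
  fixed <- s$fst >= fstThreshold
  nonsyn <- s$class == "nonsynonymous"
  tab <- function(sel) {
    t <- table(factor(s$gene[sel], levels = genes))
    as.integer(t)
  }
  data.frame(gene = genes,
             Pn = tab(!fixed & nonsyn), Ps = tab(!fixed & !nonsyn),
             Dn = tab(fixed & nonsyn), Ds = tab(fixed & !nonsyn),
             stringsAsFactors = FALSE)
}

#' G-test of independence on the pooled MK table
#'
#' Likelihood-ratio test on the 2x2 table (polymorphic/fixed x
#' nonsynonymous/synonymous): \code{G = 2 sum O log(O/E)} with expectations
#' from the margins, compared to chi-square with 1 df. The optional
#' Williams correction divides G by
#' \code{1 + ((N/r1 + N/r2 - 1)(N/c1 + N/c2 - 1)) / (6N)}.
#'
#' @param Pn,Ps,Dn,Ds pooled counts.
#' @param williams apply the Williams correction (default FALSE).
#' @return list with G, p.value, df.
#' @export
gTest <- function(Pn, Ps, Dn, Ds, williams = FALSE) {
  O <- matrix(c(Pn, Ps, Dn, Ds), 2L, 2L, byrow = TRUE,
              dimnames = list(c("polymorphic", "fixed"),
                              c("nonsyn", "syn")))
  if (any(rowSums(O) == 0) || any(colSums(O) == 0))
    stop("zero marginal total: G-test undefined")
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  G <- 2 * sum(ifelse(O > 0, O * log(O / E), 0))
  if (williams) {
    N <- sum(O)
    q <- 1 + (sum(N / rowSums(O)) - 1) * (sum(N / colSums(O)) - 1) / (6 * N)
    G <- G / q
  }
  list(G = G, p.value = pchisq(G, df = 1L, lower.tail = FALSE), df = 1L)
}

# Point alpha from a per-gene count table (rows = genes).
.alphaPoint <- function(counts, variant) {
  Ps <- mean(counts$Ps); Pn <- mean(counts$Pn)
  Ds <- mean(counts$Ds); Dn <- mean(counts$Dn)
  if (Dn == 0 || Ps == 0) return(NA_real_)
  if (variant == "means") {
    1 - (Ds * Pn) / (Dn * Ps)
  } else if (variant == "sew_ps1") {
    1 - (Ds / Dn) * mean(counts$Pn / (counts$Ps + 1))
  } else stop("unknown variant: ", variant)
}

#' Genome-wide alpha point estimate
#'
#' The proportion of substitutions fixed by positive selection, from
#' cross-gene averages of the MK cells. Variant \code{"means"} (default):
#' \code{alpha = 1 - (mean(Ds) mean(Pn)) / (mean(Dn) mean(Ps))},
#' algebraically equal to the pooled-count estimate over the same gene set.
#' Variant \code{"sew_ps1"} uses the per-gene ratio form with a +1
#' adjustment to Ps: \code{1 - (mean(Ds)/mean(Dn)) mean_i(Pn_i/(Ps_i+1))}.
#' Undefined (NA) when mean(Dn) or mean(Ps) is zero.
#'
#' @param counts data.frame with columns Pn, Ps, Dn, Ds (one row per gene).
#' @param variant "means" or "sew_ps1".
#' @return An \linkS4class{AlphaEstimate} without confidence bounds.
#' @export
alphaGenomewide <- function(counts, variant = "means") {
  a <- .alphaPoint(counts, variant)
  methods::new("AlphaEstimate", alpha = a, ciLow = NA_real_,
               ciHigh = NA_real_, nGenes = nrow(counts), variant = variant,
               B = 0L, nUndefined = 0L, unreliable = FALSE,
               seed = NA_integer_)
}

#' Alpha with percentile bootstrap confidence interval
#'
#' Resamples genes with replacement \code{B} times, recomputes alpha per
#' resample and reports the 2.5/97.5 percentile bounds. Resamples with
#' undefined alpha are dropped and counted; the interval is flagged
#' unreliable when more than half are undefined.
#'
#' @param counts per-gene count data.frame (columns Pn, Ps, Dn, Ds).
#' @param B number of bootstrap resamples (default 1000).
#' @param seed RNG seed for the resampling.
#' @param variant estimator variant, see \code{\link{alphaGenomewide}}.
#' @return An \linkS4class{AlphaEstimate} with confidence bounds.
#' @export
alphaBootstrap <- function(counts, B = 1000L, seed = 1L, variant = "means") {
  n <- nrow(counts)
  if (n < 1L) stop("need at least one gene")
  point <- .alphaPoint(counts, variant)
  cm <- as.matrix(counts[, c("Pn", "Ps", "Dn", "Ds")])
  set.seed(seed)
  idx <- sample.int(n, n * B, replace = TRUE)
  grp <- rep(seq_len(B), each = n)
  sums <- rowsum(cm[idx, , drop = FALSE], grp)  # B x 4 totals
  if (variant == "means") {
    al <- 1 - (sums[, "Ds"] * sums[, "Pn"]) / (sums[, "Dn"] * sums[, "Ps"])
    al[sums[, "Dn"] == 0 | sums[, "Ps"] == 0] <- NA_real_
  } else {
    ratio <- cm[idx, "Pn"] / (cm[idx, "Ps"] + 1)
    mr <- rowsum(ratio, grp)[, 1L] / n
    al <- 1 - (sums[, "Ds"] / sums[, "Dn"]) * mr
    al[sums[, "Dn"] == 0] <- NA_real_
  }
  bad <- sum(is.na(al))
  qs <- if (bad < B) quantile(al, c(0.025, 0.975), na.rm = TRUE,
                              names = FALSE)
        else c(NA_real_, NA_real_)
  methods::new("AlphaEstimate", alpha = point, ciLow = qs[1L],
               ciHigh = qs[2L], nGenes = n, variant = variant,
               B = as.integer(B), nUndefined = as.integer(bad),
               unreliable = bad > B / 2, seed = as.integer(seed))
}

#' Alpha scan over GO categories
#'
#' Computes alpha with bootstrap confidence bounds for every GO category
#' holding at least \code{minGenes} genes with MK counts, ranks categories
#' by alpha and flags the top five.
#'
#' @param counts per-gene count data.frame (columns gene, Pn, Ps, Dn, Ds).
#' @param goMap data.frame with columns gene, go and optionally
#'   description (genes may appear under several categories).
#' @param minGenes minimum category size (default 50).
#' @param B bootstrap resamples per category.
#' @param seed RNG seed.
#' @param variant estimator variant.
#' @return data.frame with go, description, nGenes, alpha, ciLow, ciHigh,
#'   top5 (logical), ordered by decreasing alpha.
#' @export
goAlphaScan <- function(counts, goMap, minGenes = 50L, B = 1000L, seed = 1L,
                        variant = "means") {
  if (!"description" %in% names(goMap)) goMap$description <- goMap$go
  goMap <- goMap[goMap$gene %in% counts$gene, , drop = FALSE]
  cats <- split(goMap$gene, goMap$go)
  cats <- cats[lengths(lapply(cats, unique)) >= minGenes]
  if (!length(cats))
    return(data.frame(go = character(), description = character(),
                      nGenes = integer(), alpha = numeric(),
                      ciLow = numeric(), ciHigh = numeric(),
                      top5 = logical(), stringsAsFactors = FALSE))
  desc <- goMap$description[match(names(cats), goMap$go)]
  rows <- lapply(seq_along(cats), function(i) {
    sub <- counts[counts$gene %in% cats[[i]], , drop = FALSE]
    est <- alphaBootstrap(sub, B = B, seed = seed + i, variant = variant)
    data.frame(go = names(cats)[i], description = desc[i],
               nGenes = nrow(sub), alpha = est@alpha, ciLow = est@ciLow,
               ciHigh = est@ciHigh, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$alpha), , drop = FALSE]
  out$top5 <- seq_len(nrow(out)) <= 5L
  rownames(out) <- NULL
  out
}
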