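# End-to-end orchestration: genotyping -> population genetics -> coding ->
# McDonald-Kreitman -> expression -> correlates, per species pair, with a
# written report bundle.

#' Read and validate a pipeline configuration
#'
#' The configuration is a YAML (or R list) with an \code{inputs} block
#' (paths: fasta, sites, pops, expression, libhits, goMap, optionally lnp),
#' an optional \code{pairs} list of two-element population pairs (default:
#' all pairs), a \code{params} block overriding thresholds, a \code{seed}
#' and an \code{outdir}. All input paths are checked before any stage runs.
#'
#' @param config path to a YAML file, or a list with the same structure.
#' @return validated configuration list.
#' @export
readPipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$inputs)) stop("config has no 'inputs' block")
  needed <- c("fasta", "sites", "pops", "expression", "libhits", "goMap")
  for (f in needed) {
    p <- config$inputs[[f]]
    if (is.null(p)) stop("config inputs missing '", f, "'")
    if (!file.exists(p)) stop("input '", f, "' not found: ", p)
  }
  if (!is.null(config$inputs$lnp) && !file.exists(config$inputs$lnp))
    stop("input 'lnp' not found: ", config$inputs$lnp)
  if (is.null(config$outdir)) stop("config has no 'outdir'")
  if (is.null(config$seed)) config$seed <- 1L
  defaults <- list(fstThreshold = 0.9, minGenes = 50L, B = 1000L,
                   minExpression = 14, epsilon = 0.5, minOrfLen = 300L,
                   minDepth = 3L, minMinorReads = 3L, minMaf = 0.10,
                   maxMissingFrac = 0.20, minHe = 0.2, maxHo = 0.6,
                   thirdAlleleMaxFrac = 0.05)
  config$params <- utils::modifyList(defaults,
                                     as.list(config$params %||% list()))
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.log <- function(...) message(sprintf("[rnaPopGen] %s", sprintf(...)))

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured inputs and writes the report
#' bundle to \code{outdir}: called SNPs (\code{snps.vcf}), per-pair
#' per-gene statistics (\code{genes_<pair>.tsv}: mean FST, pi, Watterson's
#' theta, dN, dS, dN/dS, MK cells, expression metrics), per-pair partial
#' correlation matrices (\code{pcorr_<pair>.tsv},
#' \code{pcorr_pvalues_<pair>.tsv}), the GO alpha scan
#' (\code{go_alpha.tsv}), the deltaK table (\code{deltak.tsv}) when a
#' clustering log-likelihood table is configured, a per-pair summary
#' (\code{summary.tsv}) and a run manifest (\code{manifest.yaml}). Outputs
#' are a pure function of (inputs, config, seed).
#'
#' @param config path to a YAML configuration or a configuration list; see
#'   \code{\link{readPipelineConfig}}.
#' @return invisibly, a list with the summary data.frame and output paths.
#' @export
runPipeline <- function(config) {
  cfg <- readPipelineConfig(config)
  par <- cfg$params
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  .log("reading inputs")
  ref <- readTranscriptome(cfg$inputs$fasta)
  pops <- readPopulationMap(cfg$inputs$pops)
  sites <- readSiteTable(cfg$inputs$sites, pops)
  exprCounts <- readCountMatrix(cfg$inputs$expression)
  libhits <- readCountMatrix(cfg$inputs$libhits)
  goMap <- readGoMap(cfg$inputs$goMap)
  lens <- setNames(Biostrings::width(ref), names(ref))

  ccfg <- callingConfig(par$minDepth, par$minMinorReads, par$minMaf,
                        par$maxMissingFrac, par$minHe, par$maxHo,
                        par$thirdAlleleMaxFrac)
  .log("genotyping %d sites x %d individuals", nrow(sites), ncol(sites))
  gc <- genotypeSiteTable(sites, ccfg)
  .log("%d SNPs retained after filtering", nrow(gc))
  vcfPath <- file.path(cfg$outdir, "snps.vcf")
  writeVcf(gc, vcfPath)
  dens <- snpDensityPer100bp(nrow(gc), sum(lens))
  .log("SNP density %.1f per 100 bp", dens)

  .log("detecting ORFs (min %d nt)", par$minOrfLen)
  orfs <- findOrfs(ref, par$minOrfLen)
  .log("%d ORFs found in %d contigs", nrow(orfs), length(ref))

  .log("normalizing expression")
  normExpr <- normalizeExpression(exprCounts, lens)
  spec <- expressionSpecificity(libhits)

  species <- sort(unique(pops))
  pairs <- cfg$pairs %||%
    utils::combn(species, 2L, simplify = FALSE)
  pairs <- lapply(pairs, as.character)

  summary <- list()
  mkList <- list()
  outputs <- list(vcf = vcfPath)
  for (pair in pairs) {
    tag <- paste(pair, collapse = "_")
    .log("pair %s: population statistics", tag)
    fst <- snpFst(gc, pair)
    gdiv <- geneDiversity(gc, pair, lens)
    .log("pair %s: consensus dN/dS over %d ORFs", tag, nrow(orfs))
    dnds <- pairDnDs(gc, orfs, ref, pair)
    .log("pair %s: McDonald-Kreitman", tag)
    coding <- classifyCodingSnps(gc, orfs, ref)
    key <- paste(fst$contig, fst$pos)
    coding$fst <- fst$theta[match(paste(coding$gene, coding$pos), key)]
    mk <- mkCounts(coding, par$fstThreshold)
    pooled <- colSums(mk[, c("Pn", "Ps", "Dn", "Ds")])
    gres <- tryCatch(gTest(pooled["Pn"], pooled["Ps"], pooled["Dn"],
                           pooled["Ds"]),
                     error = function(e) list(G = NA_real_,
                                              p.value = NA_real_))
    alpha <- alphaBootstrap(mk, B = par$B, seed = cfg$seed)
    .log("pair %s: expression metrics", tag)
    div <- expressionDivergence(normExpr, pops, pair, par$epsilon)
    lvl <- data.frame(gene = rownames(normExpr),
                      meanExpr = rowMeans(
                        normExpr[, pops[colnames(normExpr)] %in% pair,
                                 drop = FALSE]),
                      stringsAsFactors = FALSE)
    genesTab <- Reduce(function(a, b) merge(a, b, by = "gene", all = TRUE),
                       list(gdiv, dnds[, c("gene", "dN", "dS", "ratio")],
                            mk, spec, lvl,
                            div[, c("gene", "divergence")]))
    write.table(genesTab, file.path(cfg$outdir,
                                    sprintf("genes_%s.tsv", tag)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    .log("pair %s: partial correlations", tag)
    ptab <- tryCatch(
      buildGeneTable(dnds, gdiv[, c("gene", "fst")],
                     gdiv[, c("gene", "pi")], spec, lvl,
                     div[, c("gene", "divergence")],
                     minExpression = par$minExpression),
      error = function(e) NULL)
    if (!is.null(ptab) && nrow(ptab) > ncol(ptab) + 2L) {
      pc <- partialCorr(ptab[, c("logDnds", "fst", "pi", "specificity",
                                 "logExpr", "exprDivergence")])
      write.table(round(pc@estimate, 6),
                  file.path(cfg$outdir, sprintf("pcorr_%s.tsv", tag)),
                  sep = "\t", quote = FALSE)
      write.table(signif(pc@p.value, 6),
                  file.path(cfg$outdir, sprintf("pcorr_pvalues_%s.tsv", tag)),
                  sep = "\t", quote = FALSE)
      nCorr <- pc@n
    } else {
      .log("pair %s: too few genes for partial correlations", tag)
      nCorr <- 0L
    }
    summary[[tag]] <- data.frame(
      pair = tag,
      nSnps = sum(fst$defined),
      meanFst = mean(gdiv$fst, na.rm = TRUE),
      medianFst = median(gdiv$fst, na.rm = TRUE),
      Pn = pooled[["Pn"]], Ps = pooled[["Ps"]],
      Dn = pooled[["Dn"]], Ds = pooled[["Ds"]],
      alpha = alpha@alpha, ciLow = alpha@ciLow, ciHigh = alpha@ciHigh,
      G = gres$G, p = gres$p.value,
      meanDnDs = mean(dnds$ratio, na.rm = TRUE),
      nGenesCorrelated = nCorr,
      stringsAsFactors = FALSE)
    mkList[[tag]] <- mk
    outputs[[sprintf("genes_%s", tag)]] <-
      file.path(cfg$outdir, sprintf("genes_%s.tsv", tag))
  }

  .log("GO-category alpha scan")
  goTabs <- lapply(names(mkList), function(tag) {
    g <- goAlphaScan(mkList[[tag]], goMap, minGenes = par$minGenes, B = par$B,
                     seed = cfg$seed)
    if (nrow(g)) cbind(pair = tag, g) else NULL
  })
  goTab <- do.call(rbind, goTabs)
  if (!is.null(goTab))
    write.table(goTab, file.path(cfg$outdir, "go_alpha.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  if (!is.null(cfg$inputs$lnp)) {
    lnp <- read.delim(cfg$inputs$lnp)
    dk <- deltaK(lnp[, c("K", "lnP")])
    write.table(dk, file.path(cfg$outdir, "deltak.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    .log("deltaK peak at K = %d", dk$K[which.max(dk$deltaK)])
  }

  summaryTab <- do.call(rbind, summary)
  summaryTab$snpDensityPer100bp <- dens
  write.table(summaryTab, file.path(cfg$outdir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest <- list(package = "rnaPopGen",
                   version = as.character(packageVersion("rnaPopGen")),
                   seed = cfg$seed, params = par,
                   inputs = cfg$inputs,
                   pairs = vapply(pairs, paste, "", collapse = "_"))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  .log("done; report in %s", cfg$outdir)
  invisible(list(summary = summaryTab, outdir = cfg$outdir,
                 outputs = outputs))
}
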