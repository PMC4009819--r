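test_that("every generator is a pure function of its seed", {
  g1 <- simulateGenotypes(2, 6, 4, 10, 0.2, seed = 11)
  g2 <- simulateGenotypes(2, 6, 4, 10, 0.2, seed = 11)
  g3 <- simulateGenotypes(2, 6, 4, 10, 0.2, seed = 12)
  expect_identical(genotypes(g1), genotypes(g2))
  expect_false(identical(genotypes(g1), genotypes(g3)))

  p1 <- simulatePileups(g1, 20, 0.01, seed = 3)
  p2 <- simulatePileups(g1, 20, 0.01, seed = 3)
  expect_identical(SummarizedExperiment::assay(p1, "A"),
                   SummarizedExperiment::assay(p2, "A"))

  m1 <- simulateMkGenes(100, adaptiveFrac = 0.2, seed = 5)
  m2 <- simulateMkGenes(100, adaptiveFrac = 0.2, seed = 5)
  expect_identical(m1$counts, m2$counts)

  e1 <- simulateExpression(50, groups = rep(c("A", "B"), 3), seed = 7)
  e2 <- simulateExpression(50, groups = rep(c("A", "B"), 3), seed = 7)
  expect_identical(e1$counts, e2$counts)

  t1 <- simulateTranscriptome(10, seed = 9)
  t2 <- simulateTranscriptome(10, seed = 9)
  expect_identical(as.character(t1$sequences), as.character(t2$sequences))
  expect_identical(t1$orfs, t2$orfs)
})

test_that("pileup depths and heterozygote balance match the model", {
  pops <- setNames(rep(c("p1", "p2"), each = 2), sprintf("i%02d", 1:4))
  geno <- matrix(1L, 2500, 4, dimnames = list(NULL, names(pops)))
  gc <- makeCalls(geno, pops, contig = rep("c1", 2500),
                  pos = seq_len(2500) * 3L)
  sc <- simulatePileups(gc, meanDepth = 10, errorRate = 0, seed = 13)
  tot <- SummarizedExperiment::assay(sc, "A") +
    SummarizedExperiment::assay(sc, "G")
  # empirical mean depth within 2% at 10^4 draws
  expect_lt(abs(mean(tot) / 10 - 1), 0.02)
  # heterozygote minor-read fraction near one half
  frac <- sum(SummarizedExperiment::assay(sc, "G")) / sum(tot)
  expect_lt(abs(frac - 0.5), 0.02)
})

test_that("Balding-Nichols output recovers the target differentiation", {
  gc <- simulateGenotypes(nPops = 2, nPerPop = 15, nGenes = 100,
                          snpsPerGene = 50, targetFst = 0.25, seed = 17)
  fst <- snpFst(gc, c("pop1", "pop2"))
  expect_lt(abs(fstRatioOfSums(fst) - 0.25), 0.02)
  # near-zero F: the two populations look statistically identical
  gc0 <- simulateGenotypes(nPops = 2, nPerPop = 15, nGenes = 40,
                           snpsPerGene = 50, targetFst = 0.005, seed = 18)
  truth <- S4Vectors::metadata(gc0)$truth
  ks <- suppressWarnings(stats::ks.test(truth$popFreq[, 1],
                                        truth$popFreq[, 2]))
  expect_gt(ks$p.value, 0.01)
})

test_that("planted MK counts carry the configured adaptive fraction", {
  sim <- simulateMkGenes(2000, adaptiveFrac = 0.3, seed = 19)
  expect_lt(abs(alphaGenomewide(sim$counts)@alpha - 0.3), 0.05)
  sim0 <- simulateMkGenes(2000, adaptiveFrac = 0, seed = 20)
  expect_lt(abs(alphaGenomewide(sim0$counts)@alpha), 0.05)
  expect_equal(sim$truth$alpha, 0.3)
})

test_that("expression divergence recovers planted fold changes", {
  groups <- setNames(rep(c("A", "B"), each = 5), sprintf("s%02d", 1:10))
  sim <- simulateExpression(5000, groups = groups, dispersion = 0.1,
                            lfcSd = 1, seed = 21)
  norm <- normalizeExpression(sim$counts, sim$geneLengths)
  # eps = 0 so the pseudo-count cannot shrink the ratio; restrict to genes
  # deep enough that the log ratio is estimable
  d <- expressionDivergence(norm, groups, c("A", "B"), eps = 0)
  trueLfc <- abs(sim$truth$log2Offsets[, "B"] -
                   sim$truth$log2Offsets[, "A"])
  keep <- rowMeans(sim$counts) > 50 & is.finite(d$divergence)
  fit <- lm(d$divergence[keep] ~ trueLfc[keep])
  expect_lt(abs(coef(fit)[2] - 1), 0.1)
  # no planted change: divergence stays near zero on average
  sim0 <- simulateExpression(2000, groups = groups, dispersion = 0.1,
                             lfcSd = 0, seed = 22)
  norm0 <- normalizeExpression(sim0$counts, sim0$geneLengths)
  d0 <- expressionDivergence(norm0, groups, c("A", "B"))
  expect_lt(mean(d0$divergence), 0.25)
})

test_that("planted ORFs are recovered and empty contigs stay empty", {
  tx <- simulateTranscriptome(40, orfFrac = 0.75, seed = 23)
  found <- findOrfs(tx$sequences)
  m <- merge(tx$orfs, found, by = "gene")
  expect_equal(nrow(m), nrow(tx$orfs))
  expect_true(all(m$start.x == m$start.y & m$end.x == m$end.y &
                    m$strand.y == "+"))
  nonOrf <- setdiff(names(tx$sequences), tx$orfs$gene)
  expect_gte(mean(!(nonOrf %in% found$gene)), 0.95)
})

test_that("the study bundle writes every input file reproducibly", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  cfg <- smallFixtureConfig(12)
  p1 <- simulateStudy(d1, cfg, seed = 29)
  p2 <- simulateStudy(d2, cfg, seed = 29)
  for (f in c("fasta", "sites", "pops", "expression", "libhits",
              "goMap", "lnp")) {
    expect_true(file.exists(p1[[f]]))
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]))
  }
  # the site table is consumable with the generated population map
  pops <- readPopulationMap(p1$pops)
  sc <- readSiteTable(p1$sites, pops)
  expect_equal(ncol(sc), cfg$nPops * cfg$nPerPop)
})
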