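test_that("MK cells split on the FST threshold with D inclusive at 0.9", {
  snps <- data.frame(gene = "g1",
                     class = c("nonsynonymous", "synonymous",
                               "synonymous", "nonsynonymous"),
                     fst = c(0.95, 0.50, 0.92, 0.10))
  mk <- mkCounts(snps)
  expect_equal(unlist(mk[, c("Pn", "Ps", "Dn", "Ds")]),
               c(Pn = 1L, Ps = 1L, Dn = 1L, Ds = 1L))
  # boundary: exactly 0.9 counts as a substitution
  mkB <- mkCounts(data.frame(gene = "g", class = "synonymous", fst = 0.9))
  expect_equal(mkB$Ds, 1L)
  expect_equal(mkB$Ps, 0L)
  # undefined FST SNPs are dropped; gene retains a zero row
  mk0 <- mkCounts(data.frame(gene = "g", class = "synonymous",
                             fst = NA_real_))
  expect_equal(unlist(mk0[, c("Pn", "Ps", "Dn", "Ds")]),
               c(Pn = 0L, Ps = 0L, Dn = 0L, Ds = 0L))
})

test_that("G-test matches the frozen value and an independent oracle", {
  flat <- gTest(10, 10, 10, 10)
  expect_equal(flat$G, 0)
  expect_equal(flat$p.value, 1)
  # pooled two-species comparison table; frozen direct-summation value
  big <- gTest(104969, 147193, 3581, 3339)
  expect_equal(big$G, 279.293769222, tolerance = 1e-8)
  expect_lt(big$p.value, 1e-10)
  # doubling all cells doubles G
  expect_equal(gTest(20, 14, 8, 2)$G * 2, gTest(40, 28, 16, 4)$G,
               tolerance = 1e-12)
  expect_error(gTest(5, 5, 0, 0), "marginal")
  # random tables agree with the entropy-form computation
  set.seed(53)
  for (rep in 1:100) {
    x <- rpois(4, lambda = c(200, 300, 20, 15)) + 1L
    expect_equal(gTest(x[1], x[2], x[3], x[4])$G,
                 entropyG(x[1], x[2], x[3], x[4]), tolerance = 1e-9)
    expect_gte(gTest(x[1], x[2], x[3], x[4])$G, 0)
  }
})

test_that("alpha point estimates follow the cross-gene means formula", {
  neutral <- data.frame(gene = paste0("g", 1:5), Pn = 10, Ps = 10,
                        Dn = 10, Ds = 10)
  expect_equal(alphaGenomewide(neutral)@alpha, 0)
  adaptive <- data.frame(gene = paste0("g", 1:5), Pn = 10, Ps = 10,
                         Dn = 20, Ds = 10)
  expect_equal(alphaGenomewide(adaptive)@alpha, 0.5)
  # frozen arithmetic from the pooled two-species table
  pooled <- data.frame(gene = "all", Pn = 104969, Ps = 147193,
                       Dn = 3581, Ds = 3339)
  expect_equal(alphaGenomewide(pooled)@alpha, 0.335054577019,
               tolerance = 1e-9)
  # undefined when no substitutions
  noD <- data.frame(gene = "g", Pn = 5, Ps = 5, Dn = 0, Ds = 0)
  expect_true(is.na(alphaGenomewide(noD)@alpha))
})

test_that("alpha on a union of gene sets equals the pooled-count value", {
  set.seed(59)
  mk1 <- simulateMkGenes(150, adaptiveFrac = 0.2, seed = 60)$counts
  mk2 <- simulateMkGenes(250, adaptiveFrac = 0.4, seed = 61)$counts
  both <- rbind(mk1, mk2)
  a <- alphaGenomewide(both)@alpha
  tot <- colSums(both[, c("Pn", "Ps", "Dn", "Ds")])
  expect_equal(a, 1 - (tot["Ds"] * tot["Pn"]) / (tot["Dn"] * tot["Ps"]),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("bootstrap intervals behave at the degenerate boundaries", {
  one <- data.frame(gene = "g", Pn = 8, Ps = 10, Dn = 4, Ds = 2)
  est <- alphaBootstrap(one, B = 50, seed = 7)
  expect_equal(est@ciLow, est@alpha)
  expect_equal(est@ciHigh, est@alpha)
  # identical genes: zero-width interval under the means variant
  homog <- data.frame(gene = paste0("g", 1:20), Pn = 8, Ps = 10,
                      Dn = 4, Ds = 2)
  est2 <- alphaBootstrap(homog, B = 100, seed = 8)
  expect_equal(est2@ciLow, est2@ciHigh)
  expect_equal(est2@ciLow, est2@alpha)
  # threshold 1.0 with no fully fixed SNPs: all D cells zero, no crash
  snps <- data.frame(gene = rep(c("g1", "g2"), each = 3),
                     class = "synonymous", fst = runif(6, 0, 0.8))
  mk <- mkCounts(snps, fstThreshold = 1.0)
  expect_true(all(mk$Dn == 0))
  est3 <- alphaBootstrap(mk, B = 50, seed = 9)
  expect_true(is.na(est3@alpha))
  expect_true(est3@unreliable)
})

test_that("GO scan respects the size threshold and ranks planted signal", {
  set.seed(67)
  sim <- simulateMkGenes(400, adaptiveFrac = 0, seed = 68)
  counts <- sim$counts
  goMap <- rbind(
    data.frame(gene = counts$gene[1:49], go = "GO:small",
               description = "too small"),
    data.frame(gene = counts$gene[50:149], go = "GO:null",
               description = "background"),
    data.frame(gene = counts$gene[150:249], go = "GO:hot",
               description = "planted"))
  # plant a doubled substitution excess in the hot category
  hot <- counts$gene %in% counts$gene[150:249]
  counts$Dn[hot] <- counts$Dn[hot] + rpois(sum(hot), 2)
  res <- goAlphaScan(counts, goMap, minGenes = 50, B = 200, seed = 69)
  expect_false("GO:small" %in% res$go)
  expect_equal(res$go[1], "GO:hot")
  expect_true(res$top5[res$go == "GO:hot"])
  expect_gt(res$alpha[res$go == "GO:hot"],
            res$alpha[res$go == "GO:null"])
  # a uniform random category stays consistent with the genome-wide value
  genome <- alphaBootstrap(counts[!hot, ], B = 200, seed = 70)
  nullAlpha <- res$alpha[res$go == "GO:null"]
  expect_gt(nullAlpha, genome@ciLow - 0.25)
  expect_lt(nullAlpha, genome@ciHigh + 0.25)
})
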