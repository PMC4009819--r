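test_that("codon site fractions are consistent with the genetic code", {
  # third-position Phe: TTT->TTC synonymous only (TTA/TTG are Leu)
  expect_equal(codonSiteFractions("TTT"), c(syn = 1 / 3, nonsyn = 8 / 3))
  # fourfold degenerate third position: GGA
  expect_equal(codonSiteFractions("GGA")[["syn"]], 1,
               tolerance = 1e-12)
  # Met has no synonymous change
  expect_equal(codonSiteFractions("ATG")[["syn"]], 0)
  expect_true(all(is.na(codonSiteFractions("TAA"))))
  expect_true(all(is.na(codonSiteFractions("ANA"))))
})

test_that("SNP classification distinguishes synonymous changes and stops", {
  expect_equal(as.character(classifySnp("GGA", 3, "G")), "synonymous")
  expect_equal(as.character(classifySnp("ATG", 2, "C")), "nonsynonymous")
  # first-position Leu degeneracy: TTA -> CTA
  expect_equal(as.character(classifySnp("TTA", 1, "C")), "synonymous")
  stopHit <- classifySnp("TAC", 3, "A")   # Tyr -> stop
  expect_equal(as.character(stopHit), "nonsynonymous")
  expect_true(attr(stopHit, "stop"))
})

test_that("the ORF finder returns the longest open-ended stop-free run", {
  set.seed(31)
  # 399 nt with no stop in forward frame 0
  s <- randomCds(133)
  orf <- findOrf(s)
  expect_equal(orf$start, 1L)
  expect_equal(orf$end, 399L)
  expect_equal(orf$strand, "+")
  # best stop-free run of 250 nt in every frame -> none at min 300
  short <- paste0(randomCds(40), "TAA", randomCds(40), "TAA",
                  randomCds(40))
  expect_null(findOrf(short, 300L))
})

test_that("minus-strand ORFs are reported in forward coordinates", {
  set.seed(37)
  # build a sequence whose reverse complement holds the clean run
  coding <- randomCds(120)                      # 360 nt stop-free
  insert <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(paste0("TAA", coding, "TAA"))))
  lead <- "TAGTAGTAGTAGTAGTAG"
  s <- paste0(lead, insert, "TAGTAGTAGTAGTAG")
  orf <- findOrf(s, 300L)
  expect_equal(orf$strand, "-")
  # exhaustive check: extractions equal the planted run
  sub <- substr(s, orf$start, orf$end)
  back <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sub)))
  expect_equal(back, coding)
  expect_equal(orf$length, 360L)
})

test_that("species consensus substitutes the major allele with ties to ref", {
  pops <- setNames(rep(c("sp1", "sp2"), each = 5), sprintf("i%02d", 1:10))
  ref <- Biostrings::DNAStringSet(c(g1 = randomCds(110)))
  orfs <- findOrfs(ref, 300L)
  expect_equal(nrow(orfs), 1L)
  refseq <- as.character(ref[[1]])
  base5 <- substr(refseq, 5, 5)
  alt5 <- setdiff(c("A", "C", "G", "T"), base5)[1]
  # sp1 mostly alt (9 of 10 copies), sp2 tied 5:5
  geno <- rbind(c(2L, 2L, 2L, 2L, 1L, 2L, 2L, 1L, 0L, 0L))
  gc <- makeCalls(geno, pops, contig = "g1", pos = 5L,
                  alleleA = base5, alleleB = alt5)
  cons1 <- speciesConsensus(gc, orfs[1, ], ref, "sp1")
  cons2 <- speciesConsensus(gc, orfs[1, ], ref, "sp2")
  expect_equal(substr(cons1, 5, 5), alt5)   # sp1 major allele: 9 alt vs 1
  expect_equal(substr(cons2, 5, 5), base5)  # 5:5 tie -> reference base
  # no SNPs -> consensus is the reference ORF
  gcEmpty <- gc[0, ]
  expect_equal(speciesConsensus(gcEmpty, orfs[1, ], ref, "sp1"), refseq)
})

test_that("NG86 counting matches an independent site-count oracle", {
  # identical sequences
  s <- "ATGGCTGCTAAAGCTTGA"
  s <- substr(s, 1, 15)  # strip the stop codon
  r <- ng86DnDs(s, s)
  expect_equal(r$dN, 0)
  expect_equal(r$dS, 0)
  expect_true(is.na(r$ratio))
  # single synonymous difference in a 300-nt pair: AAA -> AAG
  set.seed(41)
  s1 <- paste0(randomCds(99), "AAA")
  s2 <- paste0(substr(s1, 1, 297), "AAG")
  r <- ng86DnDs(s1, s2)
  expect_equal(r$dN, 0)
  Sbar <- (oracleSynSites(s1) + oracleSynSites(s2)) / 2
  pS <- 1 / Sbar
  expect_equal(r$dS, -0.75 * log(1 - 4 * pS / 3), tolerance = 1e-12)
  expect_true(is.na(r$ratio))  # dN = 0 -> gene discarded downstream
  # single nonsynonymous difference: ratio undefined because dS = 0
  s3 <- paste0("ATG", substr(s1, 4, 300))
  s4 <- paste0("CTG", substr(s1, 4, 300))
  r2 <- ng86DnDs(s3, s4)
  expect_equal(r2$dS, 0)
  expect_gt(r2$dN, 0)
  expect_true(is.na(r2$ratio))
  # symmetry
  rAB <- ng86DnDs(s1, s2)
  rBA <- ng86DnDs(s2, s1)
  expect_equal(rAB[c("dN", "dS", "Sd", "Nd")], rBA[c("dN", "dS", "Sd", "Nd")])
  expect_error(ng86DnDs(s1, substr(s2, 1, 294)), "equal length")
})

test_that("purely synonymous or nonsynonymous divergence hits one axis", {
  set.seed(43)
  fourfold <- c("GGT", "GCT", "CCT", "ACT", "TCT", "CGT", "GTT", "CTT")
  for (rep in 1:10) {
    cods <- sample(fourfold, 80, replace = TRUE)
    s1 <- paste(cods, collapse = "")
    cods2 <- cods
    idx <- sample(80, 6)
    for (i in idx)  # third-position change within a fourfold box: synonymous
      substr(cods2[i], 3, 3) <- sample(setdiff(c("A", "C", "G", "T"),
                                               substr(cods2[i], 3, 3)), 1)
    s2 <- paste(cods2, collapse = "")
    r <- ng86DnDs(s1, s2)
    expect_equal(r$dN, 0)
    expect_gt(r$dS, 0)
  }
})

test_that("coding SNPs are classified in reference codon context", {
  pops <- setNames(rep(c("sp1", "sp2"), each = 2), sprintf("i%02d", 1:4))
  ref <- Biostrings::DNAStringSet(c(
    g1 = paste0("ATG", "GGA", paste(rep("GCT", 98), collapse = ""))))
  orfs <- findOrfs(ref, 300L)
  # SNP at pos 6: GGA third position A<->G is synonymous
  # SNP at pos 7: GCT first position G<->A (Ala->Thr) nonsynonymous
  geno <- rbind(c(0L, 0L, 2L, 2L), c(0L, 1L, 1L, 2L))
  gc <- makeCalls(geno, pops, contig = "g1", pos = c(6L, 7L),
                  alleleA = c("A", "G"), alleleB = c("G", "A"))
  cls <- classifyCodingSnps(gc, orfs, ref)
  expect_equal(cls$class[cls$pos == 6], "synonymous")
  expect_equal(cls$class[cls$pos == 7], "nonsynonymous")
  # SNP outside the ORF is ignored
  gcOut <- makeCalls(geno, pops, contig = "g1", pos = c(6L, 400L),
                     alleleA = c("A", "G"), alleleB = c("G", "A"))
  expect_equal(nrow(classifyCodingSnps(gcOut, orfs, ref)), 1L)
})
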