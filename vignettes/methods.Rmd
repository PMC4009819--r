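---
title: "Methods: from RNA-seq base counts to determinants of protein evolution"
author: "rnaPopGen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from RNA-seq base counts to determinants of protein evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnaPopGen)
```

# Scope and data model

`rnaPopGen` analyses transcriptome-wide polymorphism, divergence and
expression for a set of closely related, hybridizing species whose RNA-seq
reads have been aligned to a shared reference transcriptome. The package
starts *after* alignment: its elementary input is a per-site, per-individual
table of A/C/G/T read counts (`SiteCounts`, a `RangedSummarizedExperiment`
with one assay per base). Everything downstream — genotypes
(`GenotypeCalls`), per-gene statistics, McDonald–Kreitman tables,
expression metrics, partial correlations — derives from that table, a
reference FASTA, a population map, an expression count matrix, a
tissue-library hit matrix and a gene→GO map. Read cleaning, alignment and
transcriptome assembly are out of scope, as is the Bayesian clustering MCMC
itself (only the ΔK model-choice statistic is implemented).

# Genotype calling and site filters

Calling is count-driven; the reference base plays no role. At each site the
two alleles are the two bases with the highest read counts pooled over all
individuals (ties resolved toward the alphabetically smaller base). A site
is rejected when the third-ranked base exceeds 5% of all pooled reads
(`thirdAlleleMaxFrac`) — true tri-allelic SNPs are rare, so such sites are
better explained by collapsed paralogs or alignment artifacts.

Per individual, depth is counted over the two site alleles only; reads on
other bases are treated as sequencing error. The rules, with defaults in
`callingConfig()`:

* depth < 3 → missing call;
* heterozygous iff the minor allele has ≥ 3 reads ("more than two") *and*
  a minor read fraction ≥ 10%;
* otherwise homozygous for the individual's major allele.

Site-level retention requires ≤ 20% missing individuals, expected
heterozygosity He = 2p(1−p) > 0.2 (pooled allele frequency over non-missing
calls, uncorrected for sample size — the threshold is a coarse screen and
the simplest reading of the rule), and observed heterozygosity Ho < 0.6
(an excess of heterozygotes across individuals is the signature of
paralogous loci collapsed onto one contig). Boundary semantics are exactly
as stated: 20% missing passes; He = 0.2 and Ho = 0.6 fail. Whether He
should be sample-size corrected, and whether the minor-allele fraction
should include non-allele reads, are genuinely open readings; both are
exposed as configuration, with the defaults above.

# Differentiation, diversity, ΔK

Per-SNP differentiation uses the Weir–Cockerham (1984) variance components
for diploids: `a` (among populations), `b` (among individuals within
populations), `c` (within individuals), and θ̂ = a/(a+b+c). θ̂ may be
legitimately negative and such values are retained in per-gene means —
truncating at zero would bias averages upward. The per-gene statistic is
the arithmetic mean of defined per-SNP θ̂ (sites monomorphic in the pair
are flagged undefined and skipped); the multi-locus ratio-of-sums estimate
Σa/Σ(a+b+c) is also provided (`fstRatioOfSums`) and is the quantity used in
estimator-recovery checks, because the mean of per-SNP ratios is a noisier,
slightly biased summary — the package reports both and the documentation is
explicit about which is which.

Nucleotide diversity is computed per gene as
π = Σ_sites [nₛ/(nₛ−1)]·2p̂ₛ(1−p̂ₛ)/L with per-site allele-copy counts nₛ
varying with missingness; this equals the mean pairwise difference per site
(tested against brute-force pair enumeration, exactly). Watterson's
θ_W = S/(a_{n−1}L) takes n as the median non-missing allele-copy count of
the gene — the estimator needs one n per gene, and the median is robust to
a few low-coverage sites.

ΔK follows the Evanno construction: per replicate run, the second
difference L''(K) = L(K+1) − 2L(K) + L(K−1) of the clustering
log-likelihood; ΔK(K) = mean(|L''(K)|)/sd(L(K)). Endpoints are undefined,
as is any K with zero replicate variance (flagged rather than infinite).
Equal replicate counts per K are required.

# Coding sequence analysis

The reading-frame finder scans all six frames for maximal stop-free codon
runs, open-ended (no start codon required; runs may abut contig ends —
transcriptome contigs routinely truncate UTRs and even coding ends), and
keeps the longest run ≥ 300 nt, ties resolved deterministically (+ strand,
lowest frame, lowest start). "≥ 300" is adopted as the threshold semantics.

For each species, a consensus coding sequence substitutes the major allele
(by allele-copy count among that species' called genotypes) at every SNP
inside the ORF; ties keep the reference base, making the consensus
conservative. dN/dS between the two consensus sequences uses Nei–Gojobori
(1986) counting: synonymous site totals from the 1/3-fraction rule averaged
over both sequences; observed differences pathway-averaged over all
substitution orders in multi-hit codons; Jukes–Cantor correction
d = −(3/4)·ln(1 − 4p/3). Two deliberate conventions: mutations creating a
stop codon count as nonsynonymous (so per-codon site fractions sum to
exactly 3 — an invariant the tests assert for all 61 sense codons), and
codons containing N in either sequence are skipped and counted. A
maximum-likelihood codon model (accounting for codon usage and GC content)
would be the heavier alternative; at the low divergences this pipeline
targets (dS ≪ 0.1) counting and ML estimates agree closely, the counting
route is dependency-free and fast, and the module exposes raw counts
(Sd, Nd, S̄, N̄) so an ML backend could be substituted. Genes with dN = 0
or dS = 0 have an undefined ratio — not 0 or ∞ — and are excluded from
ratio-based analyses.

# McDonald–Kreitman with FST-threshold substitutions

Between species that still exchange genes, almost no site is truly fixed;
the MK "divergence" class is therefore defined as SNPs with pairwise
F_ST ≥ 0.9 (threshold inclusive), all remaining coding SNPs being
polymorphisms. Each SNP lands in exactly one cell of (Pn, Ps, Dn, Ds); a
configuration flag can additionally count D SNPs as polymorphisms for
sensitivity analyses. The pooled 2×2 table is tested with the likelihood
ratio G = 2ΣO·ln(O/E) on 1 df; the Williams correction is available but
off by default (it is negligible at transcriptome-scale counts).

The adaptive fraction is estimated as α = 1 − (D̄s·P̄n)/(D̄n·P̄s), all
averages across genes — algebraically identical to the pooled-count
estimate on the same gene set. A second variant,
α = 1 − (D̄s/D̄n)·mean(Pnᵢ/(Psᵢ+1)) (`"sew_ps1"`), implements the
per-gene-ratio form with a +1 guard on Ps; both are provided because the
published formulation is ambiguous between them, and on pooled
transcriptome-scale counts they differ. Confidence intervals are
percentile bootstrap over genes (default B = 1000, seeded; resamples with
undefined α are dropped and counted, and the interval is flagged
unreliable past 50% undefined). GO categories with ≥ 50 genes are scanned
with the same machinery and the top five per pair flagged.

# Expression metrics

Raw counts are divided by each library's median over genes with ≥ 1 read —
a median over all genes can be zero in sparse libraries — then by gene
length in kb. Full RPKM-style total-count scaling is deliberately avoided:
totals are dominated by a few extreme genes, medians are not. Expression
divergence per gene is |log2((m₁+ε)/(m₂+ε))| on species-group means of
normalized expression, ε = 0.5 by default (ε = 0 is allowed and yields
flagged infinities for group-exclusive genes; the mean is taken before the
log, i.e. the statistic is a ratio of group means). Tissue specificity is
S − (libraries with ≥ 1 hit) over S = 11 libraries; because hit tables
from shallow sequencing miss lowly expressed genes, shallow sampling
inflates specificity — a caveat that carries into any correlation
involving it.

# Partial correlations

The per-gene table joins log(dN/dS) (natural log; the base shifts scales,
not correlations), mean F_ST, π, specificity, log mean normalized
expression over the pair's individuals, and expression divergence. Genes
enter only when dN > 0 and dS > 0 and mean normalized expression reaches
`minExpression` (default 14, interpreted as a per-gene mean; the exact
construction of that floor is an open reading). Partial correlations come
from the precision matrix Ω = R⁻¹ of the Pearson correlation matrix,
r_ij·rest = −Ω_ij/√(Ω_ii·Ω_jj), with two-sided p-values from
t = r√((n−2−g)/(1−r²)), g = k−2, df = n−2−g. For k = 2 this reduces
exactly to Pearson's test; for k = 3 it agrees with the recursive
first-order formula to numerical precision (tested to 1e−10). p-values are
reported raw (no multiplicity correction by default; Benjamini–Hochberg is
a flag away via `p.adjust`).

One mechanism deserves a warning label: with RNA-seq, SNP discovery power
rises with coverage, and coverage *is* expression. Detected π therefore
correlates positively with expression level even when true diversity is
flat. The test suite demonstrates the direction of this artifact on
simulated data and shows that raising the expression floor shrinks it;
magnitudes are data-dependent and deliberately not asserted.

# The synthetic study

The generators define the conditions under which the pipeline is
validated:

* **Genotypes**: ancestral minor-allele frequencies Uniform(0.05, 0.5),
  population frequencies Balding–Nichols Beta(p(1−F)/F, (1−p)(1−F)/F),
  diploid genotypes binomial. Balding–Nichols is used instead of a
  coalescent because it is parameterized directly by F_ST, which is what
  the recovery checks need; it produces no linkage disequilibrium and no
  demographic history, so passing tests say nothing about those.
* **Pileups**: depth Poisson, allele reads binomial(depth, dose/2),
  per-read miscalls uniform over the other bases. No mapping bias, indels
  or base-quality structure.
* **Transcriptomes**: a configured fraction of contigs carries a planted
  stop-free frame ≥ 300 nt at recorded coordinates; all competing runs
  long enough to displace it are disrupted with injected stops, and
  contigs without a planted frame are repaired until no qualifying run
  remains, so finder recovery can be asserted exactly.
* **MK counts**: Ps ~ Pois(λ), Pn ~ Pois(rλ), Ds ~ Pois(μ),
  Dn ~ Pois(rμ) + Pois(rμ·a/(1−a)), so the expected α equals the planted
  a. λ = 12 and r = 0.7 mirror the per-gene polymorphism scale of a deep
  two-species transcriptome comparison. μ defaults to 3: the standard
  error of α̂ at G genes is ≈ √(2/(μG))·(1−a), so μ = 3 puts a
  2,000-gene recovery within ±0.02 (one SE) and makes the ±0.05 recovery
  assertion a ≈ 3σ bound; a μ below ~1 would leave that assertion at the
  mercy of Monte-Carlo noise rather than estimator quality.
* **Expression**: negative-binomial counts, lognormal baselines, uniform
  library size factors, per-group log2 offsets with configurable spread.
* **The bundled study** (`smallFixtureConfig()`): 3 populations × 8
  diploids, 200 contigs of 0.5–1.6 kb, ~3 candidate SNPs per 100 bp,
  Balding–Nichols differentiation 0.25, median depth 25, error rate 0.005
  — the shape of a multi-species seedling-transcriptome experiment at
  desk scale. Its `minExpression` is 0.5 rather than 14 because the floor
  lives on the normalized-expression scale of the data at hand: the
  fixture's libraries are shallower and its median-normalized values
  correspondingly smaller, and the floor is meant to remove the lowest
  tier of genes, not most of them. Problem sizes throughout the test
  suite (5,000-SNP recovery panels, 2,000-gene α panels, 200-gene
  end-to-end runs) are chosen so the full suite exercises every claim at
  meaningful precision while remaining a few minutes of compute.

Alleles at simulated SNPs are drawn uniformly, so the fixture's Pn/Ps
ratio (~3) reflects the genetic code, not purifying selection; the fixture
validates machinery, and no test asserts a selection-like Pn/Ps on it.

# Numerical and degenerate-input conventions

Positions are 1-based inclusive everywhere visible; VCF output follows the
v4.2 GT conventions with missing calls as `./.`. Monomorphic sites drop
out of F_ST (undefined, flagged) rather than contributing zeros. The
Jukes–Cantor correction is undefined at p ≥ 3/4 (gene flagged
`saturated`). α is undefined (NA, never ±∞) when D̄n or P̄s is zero — e.g.
an F_ST threshold of 1.0 with no fully fixed SNPs. The G-test refuses
tables with a zero margin. Partial correlation reports the most collinear
pair when the correlation matrix is singular. All generators are pure
functions of (configuration, seed), and the pipeline writes a manifest
with package version, seed and parameters so a report can be regenerated
byte for byte.

# Known limitations

The counting dN/dS ignores codon-usage bias and GC content; transition /
transversion asymmetry is not modeled. Consensus sequences hide
within-species polymorphism at the divergence step (standard for this
design, but it discards information an ML method over alignments could
use). The FST-threshold definition of "substitution" is a pragmatic proxy
whose counts depend on the threshold; 0.9 is the adopted convention and
the threshold is configurable. Specificity from shallow hit tables is
upward biased for lowly expressed genes. The simulators generate free
recombination (no LD), equilibrium demography and error-free alignment;
conclusions about real data inherit none of the robustness that would
require modeling those.
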