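---
title: "Forensic and population-genetic analysis of autosomal STR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forensic and population-genetic analysis of autosomal STR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strpopgen)
```

## Scope and data model

strpopgen implements the statistical sequence of a classical short tandem
repeat (STR) population study: per-locus forensic efficiency parameters,
Hardy-Weinberg equilibrium (HWE) and linkage-equilibrium testing,
Nei's DA genetic distances between populations, neighbor-joining (NJ)
tree construction, classical multidimensional scaling (MDS), and
principal component analysis (PCA) of allele-frequency vectors, plus a
drift simulator that manufactures inputs with the statistical structure
these analyses assume.

Two containers carry the data. A `freq_table` holds one population's
per-locus allele frequencies plus the gene-copy count 2N they were
estimated from; the package ships one as a worked fixture, a
transcription of a published 22-locus table for a Han population sample
of 590 individuals (2N = 1180). A `genotype_table` holds unordered
per-individual allele pairs; published studies rarely release one, so the
simulator stands in for it. Allele labels are strings ordered by numeric
repeat value, which interleaves microvariants correctly (15 < 15.3 < 16).

One transcription judgement call is documented in the fixture header: the
source text of the published table yields 246 alleles against the
published census of 247, and exactly one locus (D6S477) under-sums by one
minimum-frequency unit, so a single D6S477 allele with frequency 0.0008
was restored. Its frequency is forced by the sum and census constraints;
its repeat label (recorded as "20") could not be confirmed.

## Forensic parameters

For allele frequencies $p_i$ at a locus with 2N gene copies:

* expected heterozygosity, unbiased form:
  $He = \frac{2N}{2N-1}\left(1 - \sum_i p_i^2\right)$. The correction is
  applied on gene copies, which reproduces the published per-locus values
  from the fixture (e.g. He = 0.7474 at the least polymorphic locus).
* polymorphism information content:
  $PIC = 1 - \sum_i p_i^2 - \left(\sum_i p_i^2\right)^2 + \sum_i p_i^4$.
* matching probability MP is the sum of squared *observed* genotype-class
  frequencies, and PD = 1 - MP. Computing MP from observed classes rather
  than HWE expectations follows the PowerStats convention; it means
  MP/PD (and their combined forms) require genotypes and are reported as
  unavailable in frequency-only mode rather than guessed.
* probability of exclusion from observed heterozygosity $h$ (with
  $H = 1-h$): $PE = h^2(1 - 2hH^2)$, again the PowerStats convention; it
  reproduces both published extremes (0.4940 at Ho = 0.7407 and 0.7713 at
  Ho = 524/590) and is strictly increasing in $h$.

Combined powers multiply across loci: $CPD = 1 - \prod_l MP_l$ and
$CPE = 1 - \prod_l (1 - PE_l)$. For a 22-locus panel the residual product
is of order $10^{-28}$, which a double cannot express as $1 - p$; such
values are conventionally printed to more than 30 significant digits.
`one_minus_decimal()` therefore expands $1-p$ by exact digit-string
subtraction from the decimal representation of the double-precision
product. The product itself carries 15-16 significant digits, far more
than the expansion needs.

Report output is rounded to 4 decimal places; all internal computation is
full precision.

## Equilibrium testing

`hwe_exact_mc()` is a Monte-Carlo exact test in the Guo-Thompson spirit:
the 2N observed gene copies are shuffled into N random pairs, each
labelled pairing being equally likely under the null of random union of
gametes, and the p-value is the fraction of shuffles whose conditional
genotype-array probability (given allele counts) is at most the observed
one. Full enumeration is infeasible at 16-allele loci, which is why the
Monte-Carlo form is the default (10,000 shuffles; Monte-Carlo standard
error of p at most 0.005). Numerical choices: the p-value uses the
add-one rule $(b+1)/(n_{perm}+1)$ so it is never zero; the shuffle pool
is put into canonical sorted order first, making the result invariant to
the order individuals are supplied in; statistic comparisons use a 1e-9
slack so ties of the log-probability are counted as ties. The test suite
checks the estimator against exhaustive enumeration of all pairings on
small cases, and checks type-I error and power (against inbreeding)
by simulation. A Pearson chi-square with expected-below-1 pooling is
included purely as a large-sample cross-check.

Linkage disequilibrium is tested on genotype (not haplotype) classes,
since raw STR data are unphased: the statistic is the G2 log-likelihood
ratio of the two-locus genotype contingency table and the null permutes
one locus across individuals. The descriptive composite r2 estimates
two-locus haplotype frequencies by EM (double heterozygotes split
between their two phasings; everything else phases uniquely) and
aggregates per-allele-pair $r^2_{ij} = D_{ij}^2 / (p_i(1-p_i)q_j(1-q_j))$
as the frequency-weighted mean $\sum_{ij} p_i q_j r^2_{ij}$. The
aggregation rule for multi-allelic loci is genuinely open in the
literature; the weighted mean was chosen because it is bounded in [0, 1]
and collapses to the standard r2 for biallelic loci — note it sits well
below 1 even for perfectly duplicated multi-allelic loci, because
off-diagonal allele pairs contribute less-than-unit terms. EM defaults:
convergence when no haplotype frequency moves by more than 1e-6
(frequencies are only reported to a few decimals), iteration cap 10,000,
non-convergence returned with a warning flag rather than an error.

Bonferroni corrections are reported, never silently applied: for 22 loci
the HWE threshold is 0.05/22, and for the C(22,2) = 231 locus pairs the
LD threshold is 0.05/231. Both raw and corrected decisions are returned,
since a locus can fail the raw test yet pass after correction. One
practical interaction matters: an add-one permutation p-value can never
fall below $1/(n_{perm}+1)$, so resolving a Bonferroni threshold of
0.0005 needs at least 9,999 permutations (the analysis scripts do this).

## Distances, differentiation, trees, ordination

Nei's DA between populations x and y over a shared panel of r loci is
$D_A = 1 - \frac{1}{r}\sum_j \sum_i \sqrt{x_{ij} y_{ij}}$. Allele spaces
are unioned per locus with absent alleles at frequency zero, so the value
is invariant to padding and ordering. DA is a premetric on [0, 1]; the
triangle inequality is not asserted.

Locus-by-locus differentiation between two populations is tested by an
allele-permutation homogeneity test: G2 of the 2 x k allele-count table,
null generated by reassigning the pooled gene copies preserving totals.
Published studies often run genotype-level AMOVA here, but reference
populations are published only as frequency tables; the permutation test
addresses the same null (no frequency differentiation at the locus) from
exactly the data that exist, with integer counts recovered as
round(p * 2N) floored at one copy. The Bonferroni family size m for a
focal-population design is exposed explicitly (pairs x loci) because
published family sizes are often stated without derivation.

Neighbor joining follows Saitou-Nei with the Studier-Keppler Q-criterion;
ties in argmin Q resolve to the lowest (row, column) pair in current
order so runs are deterministic, and negative branch lengths are clamped
to zero with the clamped magnitude reported (the conventional display
rule). On additive matrices the tree is exact (checked to 1e-9 on random
additive trees up to 12 taxa). Serialization roots the unrooted tree as a
trifurcation at the final join; two-taxon trees split the edge at its
midpoint.

MDS is classical/metric (Torgerson double-centering via `cmdscale`),
chosen over nonmetric stress optimization because it is deterministic and
testable against exact geometry: negative eigenvalues are truncated to
zero and their magnitude reported. PCA operates on the population x
(locus, allele) frequency matrix, column-centered but not scaled since
frequencies share a scale (covariance PCA, the MVSP-style default for
such data); at most min(populations - 1, features) components carry
variance.

## The simulator

The generator produces what the analyses consume — frequency tables and
genotype tables — rather than mutational histories, so a
Dirichlet/Balding-Nichols parameterization was chosen over coalescent
simulation: it has closed-form moments that the test suite can check.
Ancestral locus frequencies are symmetric Dirichlet(alpha) draws with
allele counts uniform on 7-16 (the span of the fixture's panel, from its
least to most polymorphic locus) and STR-like labels including ".3"
microvariants at rate 0.1 to exercise fractional ordering. Descendants
draw Dirichlet$(p(1-\theta)/\theta)$ around the ancestor, giving
$E[\tilde p_i] = p_i$ and $Var[\tilde p_i] = \theta p_i (1-p_i)$.
Genotypes follow the inbreeding law
$P(ii) = p_i^2 + f p_i(1-p_i)$, $P(ij) = 2p_ip_j(1-f)$, implemented by
copying one gamete with probability f. All generators are
bit-reproducible under a fixed seed; frequencies are floored at 1e-12
before renormalization so that validation's strict positivity always
holds.

What the synthetic data do and do not emulate: they reproduce
multi-allelic frequency spectra, HWE or inbreeding-perturbed genotype
proportions, and frequency-level drift between populations. They do not
model mutation processes (no stepwise mutation), genotyping artifacts
(stutter, allelic dropout), close kinship, or real geographic structure;
a passing suite therefore demonstrates statistical correctness of the
machinery, not robustness to those real-data complications.

## Problem sizes and reproducibility

The simulation-based checks run at sizes chosen to keep Monte-Carlo error
comfortably inside the asserted tolerances while finishing quickly:
type-I error of the HWE test on 1,000 cohorts of N = 500 at an 8-allele
locus (standard error of the rejection rate ~0.007 against a +/-0.02
band); power at f = 0.3 on 200 cohorts; LD null calibration on 1,000
independent-locus cohorts of N = 100; drift monotonicity on 50 replicates
per theta in {0.001, 0.01, 0.05, 0.1, 0.2}; and a 14-population,
590-diploid, 15-locus end-to-end scenario with 50 reduced (N = 200)
replicates for the two-tier topology-recovery check. Every stochastic
entry point demands an explicit seed and is deterministic given it; the
pipeline writes seeds and thresholds into its run manifest, and repeated
runs are byte-identical outside the manifest's timestamp.

## Known limitations

* Frequency-only inputs cannot yield MP, PD, CPD or observed Ho; the
  summary marks them unavailable instead of substituting HWE
  expectations.
* The composite r2 aggregation for multi-allelic loci is one defensible
  convention among several; compare like with like across studies.
* Reconstructed integer counts inherit the rounding of 4-decimal
  published tables; per-locus count sums may deviate from 2N by up to
  about half the allele count, and the differentiation test consumes
  those reconstructed counts as-is.
* The NJ tie-break makes runs deterministic but, on exactly tied
  matrices, the reported topology is one of several equally optimal
  trees.
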