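---
title: "Detecting parallel ecomorph divergence and introgression in lake radiations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting parallel ecomorph divergence and introgression in lake radiations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radscan)
```

## The problem

Postglacial lake radiations — Alpine whitefish are the motivating system —
repeatedly produce the same ecological forms ("ecomorphs") in different
lakes: a large benthic form ("Balchen"), a small zooplanktivorous form
("Albeli"), intermediates ("Felchen"), and rarer profundal and pelagic
specialists. Three questions drive the analyses this package implements:

1. **Are the same genomic regions shifted in parallel between ecomorphs
   across lakes?** Answered with a windowed cluster separation score (CSS)
   scan against a lake-stratified permutation null, and with per-lake
   Weir–Cockerham F\_ST outlier scans whose cross-lake overlap is compared
   to an analytic expectation.
2. **Did each sympatric species pair arise within its lake, or did the
   ecomorphs evolve once and sort into lakes?** Answered with four-taxon F4
   topology contrasts.
3. **Which species exchanged genes, and how much?** Answered with
   tree-guided excess allele-sharing: Patterson's D, f4-admixture ratios
   f(A, B; C, O), and the branch-specific f-branch statistic f_b(C), with
   block-jackknife Z-scores and a Bonferroni Z threshold.

A synthetic radiation generator with full ground truth makes every stage
testable end to end without access to real resequencing data.

## Data model

Genotypes are held as a samples × SNPs matrix of alternate-allele dosages
(0/1/2, complete — the scans assume a zero-missingness filter regime was
applied upstream), read from a biallelic multi-sample VCF. Sample metadata
carries lake, lake system, species, ecomorph, sex and two quantitative
traits (standard length, gill-raker count). Coordinates follow one rule
throughout: VCF positions stay 1-based; all internal windows, tracts, and
BED-style intervals are 0-based half-open, and conversions happen only at
the file boundary (GFF3's 1-based closed intervals are converted on read).
A SNP at 1-based position p belongs to window floor((p−1)/size).

## The cluster separation score

For one window, pairwise individual distances are Euclidean distances of
dosage vectors divided by the window's SNP count. Individuals are embedded
by classical multidimensional scaling, retaining every positive-eigenvalue
axis; because classical MDS on a Euclidean distance matrix is
distance-preserving, this embedding is exact rather than approximate, and

CSS = mean between-group distance −
(m·within₁ + n·within₂)/(m + n),

with within-group means over the 2/(k(k−1)) unordered pairs. CSS is zero
when the groups are indistinguishable and grows with between-group
separation relative to within-group spread. It is invariant to SNP order
and label swapping; both properties are unit-tested, as is agreement with
a brute-force evaluation of the definition.

**The stratified permutation null.** Ecomorph labels are reshuffled within
each lake (stratum), preserving per-stratum group counts, so lake-level
population structure survives under the null and only ecomorph assignment
is broken. One shared set of label permutations is evaluated against all
windows — consistent with a genome-wide null and vectorisable as a single
matrix product of per-window pair distances against per-permutation pair
weights. Sampled p-values use the add-one estimator
p = (1 + #{perm ≥ obs})/(1 + N), which can never return zero (important
because the p-values feed an FDR step); the identity permutation is allowed
in the sampled set since the add-one rule already guards the bias. When the
number of distinct stratified assignments is at most 200,000 the scan
switches to exact enumeration and reports the exact tail proportion
instead. Windows with fewer than 24 SNPs are removed before testing;
outliers are windows with Benjamini–Hochberg q ≤ 0.01 (a Storey-type
estimator with spline-smoothed π₀ on a 0.05–0.95 λ grid is available;
with π₀ = 1 it reduces to BH exactly).

Downstream, SNPs inside outlier windows are LD-pruned (r² > 0.1 within
50 kb by default, matching the aggressive pruning conventionally applied
before PCA) and decomposed by SVD; PC signs are fixed so each loading sum
is non-negative. Trait–PC1 regressions are ordinary least squares with the
F-test p-value, overall and per lake system.

## Windowed Weir–Cockerham F\_ST

Per SNP the 1984 two-level variance components a (among populations),
b (among individuals) and c (within individuals, the heterozygosity term)
are computed from genotype counts; θ = a/(a+b+c) and may legitimately be
negative — negative components are retained in window sums. Windows report
both the ratio-of-sums ("weighted") estimate Σa/Σ(a+b+c) and the mean of
per-SNP θ; outlier ranking uses the weighted estimate, the conventional
headline of windowed F\_ST tools, while both are emitted so either
convention can be reproduced. Loci with minor allele count below 1 within
the pair are removed first; windows with fewer than 10 usable SNPs are
dropped. "Top percentile" outliers are the ⌈0.01·W⌉ highest windows by
rank — a count rule rather than a quantile threshold, so the analytic
overlap expectation q^k · W · C(L, k) holds by construction; ties are
broken by genomic order. The implementation is pinned to an independent
equation-by-equation transcription of the 1984 estimator on an exhaustive
sweep of small instances.

## F4, f4-admixture ratio, and f-branch

F4(A,B;C,D) is the mean over SNPs of (p_A−p_B)(p_C−p_D). The topology
contrast computes F4 under two arrangements of two lakes' Balchen/Albeli
pairs: sympatric pairs opposed (F4¹) and same-ecomorph pairs opposed
(F4²). |F4¹| < |F4²| supports parallel within-lake origin. The paper-scale
analysis compares the statistics directly; because the sign conventions of
F4 depend on arbitrary pair orientation, the comparison here uses absolute
values, with the signed values also reported.

For a trio fitting ((A,B),C) with outgroup O, per-site
ABBA = (1−p_A)p_B p_C(1−p_O) and BABA = p_A(1−p_B)p_C(1−p_O);
D = Σ(ABBA−BABA)/Σ(ABBA+BABA), and the f4-admixture ratio divides the same
numerator by a donor-into-itself denominator in which C's frequencies
replace B's. That denominator contains p_C squared, and with a finite
sample of n_C haploid alleles E[p̂_C²] = p_C² + p_C(1−p_C)/n_C, which
inflates the denominator and biases f downward — severely at the 6-allele
sample sizes typical of 3-diploid population samples. The implementation
therefore applies the standard unbiased correction
p̂_C² − p̂_C(1−p̂_C)/(n_C−1) whenever the C sample size is supplied; with
population frequencies (n_C omitted) the plain substitution is used.

The f-branch statistic assigns excess allele-sharing from a donor tip C to
a specific branch b: f_b(C) is the median over recipients B below b of the
minimum over references A in b's sister clade of f(A,B;C,O), floored at
zero. Cells where C falls inside b's clade or its sister clade are
topologically untestable and marked as such. Standard errors come from a
delete-one-block jackknife over contiguous equal-SNP-count blocks
(default 20 — deterministic and robust to SNP-density variation; the exact
block construction of existing tools is not published, so equal-count
blocks are this package's documented choice), recomputing the full
median-of-minima statistic per deleted block. Note that the underlying
f4-ratio is symmetric in which partner donated: a simulated
donor-into-recipient event lights up both the recipient branch against
donor-side tips and the donor-side branch against the recipient tip, and
either orientation may carry the larger f_b. Significance uses the
one-sided upper-tail normal quantile of α/n\_testable: one-sided because it
reproduces the conventional threshold (0.01 over 1910 testable cells gives
Z > 4.41, where the two-sided conversion would give 4.55), and because
only allele-sharing excess, not deficit, is the alternative of interest.

## GWAS support computations

Mixed-model association itself is out of scope; the package provides the
surrounding computations: the strict Bonferroni line −log10(α/n\_SNPs); the
LD-considerate line over the effective test count (SNPs surviving r² > 0.95
pruning in 50 kb windows); the per-SNP variance explained
PVE = 2β²·MAF(1−MAF) / (2β²·MAF(1−MAF) + se_β²·2N·MAF(1−MAF)); and
per-group allele-frequency profiles paired with group trait means. A
plumbing-grade OLS scan (optionally PC-adjusted, binary traits via the same
linear scoring) exists so the synthetic large-effect-locus recovery test
runs end to end, with an output schema matching what PVE consumes.

LD pruning is implemented as the exact pairwise rule: scanning left to
right, a SNP is removed when its squared correlation with any retained SNP
closer than the window span exceeds the threshold. This equals the
windowed greedy scan at step 1 and is at least as strict as any coarser
step, which is why the step-size knob of PLINK-style tools is not exposed;
the removal of the later SNP of an offending pair makes the result
deterministic, order-stable and idempotent.

## The synthetic radiation generator

The generator emulates the study design at frequency level, not sequence
level: ancestral frequencies Beta(0.8, 0.8) truncated to [0.05, 0.95];
lake frequencies drifted by the Balding–Nichols model with a single
F\_lake (default 0.10, a typical between-lake differentiation for young
radiations); genotypes Binomial(2, p). Default sampling mirrors the CSS
design: 4 lakes × (Balchen, Albeli) × 3 diploids = 24 ingroup samples,
plus 4 outgroup individuals drifted independently (F = 0.2), 20,000 SNPs
on 4 chromosomes of 2.5 Mb (≈100 SNPs per 50 kb window).

Design choices worth recording:

* **Divergent loci are clustered.** Parallel and lake-specific loci are
  placed in contiguous blocks (default 50 SNPs, about half a window),
  emulating divergence islands rather than isolated SNPs; an isolated
  shifted SNP among 99 neutral ones is not what windowed scans target.
  Block membership is recorded in the truth table.
* **Parallel shifts have one global sign per locus.** The two contrast
  ecomorphs split ±shift/2 around the lake frequency with the same sign in
  every lake (clipped to [0,1]), so both CSS (non-directional) and F\_ST
  respond; the effect-size distribution is not published, so the default
  shift of 0.8 at 1% of loci is a generator parameter reported with every
  output.
* **Two origin modes.** `"parallel"` (default) drifts lakes first and adds
  ecomorph shifts within lakes; `"single"` drifts ecomorph lineages first
  (F\_ecomorph) and lakes within them, producing the opposite F4 topology
  signature. These are the two scenarios the topology contrast must
  distinguish.
* **Introgression is tract-level allele replacement.** Recipient genotypes
  inside non-overlapping tracts (sampled as whole bins of the configured
  tract length, covering the requested genome fraction) are redrawn at the
  donor lake's frequencies — haplotype-free, no recombination model, but
  sufficient to drive D/f4-ratio/f-branch signal, with every tract
  recorded per sample.
* **Trait architecture.** Gill-raker count is an ecomorph baseline
  (Balchen 26 < Felchen 28 < Albeli 30, mirroring the relative gill-raker
  ordering of the ecomorphs) plus the large-effect locus (default +2
  rakers per alt allele, with ecomorph-graded allele frequencies spanning
  0.8 ordered by the baselines) plus Gaussian noise, rounded and floored.
  The baselines are deliberately mild so that the ecomorph gradient flows
  through the causal locus rather than around it: with wide fixed
  baselines, any strongly ecomorph-differentiated SNP would predict the
  trait as well as the causal one and single-locus recovery would be
  ill-posed. Standard length is an ecomorph baseline plus a polygenic
  score (default 100 loci, N(0, 2) effects, residual SD 15 mm).
* **Determinism.** One RNG seeded once; draws consume it in a fixed,
  documented order (genome layout, ancestral frequencies, locus classes,
  per-locus randomisation, population frequencies, genotypes, traits,
  introgression), so a seed fully determines the VCF bytes.

What the generator does **not** emulate: linkage and recombination (SNPs
are exchangeable within blocks), coalescent variance in split depths,
selection, missing data, and sequencing error. Passing recovery tests
therefore demonstrates statistical correctness of the estimators under the
stated frequency-level model, not robustness to LD structure or call-rate
artefacts in real data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest sizes
chosen to exercise every code path with stable statistics: null
calibration on 500 windows (50,000 SNPs) with 1,000 sampled permutations;
drift recovery on 50,000 SNPs; CSS recall at the 24-sample default with
exact enumeration (160,000 assignments); topology contrasts over 10 seeds
at 6,000 SNPs; f-branch and f4-ratio recovery at 50,000 SNPs with 20
jackknife blocks; association recovery at 90 samples × 20,000 SNPs.
Degenerate inputs have defined behaviour: windows below the SNP floor are
absent from output, not flagged; a zero jackknife SE yields a signed
infinite Z with a warning; SNPs with a+b+c = 0 are skipped with a message;
monomorphic SNPs are dropped from association scans; an all-identical
window has CSS exactly 0.

## Known limitations

* CSS weighting follows the corrected published formula (size-weighted
  within-group means over MDS-embedded distances); any alternative
  weighting lives behind the single function `css_window`.
* Whether historical scans retained all MDS axes is not documented;
  retaining all positive-eigenvalue axes is exact for this metric and is
  the assumption here.
* The f4-ratio denominator correction matters at small sample sizes;
  omitting `n_c`/`sample_sizes` reproduces the naive plain-substitution
  estimator, which is biased downward for finite samples.
* The real-data headline numbers of the motivating study (outlier-window
  counts, median CSS values, trait-regression R², PVE percentages) depend
  on the study VCF and are not reproducible from synthetic data; the
  package reproduces every analytic (formula-level) value and recovers
  generator parameters from synthetic radiations instead.

## A minimal end-to-end run

```{r, eval = FALSE}
library(radscan)
cfg <- run_config(out_dir = "demo",
                  vcf = "demo/simulated.vcf",
                  metadata = "demo/metadata.tsv",
                  tree = "demo/tree.nwk",
                  n_permutations = 1000, permutation_mode = "auto",
                  simulate = list(large_effect_locus =
                                    list(chrom = 2, pos = 1.25e6,
                                         effect = 2)),
                  seed = 1)
run_stage("simulate", cfg)
run_stage("css-scan", cfg)
run_stage("fst-scan", cfg)
run_stage("f4-contrast", cfg)
run_stage("fbranch", cfg)
run_stage("assoc-support", cfg)
```

Each stage writes TSV/BED-compatible artifacts plus a JSON manifest with
the configuration hash, seed, and package version; identical
configurations reproduce identical files, and a stage refuses to
overwrite outputs from a different configuration unless forced.
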