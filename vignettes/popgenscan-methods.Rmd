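---
title: "Methods and design notes for popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenscan)
```

This vignette records the statistical choices behind each stage of the
pipeline, what the simulators do and do not emulate, and the numerical
conventions that make results reproducible. It states no empirical result
that the test suite does not itself compute.

## The data model

Genotypes are diploid alternate-allele dosages in {0, 1, 2, NA} over
biallelic SNPs, held in a `geno_matrix` with 1-based VCF positions. All
window outputs use 0-based half-open intervals (BED convention). When data
come from a simulator, both phased haplotypes are carried and always sum to
the dosage; real unphased data simply lack them, and every statistic that
can work from dosages does so.

## SNP filtering

Filters run in a fixed order — biallelic → missingness → MAF → HWE — and a
removed variant is attributed to the *first* rule it fails, so the filter
report is deterministic and its counts sum to the input count. MAF is
computed on the pooled cohort (the filters describe a single merged VCF),
with the retain condition MAF > 0.05 strict, missingness ≤ 0.10, and HWE
exact *p* ≥ 0.001.

Two points deserve emphasis:

* **HWE direction.** Field write-ups are sometimes worded as if variants
  with *p* < 0.001 were *kept*; standard QC practice (PLINK, GATK-style) is
  to *remove* them, and that is the default here. The literal keep-low
  reading is available behind `hwe_keep_low = TRUE`.
* **Pooling and the Wahlund effect.** Testing HWE on a pooled structured
  cohort flags heterozygote-deficient sites, which are disproportionately
  the most differentiated ones. On strongly structured cohorts this filter
  removes many real SNPs and biases downstream Fst downward. That is a
  faithful consequence of the published filtering regime, not an artifact;
  analyses that need the unbiased contrast (e.g. the parameter-recovery
  tests) run on the unfiltered matrix.

The exact test itself is the two-sided conditional test on the heterozygote
count given the allele counts: the p-value sums the probabilities of all
heterozygote counts whose conditional probability does not exceed the
observed one. Probabilities come from the standard two-term recurrence; the
test suite checks the result against an independent log-factorial
enumeration for *every* genotype table with up to 30 individuals, to 1e-12.
A relative tie tolerance of 1e-9 in the comparison makes theoretically tied
tables land identically under both evaluation orders; mid-p variants are
deliberately not offered.

## Diversity indices

The per-locus kernel is the within-subset allele frequency p̂ and call count
n. The indices (all means over usable loci) are the standard biallelic
forms: Ho = fraction of heterozygous calls; He = 1 − p̂² − q̂²; Nei's
unbiased gene diversity (2n/(2n−1))·He with n the number of *individuals*
(so 2n is the number of gene copies); Shannon–Wiener −Σₐ p̂ₐ ln p̂ₐ (natural
log, max ln 2); allele number = count of observed alleles (1 or 2). Loci
monomorphic in the population still enter the means, with indices 0 and
allele number 1; fully missing loci are dropped.

Windowed π uses the unbiased per-site estimator
Σ_SNPs 2p̂(1−p̂)·2n/(2n−1), divided by the *window span* in bp (not the SNP
count). With this n-of-individuals convention the per-site term equals the
mean pairwise difference among the 2n sampled sequences exactly, which is
what the oracle-equivalence test asserts on phased toys. Windows below
`min_snps` (default 10, to keep downstream ratios stable) are reported as
missing; terminal partial windows are emitted but flagged, and excluded
from all quantile computations.

## Fst

Per-site Weir & Cockerham (1984) variance components a (among populations),
b (among individuals within populations) and c (within individuals), using
within-population frequencies, sample sizes and observed heterozygosities.
Aggregation over windows or the genome is the ratio of sums Σa/Σ(a+b+c) —
stable in low-diversity windows, unlike the mean of per-site ratios. Sites
with fewer than two called genotypes in either group are unusable and never
enter sums. Small negative estimates are reported unclamped, and quantile
thresholds operate on the raw values. The Hudson ratio-of-sums estimator is
implemented only inside the test suite, as an independent cross-check.

On the hierarchical simulation, region-level Fst (samples grouped by
region) recovers the generating region-level F: with r groups of size n̄,
the observed-heterozygosity terms cancel in b + c up to O(1/n̄), so
within-region substructure barely perturbs the estimand. One caveat worth
knowing: a region observed through a *single* subpopulation contributes its
unaveraged local drift, inflating that region's pairwise entries by roughly
(1−F_region)·F_local·(1/k_i + 1/k_j)/2 for k subpopulations per region.
With F_region = 0.30, F_local = 0.07 and k = 1 this pushes the expectation
to ≈ 0.33 — visible in the recovery tests as entries near the upper edge of
the tolerance band, and inherent to the stated design rather than an
estimator defect.

## Sweep scan

Candidates are windows in the top-q Fst tail (default q = 0.05, test ≥, so
ties at the threshold are included) **and** in an extreme tail of the
log2 π-ratio (strict >, so a degenerate all-equal track selects nothing —
the documented tie behaviour). The π-ratio tail mass is split q/2 per side,
one tail per population, mirroring selection scans that color the two
populations separately; a single-tail mode is available by flag. Thresholds
are type-7 (linear-interpolation) empirical quantiles of the usable
windows. The scan unit is the window; published "selection site" counts are
of ambiguous unit, so window counts are reported as primary. The
pseudocount in the ratio (default 1e-6 per site, one mismatch per Mb) only
matters for zero-diversity windows and cancels in the tails otherwise.

## Junction validation

A chromosome joined from two contigs at a breakpoint admits two connection
modes: as assembled, or with the B-side contig reversed (its coordinates
mirrored onto the junction). Each mode is scored by the unweighted mean
r² over all cross-junction SNP pairs within the flank (default 500 kb) and
a pair-distance cap (default the flank); the mode with higher mean LD wins,
with relative differences below 1e-6 called undecided. r² is
haplotype-based (D²/p₁q₁p₂q₂) when phase is available and the
genotype-dosage squared correlation (composite LD, Rogers–Huff style)
otherwise; no inverse-distance weighting is applied, keeping the score the
simplest defensible reading of "degree of linkage disequilibrium". The
published score pair this procedure echoes (0.09415 vs 0.05116) depends on
an unreleased cohort and is treated as narrative, not as a target.

## Simulators: what they emulate, and what they do not

`simulate_structured_cohort()` is a hierarchical Balding–Nichols model:
ancestral frequencies uniform on [0.05, 0.95] (chosen so most sites survive
a 5 % MAF filter), region frequencies Beta-distributed around them with
variance F_region·p(1−p), population frequencies likewise with F_local,
and genotypes as two independent Bernoulli haplotypes (exact within-
population HWE). Defaults mirror the emulated survey: regions with 3, 4
and 1 subpopulations, 15–18 diploids each (cycled deterministically),
F_region = 0.25 and F_local = 0.07 — the midpoints of the reported 0.2–0.3
and 0.05–0.1 contrasts. The model was chosen over a coalescent simulator
because its closed-form expected Fst enables parameter-recovery acceptance
tests. Its deliberate omissions: no LD (sites independent), no mutation
model, no migration or admixture, no missing data by default. A green
recovery test therefore establishes estimator correctness under drift-style
differentiation — not robustness to linked selection or gene flow.

Sweep injection pushes the target population's frequencies toward the
nearest fixation point by a strength parameter s (p′ = p + s(1−p) or
p(1−s)) and redraws that population's genotypes inside the injected windows
only; s = 0 is the identity. The acceptance tests use s = 0.8 as the
"strong but not fixed" regime.

`simulate_linked_haplotypes()` is a founder-mosaic model: each haplotype
copies one of `founder_count` (default 20) founders, switching founders at
Poisson crossovers (default rate 1e-5/bp, i.e. a 100 kb LD decay scale).
Two sites at distance d share a founder block with probability
exp(−d·rate), so r² decays toward the founder-pool baseline. LD structure
and cohort structure are deliberately decoupled: the BN cohort has no LD,
the mosaic cohort has no population structure. Junction acceptance
scenarios use 50 diploids at 1 SNP/kb — scaled down from the emulated
study's 130 samples and ≈6.5 SNPs/kb for runtime, which makes the test
conservative rather than flattering.

## Numerical conventions

* Quantiles: R type 7 everywhere a threshold is an order statistic.
* Nxx: first-reach convention (cumulative sorted length ≥ x % of total),
  with `total_override` for computing full-assembly Nxx from a subset — the
  convention under which the bundled chromosome table reproduces the
  published scaffold N50.
* Rounding in report arithmetic matches the printed tables: one decimal for
  anchoring/BUSCO percentages, two for composition percentages, with
  subtotals summed before division.
* All generators are pure functions of (parameters, seed); the pipeline
  reruns byte-identically given the same config and seed, and the manifest
  records every parameter needed to regenerate a run.

## Known limitations

Indels, multiallelic sites (beyond flag-and-remove), genotype likelihoods,
haplotype-based sweep statistics (XP-CLR, CLR), dxy, jackknife confidence
intervals and AMOVA are out of scope. The HWE-on-pooled-cohort filter is
faithful to the emulated protocol but statistically aggressive under strong
structure, as discussed above; users wanting structure-robust QC should
filter per population and merge.
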