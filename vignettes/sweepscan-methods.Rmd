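---
title: "Methods: windowed selection scans, their null distributions, and the synthetic study system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed selection scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(sweepscan)
```

## The problem

Recent positive selection leaves a local footprint in population genomic
data: the swept haplotype rises quickly, dragging linked variation with it,
so diversity (π, heterozygosity) collapses around the selected site in the
affected population while allele-frequency differentiation (F_ST) against
unaffected populations spikes.  `sweepscan` implements the standard
comparative scan built on that signature: a test population is contrasted
with reference populations over sliding windows, three statistics are
standardized genome-wide, and their extreme empirical tails are intersected.
The design follows the workflow used in livestock genomics, where a breed
with a phenotype of interest (e.g. comparatively high milk yield) is scanned
against phenotypically contrasting breeds.

## Statistics and conventions

**Windowed π.** Per site, with `a` alternate alleles among `n` called
haplotypes, π = a(n−a)/C(n,2); the window value is the sum over in-window
SNPs divided by the window *span in bp* (not the SNP count), so monomorphic
positions dilute the estimate exactly as in the windowed-π convention of
standard VCF tooling.  Missing genotypes reduce the per-site `n`; nothing is
imputed.

**Weir–Cockerham F_ST.** The 1984 variance-components estimator for two
populations, computed per site from sample sizes, allele frequencies and
observed heterozygosities, and combined across a window as the weighted
ratio-of-sums Σa/Σ(a+b+c).  The mean-of-ratios variant is available
(`fst_mode = "mean"`) because windowed F_ST tools differ on this point and
the choice is rarely documented downstream.  Negative estimates are
retained: clamping at zero would truncate the left half of the empirical
null and bias the Z-transformation that follows.  When several reference
populations are used they are pooled into a single reference sample.

**Pooled heterozygosity.** Hp = 2·ΣnMAJ·ΣnMIN/(ΣnMAJ+ΣnMIN)², summing
per-site major and minor allele *counts* of the test population over the
window.  Allele counts rather than frequencies are used; with complete data
the two differ only through per-site missingness weighting, and counts are
the convention of the Hp method's original formulation.  Hp ∈ [0, 0.5] and
collapses toward 0 in swept regions.

**Tajima's D.** The classical normalized difference between the pairwise
and segregating-sites estimators of θ, with constants a₁, a₂, b₁, b₂, c₁,
c₂, e₁, e₂ from the haplotype count n.  The classical formula assumes one
fixed n; under missingness the per-site called count varies, so the package
uses n = round(mean called haplotypes over in-window segregating sites).
Windows with S < 2 segregating sites, n < 4 or a zero variance term are
flagged `NA` rather than coerced to 0 — a D of zero is a meaningful value
and must not be manufactured.

**Z-scores and tails.** ZF_ST and ZHp standardize each statistic over all
autosomal windows jointly (one empirical null, not per chromosome), using
the n−1 standard deviation.  Windows with fewer than `min_snps_per_window`
SNPs (default 10) are excluded from the distributions — under-filled
windows otherwise dominate both tails with noise.  `select_tail` flags
exactly ⌈qW⌉ windows of the W unflagged ones (default q = 0.005); ties at
the cutoff break by genomic order so reruns are byte-identical.

**π ratio.** ln(π_test/π_ref) with π_ref computed on the pooled reference
samples.  A swept test population drives this ratio *down*, so the lower
tail is flagged by default; `ratio_tail = "upper"` flips the direction for
workflows that orient the ratio the other way.  Windows where either π is
zero are flagged and excluded rather than mapped to ±∞: an exactly-zero π
usually marks a data hole (or a completed sweep core), and either way it
carries no rankable information.

**Regions, genes, intersection.** Flagged windows that overlap or abut are
merged into maximal candidate regions (the scan's overlapping windows make
single-window candidates rare); genes overlap a region with ≥ 1 bp in
0-based half-open arithmetic.  Merging precedes annotation.  The
three-method intersection is the headline output: a gene flagged by ZF_ST,
ZHp and the π ratio simultaneously.

All internal interval arithmetic is 0-based half-open; VCF and GFF3
coordinates (1-based) are converted only at the I/O boundary, and BED output
is 0-based half-open.

## Diversity/structure layer

**ROH.** The caller is PLINK-style: 50-SNP sliding windows tolerating ≤ 1
heterozygote and ≤ 2 missing calls; a SNP is in the homozygous state when
> 5% of the windows covering it are eligible; runs must span ≥ 50 SNPs,
≥ 500 kb, and ≥ 1 SNP/50 kb.  One refinement is added: raw window-fraction
boundaries systematically under-call run edges by a couple of SNPs, so each
run is expanded to the maximal surrounding heterozygote-free stretch before
filtering.  A fully homozygous tract is then recovered to its first and
last homozygous SNP.  Segments are classified into 0.5–1 Mb, 1–2 Mb and
> 2 Mb.

**LD.** r² is the squared Pearson correlation of unphased dosages over
jointly-called samples (the composite measure — the data are unphased, so
haplotype-based r² is not available).  Decay curves bin all
intra-chromosomal pairs within `max_dist` (default 500 kb, 1 kb bins).
Pruning follows the `50 10 0.2` greedy convention, with one strengthening:
every window offset is scanned and passes repeat until stable, so the
post-condition — no surviving pair within any 50 consecutive surviving SNPs
exceeds r² = 0.2 — holds unconditionally, which stepped scanning alone does
not guarantee.

**PCA.** Dosages are mean-imputed per site, centered by 2p̂ and scaled by
√(2p̂(1−p̂)) (Patterson normalization), then decomposed by SVD; explained
variance is reported per component.  Mean imputation is the simplest policy
that leaves component directions unbiased at the missingness levels the
filter admits (≤ 10%).

**Distances and trees.** IBS distance is 1 − mean allele-sharing;
population-level distances average over cross-population sample pairs.
Neighbor-joining (Saitou–Nei, via ape) serializes with a trifurcating root;
negative branch lengths are clamped to zero with a warning.

## The synthetic study system

Two generators cover complementary needs.

**Balding–Nichols** draws each population's per-site frequency from
Beta(p(1−F)/F, (1−p)(1−F)/F) around an ancestral p ~ U(0.05, 0.95), giving
a closed-form divergence target: the between-population frequency variance
is F·p(1−p) and the expected Weir–Cockerham F_ST equals F.  This is the
calibration instrument for the F_ST estimator, PCA separation and
distance-based structure.

**Forward Wright–Fisher** provides genealogical signal (site-frequency
spectra, Tajima's D, sweep troughs).  The ancestral population is
initialized at the neutral stationary spectrum (allele-count classes
weighted 1/i) — the standard shortcut that replaces a many-generation
burn-in — after which populations split and evolve by per-generation
binomial resampling with infinite-sites mutation influx at rate μ per bp.

The hard sweep is mechanistic: a beneficial allele starts at 1/2N in the
test population, updates as p′ = p(1+s)/(1+ps) plus binomial drift, and is
conditioned on fixation within the split epoch by restart (budget 1,000;
exhausting it is a reported error, never a silent fallback).  Hitchhiking
is modelled by tracking each neutral site's frequency separately on the
beneficial and wild-type backgrounds: recombination at r per bp per
generation exchanges alleles between backgrounds, and drift acts within
each background.  Tightly linked sites ride the sweep to fixation or loss;
distant sites escape.  The recorded truth interval is pos ± s/(2r·ln 2N),
the physical scale at which the expected number of recombination events
during the sweep reaches one.

**Scaling.** The defaults are a deliberately scaled-down study system:
diploid N = 200–500 with μ raised so that θ = 4Nμ ≈ 10⁻³/bp and
r = 10⁻⁷/bp, preserving the population-scaled densities of cattle-scale
data on a 5 Mb chromosome.  The end-to-end recovery experiment
(`sweep_study_params`) uses 3 populations × 25 diploids, a 150-generation
split (background F_ST ≈ 0.2), s = 0.1, and 5 kb/2.5 kb windows — 2,000
windows, so the 0.5% tails flag 10 windows per method, against a sweep
footprint of ~2 × 70 kb.  Missingness is i.i.d. per call, applied after
sampling.

**What the generators do not emulate.** Between-site linkage is absent
outside the sweep mechanism (sites drift independently, i.e. effectively
free recombination), so background LD decay, haplotype structure and
drift-induced ROH are not reproduced — LD and ROH behaviors are therefore
tested on constructed fixtures and on Balding–Nichols drift gradients
rather than on WF output.  There is no recombination map, no demographic
change, no selection other than the single sweep, and sites monomorphic in
the pooled sample are dropped (as in a real call set).  Passing tests
demonstrate the correctness and calibration of the estimators and the scan
logic under these idealized conditions; they do not validate robustness to
alignment artifacts, call-rate structure or complex demography in real
data.

## Numerical and degenerate-input policy

- Statistics on windows below the SNP minimum, with zero variance, zero
  denominators, or zero diversity are `NA` (flagged), excluded from Z
  distributions and tails, and never silently replaced by 0.
- All simulators and the pipeline are pure functions of (inputs, config,
  seed); reruns are byte-identical.
- The MAF filter keeps a site iff MAF ≥ 0.05 by default (boundary
  inclusive); the comparator is exposed because both conventions appear in
  published pipelines.
- Problem sizes in the test suite (10-seed calibrations, 20-seed recovery,
  200 oracle matrices, 100 random trees) were chosen as the smallest
  designs whose pass/fail behavior is stable across seeds.

## Known limitations

Haplotype-based statistics (iHS, XP-EHH), multi-population (> 2) F_ST,
ancestry-fraction estimation, GO/KEGG enrichment and phasing are out of
scope.  The π-ratio denominator pools the reference populations; per-
reference ratios can be derived from the per-population π columns the
window table always carries.
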