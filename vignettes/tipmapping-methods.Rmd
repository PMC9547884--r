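---
title: "Methods: bulked-segregant and mixed-model mapping of a recessive fruit-tip locus"
author: "tipmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bulked-segregant and mixed-model mapping of a recessive fruit-tip locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistics it
implements: the models, their assumptions, the defaults and why they were
chosen, and what the synthetic cohorts do and do not emulate. The numbers
any claim rests on are computed by the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) and by
`scripts/acceptance.R`; nothing here asserts a result those runs do not
produce.

## The trait and its coding

The phenotype is the shape of the fruit's distal (blossom) end: pointed
(tip code 1) iff the distal-end angle θ lies strictly in (0°, 180°), else
non-pointed (0). `classifyTip()` applies exactly this rule; 180° is
non-pointed by the strict inequality. Where a curated binary code and an
angle are both present the code is authoritative (panels are typically
phenotyped to a code, with angles recorded for a subset); inconsistencies
raise a warning. Reported group percentages are rounded half-up — base
R's banker's rounding would turn 21.854…% into 21.85% either way, but
half-up is the convention such tables use and is applied uniformly
(`roundHalfUp()`).

The trait inherits as a recessive: heterozygotes are non-pointed. All
downstream defaults assume this; dominant and additive codings are
available on `assignTipPhenotype()` for completeness.

## The F2 simulator

`simulateF2()` crosses two fully inbred founders fixed for opposite
alleles at every SNP, with the alternate allele defined as the pointed-tip
parent allele. Each F1 gamete receives a Poisson-distributed crossover
count with rate equal to the chromosome map length in Morgans, breakpoint
positions uniform on the chromosome, and no crossover interference; an F2
genotype is the sum of two independent gametes. This is the simplest
crossover model that produces the right BSA geometry (Mendelian 1:2:1
marginals, exponential decay of linkage with distance); interference
would sharpen linkage slightly but does not change window-level behaviour
at the scales used here.

The default map density is 0.5 Morgans per 10-Mb chromosome (5 cM/Mb), a
euchromatin-like figure chosen once for the packaged genome. A
consequence worth stating plainly: a single 10-Mb chromosome is then only
50 cM end to end, so *every* marker on it is linked to a causal locus in
its middle. In the packaged BSA demonstration the 99%-significant region
therefore extends over most of the chromosome; the causal position is
always inside it, and on multi-chromosome genomes the unlinked
chromosomes provide the contrast.

Bulks (`formBulks()`) are random within phenotype class — the source
design does not state how the 73 individuals per pool were chosen among
2,000 F2 plants, so uniform sampling within class is exposed as the
default and the only implemented rule. Pooled sequencing
(`poolReadSample()`) draws one depth per SNP from Poisson(mean depth)
with floor 1, shared by both bulks — "roughly 70×" without modelling
coverage bias — and alternate read counts from
Binomial(depth, p(1−e) + (1−p)e) where p is the true bulk allele
frequency and e = 0.001 the symmetric per-read miscall default. A fixed
depth mode exists for exact-conservation checks.

## SNP-index, ΔSNP-index and the no-QTL envelope

For one bulk, SNP-index = alt/(ref+alt); SNPs below `minDepth` (default
10) are masked. Δ = index(non-pointed) − index(pointed). The sign
convention is fixed to that subtraction order, so a recessive pointed-tip
allele gives a *negative* peak: at the causal SNP the pointed bulk is
fixed (index 1) and the non-pointed bulk segregates AA:Aa = 1:2 (allele
frequency 1/3), hence Δ → 1/3 − 1 = −2/3 with depth. Windowing is the
mapping default, 1000-kb windows advanced by 200 kb, unweighted means of
unmasked SNPs; windows with fewer than `minSnps` (default 10) unmasked
SNPs are masked, and terminal windows shorter than the window size are
kept and flagged rather than dropped. `minDepth` and `minSnps` are
conservative defaults the source procedure does not pin down; both are
exposed.

The confidence envelope (`nullDeltaBands()`) is Monte-Carlo under the
null of no QTL: per replicate and bulk, `bulkSize` F2 genotypes are drawn
with probabilities (1/4, 1/2, 1/4) — equivalently the bulk allele count
is Binomial(2·bulkSize, 1/2) — reads are Binomial(depth, p), and a
window-level draw averages m independent SNP-level Δs. Bands are the
empirical 2.5/97.5 (95%) and 0.5/99.5 (99%) percentiles, tabulated over
depth classes and window SNP-count classes, with each observed window
keyed to its nearest class. Two deliberate choices:

* The procedure is *window-level* (the published description does not say
  whether its intervals were per SNP or per window; the window-level
  version is the default, and the SNP-level bands are the m = 1 class).
* SNPs within a window are treated as independent. On a real segregating
  chromosome neighbouring SNPs are strongly linked, so true window means
  have a larger variance than the bands assume — the bands are
  anti-conservative for dense windows. This is documented rather than
  corrected because the replicate-level criterion (does the 99% region
  contain the causal locus?) is unaffected, and because modelling
  within-window LD would require the very linkage map the method is meant
  to localize. The calibration test in the suite therefore checks the
  bands against fresh draws from the same null (coverage ≈ 95%), not
  against whole-chromosome simulations.

Default replicate count 10,000 (floor 1,000 enforced). Region calling
flags unmasked windows outside their class band and merges overlapping or
book-ended flagged windows per chromosome.

## The mixed-model scan

`lmmScan()` fits, per SNP, y = Xb + gβ + u + e with u ~ N(0, σ²_g K) and
e ~ N(0, σ²_e I), where X is an intercept plus principal components
(default 3, matching the covariate set used for the panel) and K is the
centred relatedness matrix ZZ′/m (`kinshipMatrix()`), missing dosages
mean-imputed throughout (PCA, kinship, scan) for consistency. The binary
phenotype is fitted as quantitative 0/1 — the choice such scans make in
practice with Gaussian mixed-model software, keeping a closed-form Wald
test; a logistic mixed model is out of scope.

K is eigendecomposed once. For each SNP the ML likelihood is profiled
over δ = σ²_e/σ²_g on a 100-point log-spaced grid spanning [1e−5, 1e5]
(vectorized across SNPs), then refined by golden-section search inside
the winning grid bracket. The Wald test uses σ̂² = RSS/(n−p) and a t
reference with n−p degrees of freedom. That pairing is deliberate: with
K = I the weights are constant, every quantity cancels, and the scan
reduces *exactly* to OLS — the property the suite checks to 4 decimals.
Degenerate SNPs (rotated genotype numerically constant) are skipped with
a message.

Filtering precedes everything: MAF strictly greater than 0.05 and at
least 16 samples carrying the minor allele, both over non-missing calls —
the panel's published filter, including the strict inequality at the MAF
boundary. Thresholds are suggestive 1/n and significant 0.05/n for n
tested SNPs; λ is the median χ²₁-transformed p-value over 0.4549.

A calibration caveat the diagnostic work surfaced: with a *binary*
response and heavily drifted (near-boundary-frequency) SNPs, the exact-t
reference is mildly conservative — and identically so for plain OLS, so
it is a property of discrete y at n = 311, not of the mixed model. The
null-calibration check is therefore run on an exchangeable panel
(uniform small drift, no sweep, phenotype an independent Bernoulli draw),
which is the condition under which p-values are theoretically uniform;
under the strongly structured default panel the p < 0.05 fraction dips to
≈ 0.04. Users scanning heavily structured binary traits should expect
slight conservatism, not inflation.

## Diversity, sweeps, LD

Per site, π uses the unbiased heterozygosity 2p(1−p)·n/(n−1) with n the
called allele count; this equals the mean pairwise allele difference at
the site exactly, and the suite verifies the identity against an
exhaustive pairwise oracle on all instances with ≤ 8 alleles. Window π
divides the summed site values by the *window length in bp* (default
100-kb windows, 10-kb step), the conventional estimator in which
monomorphic stretches dilute π; the alternatives (per-variant-site
denominators, other window sizes) are configuration, not claims, since
the source does not specify its estimator.

`piRatioScan()` computes π(A)/π(B) per window — ancestral over derived,
so sweeps in the derived group give high ratios — masks zero-denominator
windows, and flags the top 1−q fraction of unmasked windows genome-wide
(q = 0.95: the "top 5% of the entire genome" rule). Flagging is
rank-based, so with heavy ties exactly ⌈(1−q)·N⌉ windows are flagged and
the reported threshold is the smallest flagged ratio.

LD r² is the squared Pearson correlation of dosage vectors over samples
non-missing at both SNPs — the composite, phase-free estimator, the
right one for unphased inbred material. Haploblocks use a greedy
left-to-right rule: grow a block while the mean pairwise r² among its
SNPs stays ≥ `r2Min` (default 0.7); single SNPs are not blocks. The
published figures show Haploview-style triangles but name no algorithm;
the mean-internal-r² rule is simple, deterministic, and exposed via its
threshold. It is greedy: a dip in LD ends a block even if the mean would
recover later.

Per-group allele frequencies default to *carrier* counting (share of
accessions carrying the allele) because the panel is predominantly
homozygous inbred material, where carrier and allele frequencies nearly
coincide; a chromosome-count mode is the `mode = "allele"` option.

## What the panel generator emulates — and what it does not

`simulatePanel()` produces 55 wild + 105 CER + 151 BIG accessions.
Neutral SNPs follow a Balding–Nichols structure: an ancestral frequency
from Beta(0.8, 0.8) and group frequencies from
Beta(p(1−F)/F, (1−p)(1−F)/F) with drift F = 0.02 (wild), 0.30 (CER),
0.50 (BIG). This was chosen over independent per-group Beta draws
because it yields both required features at once — group-specific
frequency spectra with expected heterozygosity falling wild > CER > BIG
(the domestication diversity loss), and cross-group correlation, without
which PCs and kinship would have no structure to capture. The causal SNP
is coded inbred-style (homozygous carrier at the group's carrier
frequency: wild 1.8%, CER 8.6%, BIG 24.5% by default) and the phenotype
is fully penetrant recessive. Inside the sweep region (default
ch05:6.0–6.6 Mb, containing the causal position 6,401,270) each
derived-group site is fixed for its major allele with probability
1 − `sweepShrink` (default 0.1), shrinking expected diversity roughly
tenfold.

Not emulated, hence not demonstrated by passing tests: linkage
disequilibrium decay among neutral SNPs (sites are exchangeable given
group frequencies, so LD structure beyond the causal/sweep construction
is absent), residual heterozygosity patterns of real inbred collections
(neutral genotypes are Hardy–Weinberg within groups), mutation/recomb
coalescent realism, imperfect penetrance (real wild accessions can carry
the derived allele yet show no pointed fruit), and any phenotype
misclassification. Conclusions about the *method* — recovery rates,
calibration, threshold behaviour — transfer; conclusions about real
tomato diversity data do not follow from these simulations.

## Determinism, seeds, problem sizes

Every stochastic function takes an explicit seed and restores the RNG
state afterwards (`withr::with_seed`); identical seeds give bit-identical
outputs, which the suite checks at the file level through
`runPipeline()` (stage seeds are fixed offsets from the master seed, so
stages are reproducible in isolation). Coordinates are 1-based inclusive
in all VCF/TSV files and GRanges containers; BED output is the single
0-based half-open conversion point.

The packaged problem sizes — 10-Mb chromosomes with 10-kb SNP spacing,
F2 of 2,000 with bulks of 73 at 70×, panels of 311 accessions with
5,000–20,000 SNPs, 10,000-replicate null bands, 20-replicate recovery
experiments — were chosen as the smallest scales at which the design
quantities (1:2:1 ratios, the −2/3 causal Δ, 95% coverage, λ ≈ 1,
top-5% sweep recovery) are measurable with comfortable Monte-Carlo
margins; they complete in minutes on one CPU.

## Known limitations

* No multi-QTL or dominance-varying BSA models; no G-statistic or
  Euclidean-distance BSA variants.
* The LMM is Gaussian on a 0/1 trait and ML-only (no REML option, no
  logistic mixed model). Kinship always includes the tested SNP's
  chromosome — no leave-one-chromosome-out variant — a small proximal
  contamination at these SNP counts.
* Null bands ignore within-window LD (anti-conservative; see above).
* The VCF dialect is minimal: biallelic SNPs, GT only, INFO/FILTER
  ignored on read; no BCF/CRAM.
* Haploblocking is greedy mean-r², not a confidence-interval method.
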