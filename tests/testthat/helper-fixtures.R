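## Small programmatic fixtures shared across the suite.

suppressMessages({
  library(SummarizedExperiment)   # assay/colData/rowRanges in tests
  library(GenomicRanges)
})

## a 1-Mb single-chromosome genome with evenly spaced SNPs
tinyGenome <- function(nSnps = 10, recombRate = 0.5) {
  GenomeSpec(c(ch05 = 1e6),
             snpPositions = list(ch05 = seq(1e5, 1e6, length.out = nSnps)),
             recombRate = recombRate)
}

## GenotypeData built directly from a dosage matrix (rows = SNPs)
gtFrom <- function(dosage, chrom = "ch05",
                   pos = seq(1e4, by = 1e4, length.out = nrow(dosage)),
                   ...) {
  GenotypeData(dosage, chrom = chrom, pos = pos, ...)
}

## BulkCounts at a handful of SNPs from explicit count vectors
countsFrom <- function(refP, altP, refN, altN, chrom = "ch05",
                       pos = seq(1e5, by = 1e5, length.out = length(refP))) {
  BulkCounts(chrom, pos, refP, altP, refN, altN)
}

## brute-force nucleotide diversity at one site: mean pairwise difference
## over all called allele pairs (dosage 0 -> ref/ref, 1 -> ref/alt, 2 -> alt/alt)
bruteSitePi <- function(dosages) {
  alleles <- unlist(lapply(dosages[!is.na(dosages)], function(d)
    c(rep(1L, d), rep(0L, 2L - d))))
  n <- length(alleles)
  if (n < 2) return(NA_real_)
  diffs <- outer(alleles, alleles, "!=")
  sum(diffs[upper.tri(diffs)]) / choose(n, 2)
}

## brute-force unweighted window mean of unmasked SNP values
bruteWindowMean <- function(pos, val, start, end) {
  sel <- !is.na(val) & pos >= start & pos <= end
  if (!any(sel)) NA_real_ else mean(val[sel])
}
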