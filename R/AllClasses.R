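#' @import methods
NULL

## ---------------------------------------------------------------------------
## GenotypeData: samples x biallelic SNPs, stored as a RangedSummarizedExperiment
## with a single "dosage" assay (SNPs in rows, samples in columns).
## Dosage counts copies of the alternate allele; for F2 material the alternate
## allele is, by convention, the pointed-tip parent allele.
## ---------------------------------------------------------------------------

#' GenotypeData: biallelic SNP dosages with genomic coordinates
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment] with a single
#' integer `dosage` assay (rows = SNPs, columns = samples). Dosages are
#' alternate-allele counts in \{0, 1, 2\} with `NA` for missing calls.
#' `rowRanges()` holds 1-based SNP positions with `ref`/`alt` alleles in its
#' metadata columns; `colData()` carries sample metadata such as `group`,
#' `phenotype` or `theta`.
#'
#' @aliases GenotypeData-class
#' @exportClass GenotypeData
setClass("GenotypeData",
         contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- character()
  if (!"dosage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- SummarizedExperiment::assay(object, "dosage")
    bad <- !is.na(d) & !(d %in% 0:2)
    if (any(bad))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  rr <- SummarizedExperiment::rowRanges(object)
  mc <- S4Vectors::mcols(rr)
  if (!all(c("ref", "alt") %in% colnames(mc)))
    msg <- c(msg, "rowRanges must carry 'ref' and 'alt' metadata columns")
  if (length(rr) > 1) {
    o <- order(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
    if (!identical(o, seq_along(rr)))
      msg <- c(msg, "SNPs must be sorted by (chromosome, position)")
    key <- paste(GenomicRanges::seqnames(rr), GenomicRanges::start(rr))
    if (anyDuplicated(key))
      msg <- c(msg, "(chromosome, position) pairs must be unique")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## BulkCounts: per-SNP pooled read counts for the two phenotype bulks.
## ---------------------------------------------------------------------------

#' BulkCounts: pooled read counts for two phenotype-contrasted bulks
#'
#' Extends [SummarizedExperiment::RangedSummarizedExperiment] with two assays,
#' `refReads` and `altReads` (rows = SNPs, columns = the bulks `"pointed"`
#' and `"non_pointed"`). The alternate allele is oriented to the pointed-tip
#' parent allele, so the pointed bulk is expected to approach SNP-index 1 at
#' a recessive causal locus.
#'
#' @aliases BulkCounts-class
#' @exportClass BulkCounts
setClass("BulkCounts",
         contains = "RangedSummarizedExperiment")

setValidity("BulkCounts", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  if (!all(c("refReads", "altReads") %in% an))
    msg <- c(msg, "assays 'refReads' and 'altReads' are required")
  else {
    r <- SummarizedExperiment::assay(object, "refReads")
    a <- SummarizedExperiment::assay(object, "altReads")
    if (any(r < 0, na.rm = TRUE) || any(a < 0, na.rm = TRUE))
      msg <- c(msg, "read counts must be non-negative")
  }
  if (!identical(colnames(object), c("pointed", "non_pointed")))
    msg <- c(msg, "columns must be 'pointed' and 'non_pointed' in that order")
  rr <- SummarizedExperiment::rowRanges(object)
  if (length(rr) > 1) {
    o <- order(as.character(GenomicRanges::seqnames(rr)),
               GenomicRanges::start(rr))
    if (!identical(o, seq_along(rr)))
      msg <- c(msg, "SNPs must be sorted by (chromosome, position)")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## IndexTrack: per-SNP statistic (SNP-index or delta-SNP-index) with mask.
## ---------------------------------------------------------------------------

#' IndexTrack: per-SNP statistic track with mask
#'
#' Holds one value per SNP (`NA` = masked, e.g. below the depth filter)
#' together with the SNP positions and the read depth the value was computed
#' from. `stat` is `"snp_index"` (values in \[0, 1\]) or `"delta"`
#' (values in \[-1, 1\]).
#'
#' @aliases IndexTrack-class
#' @exportClass IndexTrack
setClass("IndexTrack",
         representation(ranges = "GRanges",
                        value = "numeric",
                        depth = "numeric",
                        stat = "character"))

setValidity("IndexTrack", function(object) {
  msg <- character()
  n <- length(object@ranges)
  if (length(object@value) != n || length(object@depth) != n)
    msg <- c(msg, "value and depth must match the number of SNPs")
  if (!object@stat %in% c("snp_index", "delta"))
    msg <- c(msg, "stat must be 'snp_index' or 'delta'")
  v <- object@value[!is.na(object@value)]
  lim <- if (identical(object@stat, "delta")) c(-1, 1) else c(0, 1)
  if (length(v) && (min(v) < lim[1] || max(v) > lim[2]))
    msg <- c(msg, sprintf("values must lie in [%g, %g]", lim[1], lim[2]))
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## WindowTrack: per-window statistic (window mean delta, pi, pi ratio, ...).
## ---------------------------------------------------------------------------

#' WindowTrack: windowed statistic track
#'
#' Sliding-window summary of a per-SNP statistic: one value per window plus
#' the number of contributing SNPs/sites, the mean SNP depth (where
#' applicable), and a mask flag for windows with too little data.
#'
#' @aliases WindowTrack-class
#' @exportClass WindowTrack
setClass("WindowTrack",
         representation(ranges = "GRanges",
                        value = "numeric",
                        nSnps = "integer",
                        meanDepth = "numeric",
                        masked = "logical",
                        stat = "character"))

setValidity("WindowTrack", function(object) {
  msg <- character()
  n <- length(object@ranges)
  if (length(object@value) != n || length(object@nSnps) != n ||
      length(object@masked) != n || length(object@meanDepth) != n)
    msg <- c(msg, "per-window vectors must match the number of windows")
  if (any(!object@masked & is.na(object@value)))
    msg <- c(msg, "unmasked windows must have a value")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## NullBands: simulated no-QTL envelopes for the windowed delta-SNP-index.
## ---------------------------------------------------------------------------

#' NullBands: Monte-Carlo confidence envelopes for windowed delta-SNP-index
#'
#' Two-sided 95% and 99% empirical envelopes of the window-mean
#' delta-SNP-index under the null hypothesis of no QTL, tabulated over a grid
#' of read-depth classes and window SNP-count classes. Windows are keyed to
#' the nearest class when regions are called.
#'
#' @aliases NullBands-class
#' @exportClass NullBands
setClass("NullBands",
         representation(table = "data.frame",
                        bulkSize = "integer",
                        nRep = "integer",
                        seed = "integer"))

setValidity("NullBands", function(object) {
  msg <- character()
  tb <- object@table
  need <- c("depth", "m", "lower99", "lower95", "upper95", "upper99")
  if (!all(need %in% colnames(tb)))
    msg <- c(msg, paste("table must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (any(tb$lower95 < tb$lower99) || any(tb$upper95 > tb$upper99))
      msg <- c(msg, "95% band must lie inside the 99% band")
    if (any(abs(c(tb$lower99, tb$upper99)) > 1))
      msg <- c(msg, "band bounds must lie in [-1, 1]")
  }
  if (object@nRep < 1000)
    msg <- c(msg, "nRep must be at least 1000")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## AssocScan: per-SNP mixed-model association results + scan-level summaries.
## ---------------------------------------------------------------------------

#' AssocScan: genome-wide association scan results
#'
#' Per-SNP Wald effect estimates, standard errors and p-values from the
#' linear mixed-model scan, together with the scan-level Bonferroni
#' suggestive/significance thresholds and the genomic inflation factor
#' lambda.
#'
#' @aliases AssocScan-class
#' @exportClass AssocScan
setClass("AssocScan",
         representation(ranges = "GRanges",
                        beta = "numeric",
                        se = "numeric",
                        p = "numeric",
                        delta = "numeric",
                        suggestive = "numeric",
                        significant = "numeric",
                        lambda = "numeric"))

setValidity("AssocScan", function(object) {
  msg <- character()
  n <- length(object@ranges)
  if (length(object@beta) != n || length(object@se) != n ||
      length(object@p) != n)
    msg <- c(msg, "beta, se, p must match the number of SNPs")
  pv <- object@p[!is.na(object@p)]
  if (length(pv) && (min(pv) <= 0 || max(pv) > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Simulation specifications.
## ---------------------------------------------------------------------------

#' GenomeSpec: chromosomes, SNP positions and a recombination map
#'
#' @aliases GenomeSpec-class
#' @exportClass GenomeSpec
setClass("GenomeSpec",
         representation(chromLengths = "numeric",
                        snpPositions = "list",
                        recombRate = "numeric"))

setValidity("GenomeSpec", function(object) {
  msg <- character()
  cl <- object@chromLengths
  if (is.null(names(cl)) || any(!nzchar(names(cl))))
    msg <- c(msg, "chromosomes must be named")
  if (any(cl <= 0)) msg <- c(msg, "chromosome lengths must be positive")
  if (!identical(sort(names(object@snpPositions)), sort(names(cl))))
    msg <- c(msg, "snpPositions must be a list named by chromosome")
  for (chr in names(object@snpPositions)) {
    p <- object@snpPositions[[chr]]
    if (length(p) && (any(diff(p) <= 0)))
      msg <- c(msg, sprintf("positions on %s must be strictly increasing", chr))
    if (length(p) && (min(p) < 1 || max(p) > cl[[chr]]))
      msg <- c(msg, sprintf("positions on %s must lie within the chromosome", chr))
  }
  if (any(object@recombRate < 0))
    msg <- c(msg, "recombRate must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CrossDesign: F2 cross and pooled bulk sequencing design
#'
#' @aliases CrossDesign-class
#' @exportClass CrossDesign
setClass("CrossDesign",
         representation(nF2 = "integer",
                        causalChrom = "character",
                        causalPos = "numeric",
                        model = "character",
                        bulkSize = "integer",
                        depth = "numeric",
                        seqError = "numeric"))

setValidity("CrossDesign", function(object) {
  msg <- character()
  if (2L * object@bulkSize > object@nF2)
    msg <- c(msg, "need 2 * bulkSize <= nF2")
  if (object@depth <= 0) msg <- c(msg, "depth must be positive")
  if (object@seqError < 0 || object@seqError >= 0.5)
    msg <- c(msg, "seqError must lie in [0, 0.5)")
  if (!object@model %in% c("recessive", "dominant", "additive"))
    msg <- c(msg, "model must be recessive, dominant or additive")
  if (length(msg)) msg else TRUE
})

#' PanelSpec: structured diversity-panel simulation design
#'
#' @aliases PanelSpec-class
#' @exportClass PanelSpec
setClass("PanelSpec",
         representation(groupSizes = "integer",
                        causalFreq = "numeric",
                        nSnps = "integer",
                        chromLengths = "numeric",
                        causalChrom = "character",
                        causalPos = "numeric",
                        sweepChrom = "character",
                        sweepStart = "numeric",
                        sweepEnd = "numeric",
                        sweepShrink = "numeric",
                        drift = "numeric",
                        derivedGroups = "character"))

setValidity("PanelSpec", function(object) {
  msg <- character()
  if (any(object@groupSizes <= 0L))
    msg <- c(msg, "group sizes must be positive")
  if (!identical(names(object@groupSizes), names(object@causalFreq)))
    msg <- c(msg, "groupSizes and causalFreq must share group names")
  if (any(object@causalFreq < 0 | object@causalFreq > 1))
    msg <- c(msg, "causal allele frequencies must lie in [0, 1]")
  if (!object@sweepChrom %in% names(object@chromLengths))
    msg <- c(msg, "sweep chromosome not in the genome")
  else if (object@sweepStart < 1 ||
           object@sweepEnd > object@chromLengths[[object@sweepChrom]] ||
           object@sweepStart >= object@sweepEnd)
    msg <- c(msg, "sweep region must lie within the genome")
  if (object@sweepShrink < 0 || object@sweepShrink > 1)
    msg <- c(msg, "sweepShrink must lie in [0, 1]")
  if (!all(object@derivedGroups %in% names(object@groupSizes)))
    msg <- c(msg, "derivedGroups must be group names")
  if (length(msg)) msg else TRUE
})
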