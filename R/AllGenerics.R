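#' Extract the dosage matrix
#'
#' @param x a [GenotypeData] object.
#' @return Integer matrix of alternate-allele dosages (SNPs x samples),
#'   `NA` for missing calls.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' SNP coordinates of a track or container
#'
#' @param x a tipmapr object holding per-SNP or per-window data.
#' @return A [GenomicRanges::GRanges].
#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' Per-SNP or per-window statistic values
#'
#' @param x a track object ([IndexTrack] or [WindowTrack]).
#' @return Numeric vector, `NA` where masked.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' Convert a tipmapr object to a plain data.frame
#'
#' @param x a tipmapr track/scan object.
#' @return A base `data.frame` with one row per SNP or window.
#' @export
setGeneric("asTable", function(x) standardGeneric("asTable"))
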