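#' @importFrom methods new validObject is slot setValidity show as
#' @importFrom stats rbinom rpois runif rbeta quantile median cor pt qchisq
#'   setNames complete.cases
#' @importFrom utils read.delim write.table head
NULL

## round-half-up (base round() is banker's rounding; reported percentages
## must round 21.854... -> 21.85 and 1.85 -> 1.9 regardless of parity)
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## derive a stage seed from a master seed; kept inside 32-bit integer range
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * offset) %% 2147483647L)
}

withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopIfNot <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
}

#' Tile a genome with sliding windows
#'
#' Builds sliding windows of `windowBp` advancing by `stepBp` along each
#' chromosome. Terminal windows shorter than `windowBp` are kept and marked
#' via the `short` metadata column rather than dropped, so window sets tile
#' the whole chromosome.
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param windowBp window size in bp.
#' @param stepBp step between window starts in bp.
#' @return A [GenomicRanges::GRanges] of windows (1-based closed intervals)
#'   with a logical `short` metadata column.
#' @export
slidingWindows <- function(chromLengths, windowBp = 1e6, stepBp = 2e5) {
  stopIfNot(windowBp >= stepBp && stepBp > 0,
            "need windowBp >= stepBp > 0")
  stopIfNot(length(names(chromLengths)) == length(chromLengths),
            "chromLengths must be named")
  grs <- lapply(names(chromLengths), function(chr) {
    len <- chromLengths[[chr]]
    starts <- seq(1, len, by = stepBp)
    ends <- pmin(starts + windowBp - 1, len)
    GenomicRanges::GRanges(chr, IRanges::IRanges(starts, ends),
                           short = (ends - starts + 1) < windowBp)
  })
  gr <- suppressWarnings(do.call(c, grs))
  GenomeInfoDb::seqlengths(gr) <- chromLengths[GenomeInfoDb::seqlevels(gr)]
  gr
}

## write a GRanges as BED (0-based half-open); the single place where the
## internal 1-based closed convention is converted
writeBed <- function(gr, path, extraCols = NULL) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   stringsAsFactors = FALSE)
  if (!is.null(extraCols)) df <- cbind(df, extraCols)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

## snp identifiers in the ch05_64012700 style
snpIdFrom <- function(chrom, pos) paste(chrom, pos, sep = "_")
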