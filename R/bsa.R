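## Bulked-segregant QTL mapping: SNP-index, delta-SNP-index, sliding-window
## averaging, Monte-Carlo no-QTL confidence bands, and region calling.

#' Per-SNP SNP-index of one bulk
#'
#' SNP-index = alt reads / (ref + alt reads), the fraction of pooled reads
#' carrying the pointed-tip parent allele. SNPs whose total depth falls
#' below `minDepth` are masked (`NA`) and counted in a message.
#'
#' @param counts a [BulkCounts].
#' @param bulk `"pointed"` or `"non_pointed"`.
#' @param minDepth minimum total read depth for an unmasked index.
#' @return An [IndexTrack] with `stat = "snp_index"`.
#' @examples
#' bc <- BulkCounts("ch05", c(100, 200), refPointed = c(35, 70),
#'                  altPointed = c(35, 0), refNon = c(35, 35),
#'                  altNon = c(35, 35))
#' trackValues(snpIndex(bc, "pointed", minDepth = 10))
#' @export
snpIndex <- function(counts, bulk = c("pointed", "non_pointed"),
                     minDepth = 10) {
  if (!bulk[1] %in% c("pointed", "non_pointed"))
    stop("unknown bulk label '", bulk[1],
         "'; expected 'pointed' or 'non_pointed'", call. = FALSE)
  bulk <- match.arg(bulk)
  ref <- assay(counts, "refReads")[, bulk]
  alt <- assay(counts, "altReads")[, bulk]
  tot <- ref + alt
  idx <- ifelse(tot > 0, alt / tot, NA_real_)
  low <- tot < minDepth
  idx[low] <- NA_real_
  if (any(low))
    message(sum(low), " SNP(s) masked below depth ", minDepth,
            " in the ", bulk, " bulk")
  IndexTrack(rowRanges(counts), idx, tot, "snp_index")
}

#' Delta-SNP-index between the two bulks
#'
#' Delta = SNP-index(non-pointed bulk) - SNP-index(pointed bulk) per SNP.
#' With the alternate allele oriented to the pointed-tip parent, a recessive
#' pointed-tip locus drives delta toward -2/3 (pointed bulk index 1,
#' non-pointed bulk index 1/3), so causal peaks are negative under this sign
#' convention. A SNP is masked if it is masked in either input.
#'
#' @param pointed,nonPointed [IndexTrack]s over the same SNP set.
#' @return An [IndexTrack] with `stat = "delta"`, values in \[-1, 1\];
#'   `depth` holds the mean of the two bulk depths.
#' @export
deltaSnpIndex <- function(pointed, nonPointed) {
  r1 <- pointed@ranges; r2 <- nonPointed@ranges
  same <- length(r1) == length(r2) &&
    all(as.character(seqnames(r1)) == as.character(seqnames(r2))) &&
    all(start(r1) == start(r2))
  if (!same) {
    n <- min(length(r1), length(r2))
    bad <- if (n == 0) 1L else {
      diffs <- which(as.character(seqnames(r1))[seq_len(n)] !=
                       as.character(seqnames(r2))[seq_len(n)] |
                     start(r1)[seq_len(n)] != start(r2)[seq_len(n)])
      if (length(diffs)) diffs[1] else n + 1L
    }
    loc <- if (bad <= length(r1))
      sprintf("%s:%d", as.character(seqnames(r1))[bad], start(r1)[bad])
    else
      sprintf("%s:%d", as.character(seqnames(r2))[bad], start(r2)[bad])
    stop("tracks do not share the SNP set; first discordant position: ",
         loc, call. = FALSE)
  }
  IndexTrack(r1, nonPointed@value - pointed@value,
             (pointed@depth + nonPointed@depth) / 2, "delta")
}

#' Sliding-window average of a per-SNP track
#'
#' Unweighted mean of the unmasked SNP values falling in each window of
#' `windowBp` advanced by `stepBp` (the mapping default: 1000-kb windows,
#' 200-kb step). Windows with fewer than `minSnps` unmasked SNPs are
#' masked; terminal windows shorter than `windowBp` are kept and flagged.
#'
#' @param track an [IndexTrack].
#' @param windowBp,stepBp window size and step in bp.
#' @param minSnps minimum unmasked SNPs for an unmasked window.
#' @param lengths optional named chromosome lengths; defaults to the track's
#'   `seqlengths` or, failing that, the largest SNP position per chromosome.
#' @return A [WindowTrack] (same `stat` as the input); `meanDepth` is the
#'   mean depth of the contributing SNPs.
#' @export
windowAverage <- function(track, windowBp = 1e6, stepBp = 2e5, minSnps = 10,
                          lengths = NULL) {
  rr <- track@ranges
  if (is.null(lengths)) {
    lengths <- seqlengths(rr)
    obs <- tapply(end(rr), as.character(seqnames(rr)), max)
    miss <- is.na(lengths)
    lengths[miss] <- obs[seqlevels(rr)[miss]]
    lengths <- setNames(as.numeric(lengths), seqlevels(rr))
  }
  win <- slidingWindows(lengths, windowBp, stepBp)
  ok <- !is.na(track@value)
  hits <- findOverlaps(rr[ok], win)
  val <- tapply(track@value[ok][queryHits(hits)], subjectHits(hits), mean)
  dep <- tapply(track@depth[ok][queryHits(hits)], subjectHits(hits), mean)
  cnt <- tabulate(subjectHits(hits), nbins = length(win))
  value <- rep(NA_real_, length(win))
  meanDepth <- rep(NA_real_, length(win))
  idx <- as.integer(names(val))
  value[idx] <- val
  meanDepth[idx] <- dep
  masked <- cnt < minSnps
  value[masked] <- NA_real_
  WindowTrack(win, value, cnt, meanDepth, masked, track@stat)
}

## one batch of null window-mean deltas: per bulk, the bulk alternate-allele
## frequency at an unlinked SNP is Binomial(2 * bulkSize, 1/2) / (2 * bulkSize)
## (sum of 1:2:1 F2 dosages = sum of 2*bulkSize fair alleles), reads are
## Binomial(depth, p), and a window mean averages m independent SNP deltas
.nullWindowDelta <- function(n, bulkSize, depth, m) {
  draw <- function() {
    p <- rbinom(n * m, 2L * bulkSize, 0.5) / (2 * bulkSize)
    rbinom(n * m, depth, p) / depth
  }
  d <- draw() - draw()
  if (m == 1L) d else rowMeans(matrix(d, nrow = n, ncol = m))
}

#' Draw window-mean delta-SNP-index values under the no-QTL null
#'
#' Monte-Carlo sampler underlying [nullDeltaBands()]: each draw simulates
#' two bulks of `bulkSize` F2 individuals at an unlinked locus (genotypes
#' 0/1/2 with probabilities 1/4, 1/2, 1/4), binomial read sampling at
#' `depth`, and averages `m` independent SNP-level deltas.
#'
#' @param n number of window-mean draws.
#' @param bulkSize individuals per bulk.
#' @param depth reads per SNP per bulk.
#' @param m SNPs per window.
#' @param seed integer seed.
#' @return Numeric vector of `n` null window-mean delta values.
#' @export
sampleNullWindowDelta <- function(n, bulkSize, depth, m, seed) {
  stopIfNot(depth > 0 && bulkSize > 0 && m > 0, "invalid null parameters")
  withSeed(seed, .nullWindowDelta(as.integer(n), as.integer(bulkSize),
                                  as.integer(depth), as.integer(m)))
}

#' Monte-Carlo confidence bands for the windowed delta-SNP-index
#'
#' Tabulates two-sided 95% and 99% empirical envelopes (2.5/97.5 and
#' 0.5/99.5 percentiles) of the null window-mean delta over a grid of read
#' depths and window SNP counts. The window-level null treats SNPs within a
#' window as independent, which ignores linkage between neighbouring SNPs
#' and therefore makes the bands slightly anti-conservative for dense
#' windows on a real segregating chromosome.
#'
#' @param bulkSize individuals per bulk.
#' @param depths numeric vector of depth classes (e.g. deciles of observed
#'   per-SNP depth).
#' @param snpCounts integer vector of window SNP-count classes.
#' @param nRep Monte-Carlo replicates per class (>= 1000).
#' @param seed integer seed.
#' @return A [NullBands] object.
#' @export
nullDeltaBands <- function(bulkSize, depths, snpCounts, nRep = 10000, seed) {
  nRep <- as.integer(nRep)
  stopIfNot(nRep >= 1000L, "nRep must be at least 1000")
  grid <- expand.grid(depth = as.integer(round(depths)),
                      m = as.integer(snpCounts))
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      x <- .nullWindowDelta(nRep, as.integer(bulkSize),
                            grid$depth[i], grid$m[i])
      q <- quantile(x, c(0.005, 0.025, 0.975, 0.995), names = FALSE)
      data.frame(depth = grid$depth[i], m = grid$m[i],
                 lower99 = q[1], lower95 = q[2],
                 upper95 = q[3], upper99 = q[4])
    })
    new("NullBands", table = do.call(rbind, rows),
        bulkSize = as.integer(bulkSize), nRep = nRep,
        seed = as.integer(seed))
  })
}

## nearest band class for each window (Euclidean in depth and SNP count,
## each on its own scale)
.bandLookup <- function(bands, meanDepth, nSnps) {
  tb <- bands@table
  dClasses <- sort(unique(tb$depth))
  mClasses <- sort(unique(tb$m))
  nearest <- function(x, classes)
    classes[pmax(1L, findInterval(x, (classes[-1] + classes[-length(classes)]) / 2) + 1L)]
  d <- if (length(dClasses) == 1L) rep(dClasses, length(meanDepth))
       else nearest(meanDepth, dClasses)
  m <- if (length(mClasses) == 1L) rep(mClasses, length(nSnps))
       else nearest(nSnps, mClasses)
  key <- paste(d, m)
  rowIdx <- match(key, paste(tb$depth, tb$m))
  tb[rowIdx, , drop = FALSE]
}

#' Call QTL regions from windowed deltas and null bands
#'
#' Flags unmasked windows whose mean delta falls outside the band (at the
#' chosen level) of their nearest depth/SNP-count class, and merges
#' overlapping or adjacent flagged windows on a chromosome into regions.
#'
#' @param windows a [WindowTrack] of window-mean deltas.
#' @param bands a [NullBands].
#' @param level 95 or 99.
#' @return A [GenomicRanges::GRanges] of merged significant regions with
#'   metadata columns `peakValue` (the most extreme window mean inside the
#'   region) and `level`; empty when no window is significant.
#' @export
callQtlRegions <- function(windows, bands, level = c(95, 99)) {
  level <- as.integer(level[1])
  stopIfNot(level %in% c(95L, 99L), "level must be 95 or 99")
  ok <- !windows@masked & !is.na(windows@value)
  if (!any(ok)) return(GRanges())
  tb <- .bandLookup(bands, windows@meanDepth[ok], windows@nSnps[ok])
  lo <- tb[[sprintf("lower%d", level)]]
  hi <- tb[[sprintf("upper%d", level)]]
  sig <- windows@value[ok] < lo | windows@value[ok] > hi
  if (!any(sig)) return(GRanges())
  sigWin <- windows@ranges[ok][sig]
  sigVal <- windows@value[ok][sig]
  regions <- reduce(sigWin, min.gapwidth = 1L)
  hits <- findOverlaps(sigWin, regions)
  peak <- tapply(sigVal[queryHits(hits)], subjectHits(hits),
                 function(v) v[which.max(abs(v))])
  mcols(regions)$peakValue <- as.numeric(peak)
  mcols(regions)$level <- level
  regions
}
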