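## Constructors, accessors and show methods for the data containers.

#' Construct a GenotypeData object
#'
#' @param dosage integer matrix of alternate-allele dosages, SNPs in rows and
#'   samples in columns; values 0/1/2 or `NA`.
#' @param chrom,pos chromosome name and 1-based position per SNP.
#' @param ref,alt reference and alternate allele (single bases); recycled.
#' @param sampleData optional `DataFrame`/data.frame of per-sample metadata.
#' @param chromLengths optional named vector of chromosome lengths, recorded
#'   as `seqlengths`.
#' @return A [GenotypeData] object sorted by (chromosome, position).
#' @examples
#' gt <- GenotypeData(matrix(c(0L, 1L, 2L, 0L), 2), chrom = "ch05",
#'                    pos = c(100, 200))
#' dosage(gt)
#' @export
GenotypeData <- function(dosage, chrom, pos, ref = "A", alt = "G",
                         sampleData = NULL, chromLengths = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- nrow(dosage)
  chrom <- rep_len(as.character(chrom), n)
  ref <- rep_len(as.character(ref), n)
  alt <- rep_len(as.character(alt), n)
  o <- order(chrom, pos)
  dosage <- dosage[o, , drop = FALSE]
  rr <- GRanges(chrom[o], IRanges(pos[o], width = 1L),
                ref = ref[o], alt = alt[o])
  if (!is.null(chromLengths))
    seqlengths(rr) <- chromLengths[seqlevels(rr)]
  rownames(dosage) <- snpIdFrom(chrom[o], pos[o])
  names(rr) <- rownames(dosage)
  if (is.null(colnames(dosage)))
    colnames(dosage) <- sprintf("S%04d", seq_len(ncol(dosage)))
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(dosage))
  } else {
    DataFrame(sampleData, row.names = colnames(dosage))
  }
  new("GenotypeData",
      SummarizedExperiment(assays = list(dosage = dosage),
                           rowRanges = rr, colData = cd))
}

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeData", function(x) assay(x, "dosage"))

#' Chromosome lengths known to a GenotypeData object
#'
#' Returns the recorded `seqlengths`; chromosomes without a recorded length
#' fall back to the largest observed SNP position.
#'
#' @param x a [GenotypeData] or [BulkCounts] object.
#' @return Named numeric vector of chromosome lengths.
#' @export
chromLengths <- function(x) {
  rr <- rowRanges(x)
  sl <- seqlengths(rr)
  obs <- tapply(end(rr), as.character(seqnames(rr)), max)
  out <- sl[seqlevels(rr)]
  miss <- is.na(out)
  out[miss] <- obs[seqlevels(rr)[miss]]
  setNames(as.numeric(out), seqlevels(rr))
}

setMethod("show", "GenotypeData", function(object) {
  cat(sprintf("GenotypeData: %d SNPs x %d samples on %s\n",
              nrow(object), ncol(object),
              paste(seqlevels(rowRanges(object)), collapse = ", ")))
  d <- dosage(object)
  cat(sprintf("  missing calls: %.2f%%; sample metadata: %s\n",
              100 * mean(is.na(d)),
              if (ncol(colData(object))) {
                paste(colnames(colData(object)), collapse = ", ")
              } else "none"))
})

#' Construct a BulkCounts object
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param refPointed,altPointed,refNon,altNon per-SNP read counts for the
#'   pointed and non-pointed bulks; the alternate allele is the pointed-tip
#'   parent allele.
#' @param chromLengths optional named chromosome lengths.
#' @return A [BulkCounts] object sorted by (chromosome, position).
#' @export
BulkCounts <- function(chrom, pos, refPointed, altPointed, refNon, altNon,
                       chromLengths = NULL) {
  n <- length(pos)
  chrom <- rep_len(as.character(chrom), n)
  o <- order(chrom, pos)
  rr <- GRanges(chrom[o], IRanges(pos[o], width = 1L))
  if (!is.null(chromLengths))
    seqlengths(rr) <- chromLengths[seqlevels(rr)]
  ref <- cbind(pointed = as.integer(refPointed[o]),
               non_pointed = as.integer(refNon[o]))
  alt <- cbind(pointed = as.integer(altPointed[o]),
               non_pointed = as.integer(altNon[o]))
  ids <- snpIdFrom(chrom[o], pos[o])
  rownames(ref) <- rownames(alt) <- ids
  names(rr) <- ids
  new("BulkCounts",
      SummarizedExperiment(assays = list(refReads = ref, altReads = alt),
                           rowRanges = rr))
}

setMethod("show", "BulkCounts", function(object) {
  tot <- assay(object, "refReads") + assay(object, "altReads")
  cat(sprintf("BulkCounts: %d SNPs, bulks %s; mean depth %.1f\n",
              nrow(object), paste(colnames(object), collapse = "/"),
              mean(tot)))
})

#' @rdname asTable
#' @export
setMethod("asTable", "BulkCounts", function(x) {
  rr <- rowRanges(x)
  data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
             ref_reads_bulk1 = assay(x, "refReads")[, "pointed"],
             alt_reads_bulk1 = assay(x, "altReads")[, "pointed"],
             ref_reads_bulk2 = assay(x, "refReads")[, "non_pointed"],
             alt_reads_bulk2 = assay(x, "altReads")[, "non_pointed"],
             row.names = NULL, stringsAsFactors = FALSE)
})

## ---------------------------------------------------------------------------
## IndexTrack / WindowTrack
## ---------------------------------------------------------------------------

IndexTrack <- function(ranges, value, depth, stat) {
  new("IndexTrack", ranges = ranges, value = as.numeric(value),
      depth = as.numeric(depth), stat = stat)
}

WindowTrack <- function(ranges, value, nSnps, meanDepth, masked, stat) {
  new("WindowTrack", ranges = ranges, value = as.numeric(value),
      nSnps = as.integer(nSnps), meanDepth = as.numeric(meanDepth),
      masked = as.logical(masked), stat = stat)
}

#' @rdname trackRanges
#' @export
setMethod("trackRanges", "IndexTrack", function(x) x@ranges)

#' @rdname trackRanges
#' @export
setMethod("trackRanges", "WindowTrack", function(x) x@ranges)

#' @rdname trackValues
#' @export
setMethod("trackValues", "IndexTrack",
          function(x) setNames(x@value, names(x@ranges)))

#' @rdname trackValues
#' @export
setMethod("trackValues", "WindowTrack", function(x) x@value)

#' Number of contributing SNPs/sites per window
#' @param x a [WindowTrack].
#' @return Integer vector.
#' @export
windowNSnps <- function(x) x@nSnps

#' Window mask flags
#' @param x a [WindowTrack].
#' @return Logical vector, `TRUE` where the window is masked.
#' @export
windowMasked <- function(x) x@masked

setMethod("show", "IndexTrack", function(object) {
  cat(sprintf("IndexTrack (%s): %d SNPs, %d masked; range [%.3f, %.3f]\n",
              object@stat, length(object@ranges), sum(is.na(object@value)),
              suppressWarnings(min(object@value, na.rm = TRUE)),
              suppressWarnings(max(object@value, na.rm = TRUE))))
})

setMethod("show", "WindowTrack", function(object) {
  cat(sprintf("WindowTrack (%s): %d windows, %d masked\n",
              object@stat, length(object@ranges), sum(object@masked)))
})

#' @rdname asTable
#' @export
setMethod("asTable", "IndexTrack", function(x) {
  data.frame(chrom = as.character(seqnames(x@ranges)),
             pos = start(x@ranges), value = x@value, depth = x@depth,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' @rdname asTable
#' @export
setMethod("asTable", "WindowTrack", function(x) {
  data.frame(chrom = as.character(seqnames(x@ranges)),
             start = start(x@ranges), end = end(x@ranges),
             value = x@value, n_snps = x@nSnps, mean_depth = x@meanDepth,
             masked = x@masked, row.names = NULL, stringsAsFactors = FALSE)
})

setMethod("show", "NullBands", function(object) {
  cat(sprintf(
    "NullBands: bulk size %d, %d replicates, %d depth x %d SNP-count classes\n",
    object@bulkSize, object@nRep, length(unique(object@table$depth)),
    length(unique(object@table$m))))
})

#' Band lookup table of a NullBands object
#' @param x a [NullBands].
#' @return `data.frame` with columns depth, m, lower99/95, upper95/99.
#' @export
bandTable <- function(x) x@table

setMethod("show", "AssocScan", function(object) {
  ok <- !is.na(object@p)
  cat(sprintf("AssocScan: %d SNPs tested (%d skipped)\n",
              sum(ok), sum(!ok)))
  cat(sprintf("  thresholds: suggestive %.3g, significant %.3g; lambda %.3f\n",
              object@suggestive, object@significant, object@lambda))
  if (any(ok)) {
    i <- which.min(object@p)
    cat(sprintf("  top SNP: %s (p = %.3g)\n",
                names(object@ranges)[i], object@p[i]))
  }
})

#' @rdname asTable
#' @export
setMethod("asTable", "AssocScan", function(x) {
  data.frame(chrom = as.character(seqnames(x@ranges)),
             pos = start(x@ranges), beta = x@beta, se = x@se, p = x@p,
             row.names = NULL, stringsAsFactors = FALSE)
})

#' Scan-level summaries of an AssocScan
#' @param x an [AssocScan].
#' @return Named list with `suggestive`, `significant`, `lambda`, and the
#'   id/position/p-value of the lead SNP.
#' @export
scanSummary <- function(x) {
  i <- which.min(x@p)
  list(suggestive = x@suggestive, significant = x@significant,
       lambda = x@lambda,
       leadSnp = names(x@ranges)[i],
       leadChrom = as.character(seqnames(x@ranges))[i],
       leadPos = start(x@ranges)[i],
       leadP = unname(x@p[i]))
}
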