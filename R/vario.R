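## Variant and count-table IO. Coordinates in files are 1-based (VCF/TSV
## convention); BED output (writeBed) is the only 0-based half-open format.

#' Read biallelic SNP genotypes from a VCF file
#'
#' Parses VCF v4.x via `vcfR` and keeps biallelic SNP records only;
#' multiallelic and non-SNP records are skipped and the skip count reported
#' with a message. `GT` is parsed to alternate-allele dosage regardless of
#' the phasing separator (`0/1` and `0|1` both give 1); `./.` gives `NA`.
#' INFO and FILTER are ignored.
#'
#' @param path path to a (plain-text or gzipped) VCF file.
#' @return A [GenotypeData].
#' @export
readGenotypeVcf <- function(path) {
  stopIfNot(file.exists(path), "no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(!keep))
    message(sum(!keep), " non-biallelic-SNP record(s) skipped")
  stopIfNot(any(keep), "no biallelic SNP records in ", path)
  gtRaw <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  a1 <- substr(gsub("|", "/", gtRaw, fixed = TRUE), 1, 1)
  a2 <- substr(gsub("|", "/", gtRaw, fixed = TRUE), 3, 3)
  toNum <- function(a) ifelse(a %in% c("0", "1"), as.integer(a), NA_integer_)
  dos <- matrix(toNum(a1) + toNum(a2), nrow = sum(keep),
                dimnames = dimnames(gtRaw))
  lens <- .contigLengths(v)
  GenotypeData(dos, chrom = fix[keep, "CHROM"],
               pos = as.numeric(fix[keep, "POS"]),
               ref = ref[keep], alt = alt[keep],
               chromLengths = lens)
}

.contigLengths <- function(v) {
  meta <- v@meta
  cl <- meta[grepl("^##contig=", meta)]
  if (!length(cl)) return(NULL)
  ids <- sub(".*ID=([^,>]+).*", "\\1", cl)
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", cl)))
  if (anyNA(lens)) return(NULL)
  setNames(lens, ids)
}

#' Write genotypes as a minimal VCF
#'
#' Emits VCF v4.2 with contig header lines, biallelic SNP records, and a
#' single `GT` FORMAT subfield. Round-trips through [readGenotypeVcf()].
#'
#' @param gt a [GenotypeData].
#' @param path output path.
#' @return The path, invisibly.
#' @export
writeGenotypeVcf <- function(gt, path) {
  rr <- rowRanges(gt)
  lens <- chromLengths(gt)
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(lens), as.integer(lens)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(gt)), collapse = "\t"))
  d <- dosage(gt)
  gtStr <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gtStr[is.na(gtStr)] <- "./."
  body <- paste(as.character(seqnames(rr)), start(rr), names(rr),
                mcols(rr)$ref, mcols(rr)$alt, ".", ".", ".", "GT",
                apply(gtStr, 1, paste, collapse = "\t"), sep = "\t")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, body), con)
  invisible(path)
}

#' Write/read genotypes as a wide TSV
#'
#' Columns `chrom pos ref alt` followed by one dosage column per sample
#' (`NA` for missing calls).
#'
#' @param gt a [GenotypeData].
#' @param path file path.
#' @return `writeGenotypeTsv` returns the path invisibly;
#'   `readGenotypeTsv` returns a [GenotypeData].
#' @export
writeGenotypeTsv <- function(gt, path) {
  rr <- rowRanges(gt)
  df <- data.frame(chrom = as.character(seqnames(rr)), pos = start(rr),
                   ref = mcols(rr)$ref, alt = mcols(rr)$alt,
                   dosage(gt), check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeGenotypeTsv
#' @export
readGenotypeTsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopIfNot(all(c("chrom", "pos", "ref", "alt") %in% colnames(df)),
            "genotype TSV must have chrom/pos/ref/alt columns")
  samples <- setdiff(colnames(df), c("chrom", "pos", "ref", "alt"))
  GenotypeData(as.matrix(df[, samples, drop = FALSE]),
               chrom = df$chrom, pos = df$pos, ref = df$ref, alt = df$alt)
}

#' Write/read per-bulk allele read counts as TSV
#'
#' Header `chrom pos ref_reads_bulk1 alt_reads_bulk1 ref_reads_bulk2
#' alt_reads_bulk2`, with bulk1 = pointed and bulk2 = non-pointed.
#' Negative counts are rejected on read.
#'
#' @param counts a [BulkCounts].
#' @param path file path.
#' @return `writeBulkCounts` returns the path invisibly; `readBulkCounts`
#'   returns a [BulkCounts].
#' @export
writeBulkCounts <- function(counts, path) {
  write.table(asTable(counts), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeBulkCounts
#' @export
readBulkCounts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref_reads_bulk1", "alt_reads_bulk1",
            "ref_reads_bulk2", "alt_reads_bulk2")
  stopIfNot(all(need %in% colnames(df)),
            "counts TSV must have columns ", paste(need, collapse = " "))
  cnt <- as.matrix(df[, need[-(1:2)]])
  if (nrow(df) && any(cnt < 0, na.rm = TRUE))
    stop("negative read counts in ", path, call. = FALSE)
  BulkCounts(chrom = df$chrom, pos = df$pos,
             refPointed = df$ref_reads_bulk1,
             altPointed = df$alt_reads_bulk1,
             refNon = df$ref_reads_bulk2,
             altNon = df$alt_reads_bulk2)
}

#' Write/read accession metadata as TSV
#'
#' Columns `accession group theta tip_code`; `theta` (tip angle in degrees)
#' may be `NA` where only the curated binary code is available.
#'
#' @param meta data.frame with columns `accession`, `group`, `theta`,
#'   `tip_code`.
#' @param path file path.
#' @return `writeAccessionMeta` returns the path invisibly;
#'   `readAccessionMeta` returns a data.frame.
#' @export
writeAccessionMeta <- function(meta, path) {
  need <- c("accession", "group", "theta", "tip_code")
  stopIfNot(all(need %in% colnames(meta)),
            "metadata must have columns ", paste(need, collapse = " "))
  write.table(meta[, need], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeAccessionMeta
#' @export
readAccessionMeta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("accession", "group", "theta", "tip_code")
  stopIfNot(all(need %in% colnames(df)),
            "metadata TSV must have columns ", paste(need, collapse = " "))
  df
}
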