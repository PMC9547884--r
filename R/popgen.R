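## Diversity and LD layer: windowed nucleotide diversity, between-group
## pi ratios with a genome-wide top-quantile sweep threshold, per-group
## allele frequencies, pairwise r2 and haploblock extraction.

## per-site unbiased heterozygosity 2p(1-p) * n/(n-1) from allele counts;
## identical to the mean pairwise allele difference at the site
.siteHet <- function(dosageMat) {
  called <- 2 * rowSums(!is.na(dosageMat))
  altc <- rowSums(dosageMat, na.rm = TRUE)
  p <- altc / pmax(called, 1)
  h <- 2 * p * (1 - p) * called / pmax(called - 1, 1)
  h[called < 2] <- NA_real_
  h
}

#' Windowed nucleotide diversity (pi) for one sample group
#'
#' Per site, the unbiased heterozygosity 2p(1-p) n/(n-1) is computed from
#' the non-missing allele counts (n = called alleles); a window's pi is the
#' sum of its site values divided by the window length in bp, so
#' monomorphic stretches dilute pi (the conventional windowed estimator).
#' Windows with zero called sites are masked.
#'
#' @param gt a [GenotypeData].
#' @param samples optional sample names/indices (e.g. one taxonomic group);
#'   defaults to all samples.
#' @param windowBp,stepBp window size and step in bp (defaults 100 kb/10 kb).
#' @param lengths optional named chromosome lengths.
#' @return A [WindowTrack] with `stat = "pi"`; `nSnps` counts the called
#'   sites per window.
#' @export
piWindow <- function(gt, samples = NULL, windowBp = 1e5, stepBp = 1e4,
                     lengths = NULL) {
  d <- dosage(gt)
  if (!is.null(samples)) d <- d[, samples, drop = FALSE]
  stopIfNot(ncol(d) >= 2, "need at least 2 samples for pi")
  h <- .siteHet(d)
  if (is.null(lengths)) lengths <- chromLengths(gt)
  win <- slidingWindows(lengths, windowBp, stepBp)
  rr <- rowRanges(gt)
  ok <- !is.na(h)
  hits <- findOverlaps(rr[ok], win)
  hSum <- tapply(h[ok][queryHits(hits)], subjectHits(hits), sum)
  cnt <- tabulate(subjectHits(hits), nbins = length(win))
  value <- rep(NA_real_, length(win))
  value[as.integer(names(hSum))] <- hSum
  value <- value / width(win)
  masked <- cnt == 0
  WindowTrack(win, value, cnt, rep(NA_real_, length(win)), masked, "pi")
}

#' Between-group pi-ratio scan with a genome-wide top-quantile threshold
#'
#' Ratio pi(A)/pi(B) per window (conventionally A = ancestral/wild,
#' B = derived, so sweeps in the derived group give high ratios). Windows
#' where either input is masked or the denominator is zero are masked and
#' excluded from the threshold. The top `1 - q` fraction of unmasked
#' windows (by ratio) is flagged — for q = 0.95 the genome-wide "top 5%"
#' rule — and flagged windows are merged into candidate sweep regions.
#'
#' @param piA,piB [WindowTrack]s over identical windows.
#' @param q quantile defining the threshold (default 0.95).
#' @return List with `track` (a ratio [WindowTrack]), `threshold` (smallest
#'   flagged ratio), `flagged` (logical per window) and `regions`
#'   (merged [GenomicRanges::GRanges]).
#' @export
piRatioScan <- function(piA, piB, q = 0.95) {
  rA <- piA@ranges; rB <- piB@ranges
  if (length(rA) != length(rB) ||
      !all(as.character(seqnames(rA)) == as.character(seqnames(rB))) ||
      !all(start(rA) == start(rB)) || !all(end(rA) == end(rB)))
    stop("pi tracks must share identical windows", call. = FALSE)
  ratio <- piA@value / piB@value
  masked <- piA@masked | piB@masked | is.na(ratio) | !is.finite(ratio)
  ratio[masked] <- NA_real_
  nOk <- sum(!masked)
  stopIfNot(nOk > 0, "no unmasked windows")
  k <- ceiling((1 - q) * nOk - 1e-9)   # epsilon guards fp noise in 1 - q
  ord <- order(ratio, decreasing = TRUE, na.last = TRUE)
  flagged <- logical(length(ratio))
  flagged[ord[seq_len(k)]] <- TRUE
  threshold <- min(ratio[flagged])
  regions <- reduce(rA[flagged], min.gapwidth = 1L)
  track <- WindowTrack(rA, ratio, piA@nSnps, rep(NA_real_, length(ratio)),
                       masked, "pi_ratio")
  list(track = track, threshold = threshold, flagged = flagged,
       regions = regions)
}

#' Per-group frequency of an allele
#'
#' Carrier mode (default; appropriate for predominantly homozygous inbred
#' panels) reports the percentage of called samples in each group carrying
#' at least one copy of the allele; allele mode reports the percentage of
#' called chromosomes. Percentages are rounded half-up to one decimal.
#'
#' @param gt a [GenotypeData].
#' @param snp SNP id (e.g. `"ch05_6401270"`) or row index.
#' @param groups per-sample group labels; defaults to `colData(gt)$group`.
#' @param allele `"alt"` (default) or `"ref"`.
#' @param mode `"carrier"` (default) or `"allele"`.
#' @return data.frame with columns `group`, `n_called`, `n_with_allele`,
#'   `freq_pct`; empty groups are flagged with `NA`.
#' @export
alleleFreqByGroup <- function(gt, snp, groups = NULL,
                              allele = c("alt", "ref"),
                              mode = c("carrier", "allele")) {
  allele <- match.arg(allele)
  mode <- match.arg(mode)
  if (is.null(groups)) groups <- colData(gt)$group
  stopIfNot(!is.null(groups) && length(groups) == ncol(gt),
            "groups must match the samples")
  d <- dosage(gt)[snp, ]
  if (allele == "ref") d <- 2L - d
  lv <- unique(groups)
  out <- do.call(rbind, lapply(lv, function(g) {
    dg <- d[groups == g]
    called <- sum(!is.na(dg))
    if (mode == "carrier") {
      cnt <- sum(dg >= 1L, na.rm = TRUE)
      tot <- called
    } else {
      cnt <- sum(dg, na.rm = TRUE)
      tot <- 2 * called
    }
    data.frame(group = g, n_called = called, n_with_allele = cnt,
               freq_pct = if (tot) roundHalfUp(100 * cnt / tot, 1)
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (any(out$n_called == 0))
    warning("empty group(s): ",
            paste(out$group[out$n_called == 0], collapse = ", "))
  out
}

#' Pairwise LD r-squared in a genomic region
#'
#' r2 between two SNPs is the squared Pearson correlation of their dosage
#' vectors over samples non-missing at both (the composite, phase-free
#' estimator). Monomorphic SNPs in the region are excluded with a message.
#'
#' @param gt a [GenotypeData].
#' @param chrom,startBp,endBp the region (1-based inclusive).
#' @return Symmetric r2 matrix with SNP ids as dimnames and unit diagonal.
#' @export
ldR2 <- function(gt, chrom, startBp, endBp) {
  rr <- rowRanges(gt)
  sel <- as.character(seqnames(rr)) == chrom &
    start(rr) >= startBp & start(rr) <= endBp
  stopIfNot(any(sel), "no SNPs in ", chrom, ":", startBp, "-", endBp)
  d <- dosage(gt)[sel, , drop = FALSE]
  v <- apply(d, 1, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1
  })
  if (any(!v))
    message(sum(!v), " monomorphic SNP(s) excluded from the r2 matrix")
  d <- d[v, , drop = FALSE]
  stopIfNot(nrow(d) >= 2, "need at least 2 polymorphic SNPs in the region")
  r <- suppressWarnings(cor(t(d), use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- 1
  r2
}

#' Extract haploblocks from an r2 matrix
#'
#' Greedy left-to-right block growth: starting from the leftmost unassigned
#' SNP, a block is extended one SNP at a time while the mean pairwise r2
#' among all SNPs in the block stays at or above `r2Min`; single-SNP spans
#' are not blocks. This mean-internal-r2 rule is a deliberate, simple
#' alternative to confidence-interval (Gabriel-style) block definitions.
#'
#' @param r2 symmetric r2 matrix from [ldR2()].
#' @param positions bp positions of the SNPs (same order as `r2`).
#' @param r2Min minimum mean internal r2 (default 0.7).
#' @param lead optional position of a lead SNP; must lie within the span of
#'   `positions`, otherwise an error is raised.
#' @return List with `blocks` (data.frame: `startIdx`, `endIdx`, `startPos`,
#'   `endPos`, `nSnps`, `meanR2`) and, when `lead` is given, `leadBlock`
#'   (the block row containing it, or `NULL` if the lead SNP is in no
#'   block).
#' @export
haploblocks <- function(r2, positions, r2Min = 0.7, lead = NULL) {
  m <- nrow(r2)
  stopIfNot(length(positions) == m, "positions must match the r2 matrix")
  if (!is.null(lead) && (lead < min(positions) || lead > max(positions)))
    stop("lead SNP position ", lead, " lies outside the region",
         call. = FALSE)
  blocks <- list()
  i <- 1L
  while (i < m) {
    j <- i
    pairSum <- 0
    nPairs <- 0
    while (j < m) {
      cand <- j + 1L
      addSum <- sum(r2[i:j, cand])
      if ((pairSum + addSum) / (nPairs + (cand - i)) >= r2Min) {
        pairSum <- pairSum + addSum
        nPairs <- nPairs + (cand - i)
        j <- cand
      } else break
    }
    if (j > i) {
      blocks[[length(blocks) + 1L]] <-
        data.frame(startIdx = i, endIdx = j,
                   startPos = positions[i], endPos = positions[j],
                   nSnps = j - i + 1L, meanR2 = pairSum / nPairs)
      i <- j + 1L
    } else i <- i + 1L
  }
  blocks <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(startIdx = integer(), endIdx = integer(),
               startPos = numeric(), endPos = numeric(),
               nSnps = integer(), meanR2 = numeric())
  out <- list(blocks = blocks)
  if (!is.null(lead)) {
    hit <- which(blocks$startPos <= lead & blocks$endPos >= lead)
    out$leadBlock <- if (length(hit)) blocks[hit[1], ] else NULL
  }
  out
}
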