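## Synthetic-data generators: F2 cross, pooled bulk sequencing, diversity panel.
## All randomness is funnelled through an explicit seed argument.

#' Construct a GenomeSpec
#'
#' @param chromLengths named numeric vector of chromosome lengths in bp.
#' @param snpPositions list of sorted 1-based SNP positions, named by
#'   chromosome. If `NULL`, SNPs are placed every `snpSpacing` bp.
#' @param recombRate expected crossovers per chromosome per gamete (Morgans);
#'   a scalar is recycled across chromosomes. The default 0.5 M over a 10-Mb
#'   chromosome corresponds to 5 cM/Mb, a euchromatin-like map density.
#' @param snpSpacing spacing used when `snpPositions` is `NULL`.
#' @return A [GenomeSpec] object.
#' @examples
#' gs <- GenomeSpec(c(ch05 = 1e6), snpSpacing = 1e5)
#' @export
GenomeSpec <- function(chromLengths, snpPositions = NULL, recombRate = 0.5,
                       snpSpacing = 1e4) {
  if (is.null(snpPositions))
    snpPositions <- lapply(chromLengths, function(len)
      seq(snpSpacing, len, by = snpSpacing))
  rr <- rep_len(recombRate, length(chromLengths))
  names(rr) <- names(chromLengths)
  new("GenomeSpec", chromLengths = chromLengths,
      snpPositions = lapply(snpPositions, as.numeric), recombRate = rr)
}

setMethod("show", "GenomeSpec", function(object) {
  cat(sprintf("GenomeSpec: %d chromosome(s), %d SNPs\n",
              length(object@chromLengths),
              sum(lengths(object@snpPositions))))
})

#' Construct a CrossDesign
#'
#' Defaults mirror the mapping design for the pointed-tip trait: an F2 of
#' 2,000 plants, two bulks of 73 individuals each, ~70x pooled depth.
#'
#' @param nF2 number of F2 individuals.
#' @param causalChrom,causalPos location of the causal locus (must be one of
#'   the genome's SNP positions).
#' @param model inheritance of the pointed-tip (alternate) allele:
#'   `"recessive"` (default), `"dominant"` or `"additive"`.
#' @param bulkSize individuals per phenotype bulk.
#' @param depth mean pooled read depth per SNP.
#' @param seqError per-read miscall probability (symmetric).
#' @return A [CrossDesign] object.
#' @export
CrossDesign <- function(nF2 = 2000, causalChrom = "ch05", causalPos = 6401270,
                        model = "recessive", bulkSize = 73, depth = 70,
                        seqError = 0.001) {
  new("CrossDesign", nF2 = as.integer(nF2),
      causalChrom = causalChrom, causalPos = as.numeric(causalPos),
      model = model, bulkSize = as.integer(bulkSize),
      depth = as.numeric(depth), seqError = as.numeric(seqError))
}

setMethod("show", "CrossDesign", function(object) {
  cat(sprintf(
    "CrossDesign: %d F2, %s locus %s:%d, bulks of %d at %.0fx\n",
    object@nF2, object@model, object@causalChrom,
    as.integer(object@causalPos), object@bulkSize, object@depth))
})

## one gamete per call-row: Poisson crossover count, uniform breakpoints,
## no interference; returns 0/1 founder-of-origin per SNP position
.simGametes <- function(nGametes, positions, chromLen, morgans) {
  m <- length(positions)
  out <- matrix(0L, nrow = m, ncol = nGametes)
  nco <- rpois(nGametes, morgans)
  phase <- sample.int(2L, nGametes, replace = TRUE) - 1L
  for (g in seq_len(nGametes)) {
    if (nco[g] == 0L) {
      out[, g] <- phase[g]
    } else {
      breaks <- sort(runif(nco[g], 0, chromLen))
      out[, g] <- (phase[g] + findInterval(positions, breaks)) %% 2L
    }
  }
  out
}

#' Simulate an F2 population from two inbred founders
#'
#' Both founders are fixed for opposite alleles at every SNP; the alternate
#' allele is the pointed-tip parent allele, so F2 dosages follow the 1:2:1
#' Mendelian ratio at unlinked loci. Each gamete receives a
#' Poisson-distributed crossover count (rate = map length in Morgans) with
#' breakpoints placed uniformly and no interference; an F2 genotype is the
#' sum of two independent F1 gametes.
#'
#' @param genome a [GenomeSpec].
#' @param design a [CrossDesign]; its causal locus must be one of the
#'   genome's SNP positions.
#' @param seed integer seed; identical seeds give identical populations.
#' @return A [GenotypeData] with `nF2` samples.
#' @examples
#' gs <- GenomeSpec(c(ch05 = 1e6), snpSpacing = 2e5)
#' cd <- CrossDesign(nF2 = 20, causalChrom = "ch05", causalPos = 6e5,
#'                   bulkSize = 5)
#' simulateF2(gs, cd, seed = 1)
#' @export
simulateF2 <- function(genome, design, seed) {
  validObject(genome); validObject(design)
  pos <- genome@snpPositions[[design@causalChrom]]
  if (is.null(pos) || !design@causalPos %in% pos)
    stop("causal locus ", design@causalChrom, ":", design@causalPos,
         " is not among the genome's SNP positions", call. = FALSE)
  n <- design@nF2
  withSeed(seed, {
    perChrom <- lapply(names(genome@chromLengths), function(chr) {
      p <- genome@snpPositions[[chr]]
      if (!length(p)) return(NULL)
      g1 <- .simGametes(n, p, genome@chromLengths[[chr]],
                        genome@recombRate[[chr]])
      g2 <- .simGametes(n, p, genome@chromLengths[[chr]],
                        genome@recombRate[[chr]])
      list(chrom = rep(chr, length(p)), pos = p, dosage = g1 + g2)
    })
    perChrom <- Filter(Negate(is.null), perChrom)
    dos <- do.call(rbind, lapply(perChrom, `[[`, "dosage"))
    colnames(dos) <- sprintf("F2_%04d", seq_len(n))
    GenotypeData(dos,
                 chrom = unlist(lapply(perChrom, `[[`, "chrom")),
                 pos = unlist(lapply(perChrom, `[[`, "pos")),
                 ref = "A", alt = "G",
                 chromLengths = genome@chromLengths)
  })
}

#' Assign the binary tip phenotype from the causal genotype
#'
#' Under the recessive model (the inheritance the blossom-end trait shows:
#' F1 heterozygotes are non-pointed) an individual is pointed (1) iff it is
#' homozygous for the pointed-tip parent (alternate) allele. The dominant
#' model scores carriers as pointed; the additive model draws pointed status
#' with probability dosage/2 and therefore requires a seed.
#'
#' @param gt a [GenotypeData].
#' @param causalChrom,causalPos the causal SNP.
#' @param model `"recessive"` (default), `"dominant"` or `"additive"`.
#' @param seed required for `model = "additive"` only.
#' @return Integer vector (0/1) named by sample; individuals with a missing
#'   causal genotype get `NA` and are reported via a message.
#' @export
assignTipPhenotype <- function(gt, causalChrom, causalPos,
                               model = c("recessive", "dominant", "additive"),
                               seed = NULL) {
  model <- match.arg(model)
  id <- snpIdFrom(causalChrom, causalPos)
  if (!id %in% rownames(gt))
    stop("causal locus ", id, " not present in the genotypes", call. = FALSE)
  d <- dosage(gt)[id, ]
  ph <- switch(model,
    recessive = as.integer(d == 2L),
    dominant = as.integer(d >= 1L),
    additive = {
      if (is.null(seed))
        stop("the additive model is stochastic; supply a seed", call. = FALSE)
      withSeed(seed, as.integer(rbinom(length(d), 1L, d / 2)))
    })
  ph[is.na(d)] <- NA_integer_
  if (anyNA(d))
    message(sum(is.na(d)),
            " individual(s) excluded: missing genotype at the causal locus")
  names(ph) <- colnames(gt)
  ph
}

#' Draw the two phenotype bulks
#'
#' Random, disjoint subsets of `bulkSize` individuals per phenotype class
#' (pointed = 1, non-pointed = 0). Selection is uniform within class;
#' deterministic under a fixed seed.
#'
#' @param phenotypes 0/1 vector (NA allowed; NA individuals are never picked).
#' @param bulkSize individuals per bulk; 0 gives empty bulks.
#' @param seed integer seed.
#' @return List with sorted index vectors `pointed` and `nonPointed`.
#' @export
formBulks <- function(phenotypes, bulkSize, seed) {
  bulkSize <- as.integer(bulkSize)
  pool1 <- which(!is.na(phenotypes) & phenotypes == 1L)
  pool0 <- which(!is.na(phenotypes) & phenotypes == 0L)
  for (cls in list(c("pointed", length(pool1)),
                   c("non-pointed", length(pool0)))) {
    if (as.integer(cls[2]) < bulkSize)
      stop("cannot form a bulk of ", bulkSize, " from ", cls[2], " ",
           cls[1], " individuals", call. = FALSE)
  }
  withSeed(seed, {
    list(pointed = sort(sample(pool1, bulkSize)),
         nonPointed = sort(sample(pool0, bulkSize)))
  })
}

#' Sample pooled sequencing reads for the two bulks
#'
#' Per SNP, one depth is drawn from Poisson(`depth`) with floor 1 and shared
#' by both bulks (mimicking "roughly 70x" coverage without modelling
#' coverage bias); with `depthModel = "fixed"` every SNP gets exactly
#' `depth` reads. For each bulk the true alternate-allele frequency is
#' p = sum(dosage) / (2 * bulk size) over called genotypes, and the observed
#' alternate read count is Binomial(depth, p(1 - e) + (1 - p)e) with
#' symmetric per-read miscall probability e.
#'
#' @param gt a [GenotypeData] containing the bulk individuals.
#' @param bulks list with index vectors `pointed` and `nonPointed`
#'   (as from [formBulks()]).
#' @param depth mean (or fixed) per-SNP pooled read depth; must be positive.
#' @param seqError per-read miscall probability.
#' @param seed integer seed.
#' @param depthModel `"poisson"` (default) or `"fixed"`.
#' @return A [BulkCounts] object; per SNP, `refReads + altReads` equals the
#'   drawn depth in both bulks.
#' @export
poolReadSample <- function(gt, bulks, depth = 70, seqError = 0.001, seed,
                           depthModel = c("poisson", "fixed")) {
  depthModel <- match.arg(depthModel)
  stopIfNot(depth > 0, "depth must be positive")
  stopIfNot(seqError >= 0 && seqError < 0.5, "seqError must lie in [0, 0.5)")
  d <- dosage(gt)
  m <- nrow(d)
  bulkFreq <- function(idx) {
    sub <- d[, idx, drop = FALSE]
    called <- 2 * rowSums(!is.na(sub))
    rowSums(sub, na.rm = TRUE) / pmax(called, 1)
  }
  withSeed(seed, {
    dp <- if (depthModel == "poisson") pmax(rpois(m, depth), 1L)
          else rep(as.integer(depth), m)
    draw <- function(p) {
      pe <- p * (1 - seqError) + (1 - p) * seqError
      alt <- rbinom(m, dp, pe)
      list(alt = alt, ref = dp - alt)
    }
    rp <- draw(bulkFreq(bulks$pointed))
    rn <- draw(bulkFreq(bulks$nonPointed))
    rr <- rowRanges(gt)
    BulkCounts(chrom = as.character(seqnames(rr)), pos = start(rr),
               refPointed = rp$ref, altPointed = rp$alt,
               refNon = rn$ref, altNon = rn$alt,
               chromLengths = chromLengths(gt))
  })
}

#' Construct a PanelSpec
#'
#' Defaults emulate the 311-accession diversity panel: 55 wild, 105 CER
#' (cherry-type intermediates) and 151 BIG (large-fruited cultivars)
#' accessions, with derived (G) causal-allele carrier frequencies rising
#' along the domestication gradient (wild 1.8%, CER 8.6%, BIG 24.5%) and a
#' reduced-diversity sweep region around the causal gene in the derived
#' groups.
#'
#' @param groupSizes named integer vector of accessions per group.
#' @param causalFreq named per-group carrier frequency of the derived causal
#'   allele; names must match `groupSizes`.
#' @param nSnps number of neutral SNPs spread over the genome.
#' @param chromLengths named chromosome lengths.
#' @param causalChrom,causalPos causal SNP location (inside the sweep).
#' @param sweepChrom,sweepStart,sweepEnd the reduced-diversity region.
#' @param sweepShrink factor by which expected heterozygosity inside the
#'   sweep is shrunk in derived groups (0.1 = tenfold reduction).
#' @param drift named per-group Balding-Nichols drift parameter F; larger
#'   values give more extreme group frequencies and lower within-group
#'   diversity (wild < CER < BIG echoes domestication diversity loss).
#' @param derivedGroups groups subject to the sweep.
#' @return A [PanelSpec] object.
#' @export
PanelSpec <- function(groupSizes = c(wild = 55L, CER = 105L, BIG = 151L),
                      causalFreq = c(wild = 0.018, CER = 0.086, BIG = 0.245),
                      nSnps = 20000,
                      chromLengths = c(ch03 = 1e7, ch05 = 1e7),
                      causalChrom = "ch05", causalPos = 6401270,
                      sweepChrom = "ch05", sweepStart = 6e6, sweepEnd = 6.6e6,
                      sweepShrink = 0.1,
                      drift = c(wild = 0.02, CER = 0.30, BIG = 0.50),
                      derivedGroups = c("CER", "BIG")) {
  gs <- setNames(as.integer(groupSizes), names(groupSizes))
  new("PanelSpec", groupSizes = gs,
      causalFreq = causalFreq[names(gs)], nSnps = as.integer(nSnps),
      chromLengths = chromLengths, causalChrom = causalChrom,
      causalPos = as.numeric(causalPos), sweepChrom = sweepChrom,
      sweepStart = as.numeric(sweepStart), sweepEnd = as.numeric(sweepEnd),
      sweepShrink = as.numeric(sweepShrink),
      drift = drift[names(gs)], derivedGroups = derivedGroups)
}

setMethod("show", "PanelSpec", function(object) {
  cat(sprintf("PanelSpec: %s accessions, %d SNPs, sweep %s:%g-%g\n",
              paste(sprintf("%d %s", object@groupSizes,
                            names(object@groupSizes)), collapse = " + "),
              object@nSnps, object@sweepChrom, object@sweepStart,
              object@sweepEnd))
})

#' Simulate a structured diversity panel
#'
#' Neutral SNPs get an ancestral allele frequency from Beta(0.8, 0.8) and
#' group-specific frequencies from the Balding-Nichols model with per-group
#' drift F, so groups share ancestry (giving PC/kinship structure) while
#' expected heterozygosity falls from wild to BIG. Inside the sweep region,
#' each derived-group site is fixed for its major allele with probability
#' 1 - `sweepShrink`, shrinking expected diversity by roughly that factor.
#' The causal SNP is simulated as homozygous carrier-vs-non-carrier at the
#' per-group carrier frequency (inbred-panel convention), and the phenotype
#' is 1 iff homozygous for the derived causal allele (fully penetrant
#' recessive).
#'
#' @param spec a [PanelSpec].
#' @param seed integer seed.
#' @return A [GenotypeData] whose `colData()` has `accession`, `group` and
#'   `phenotype`; `metadata()` records the causal SNP id and the sweep
#'   region.
#' @export
simulatePanel <- function(spec, seed) {
  validObject(spec)
  nTot <- sum(spec@groupSizes)
  groups <- rep(names(spec@groupSizes), spec@groupSizes)
  withSeed(seed, {
    ## neutral SNP positions: uniform over the genome, unique, sorted
    lens <- spec@chromLengths
    nPer <- pmax(round(spec@nSnps * lens / sum(lens)), 1L)
    chrom <- rep(names(lens), nPer)
    pos <- unlist(lapply(names(lens), function(chr)
      sort(sample.int(lens[[chr]], nPer[[chr]]))), use.names = FALSE)
    ## drop any neutral SNP colliding with the causal position
    drop <- chrom == spec@causalChrom & pos == spec@causalPos
    chrom <- chrom[!drop]; pos <- pos[!drop]
    m <- length(pos)

    p0 <- rbeta(m, 0.8, 0.8)
    inSweep <- chrom == spec@sweepChrom &
      pos >= spec@sweepStart & pos <= spec@sweepEnd
    dos <- matrix(NA_integer_, nrow = m, ncol = nTot)
    col0 <- 0L
    for (g in names(spec@groupSizes)) {
      ng <- spec@groupSizes[[g]]
      f <- spec@drift[[g]]
      pg <- if (f <= 0) p0 else
        rbeta(m, p0 * (1 - f) / f, (1 - p0) * (1 - f) / f)
      if (g %in% spec@derivedGroups && any(inSweep)) {
        fix <- inSweep & (runif(m) > spec@sweepShrink)
        pg[fix] <- as.numeric(pg[fix] > 0.5)
      }
      dos[, col0 + seq_len(ng)] <- rbinom(m * ng, 2L, rep(pg, ng))
      col0 <- col0 + ng
    }

    ## causal SNP: inbred carrier coding (dosage 2 with the carrier
    ## frequency, else 0); phenotype = homozygous derived allele
    causal <- integer(nTot)
    col0 <- 0L
    for (g in names(spec@groupSizes)) {
      ng <- spec@groupSizes[[g]]
      causal[col0 + seq_len(ng)] <-
        2L * rbinom(ng, 1L, spec@causalFreq[[g]])
      col0 <- col0 + ng
    }
    phenotype <- as.integer(causal == 2L)

    chromAll <- c(chrom, spec@causalChrom)
    posAll <- c(pos, spec@causalPos)
    dosAll <- rbind(dos, causal)
    acc <- sprintf("TS-%03d", seq_len(nTot))
    colnames(dosAll) <- acc
    gt <- GenotypeData(dosAll, chrom = chromAll, pos = posAll,
                       ref = "A", alt = "G",
                       sampleData = DataFrame(accession = acc,
                                              group = groups,
                                              phenotype = phenotype),
                       chromLengths = lens)
    metadata(gt) <- list(
      causalSnp = snpIdFrom(spec@causalChrom, spec@causalPos),
      sweep = GRanges(spec@sweepChrom,
                      IRanges(spec@sweepStart, spec@sweepEnd)))
    gt
  })
}
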