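## End-to-end orchestration: simulate -> BSA -> GWAS -> diversity scan,
## with a JSON run manifest and per-stage seed streams.

#' Default end-to-end run configuration
#'
#' Packaged demo scale: a two-chromosome 20-Mb genome with SNPs every
#' 10 kb for the F2 cross (2,000 individuals, bulks of 73 at 70x) and a
#' 311-accession, 20,000-SNP panel with the domestication-gradient causal
#' frequencies; causal locus and sweep on ch05 near 6.4 Mb.
#'
#' @param outDir output directory for all stage files.
#' @param seed master seed; each stage derives its own stream from it.
#' @return Named list of configuration values accepted by [runPipeline()].
#' @export
demoConfig <- function(outDir, seed = 1) {
  list(
    outDir = outDir, seed = as.integer(seed),
    chromLengths = c(ch03 = 1e7, ch05 = 1e7),
    snpSpacing = 1e4, recombRate = 0.5,
    nF2 = 2000, causalChrom = "ch05", causalPos = 6.4e6,
    bulkSize = 73, depth = 70, seqError = 0.001,
    windowBp = 1e6, stepBp = 2e5, minDepth = 10, minSnps = 10,
    nRep = 10000,
    panelSnps = 20000, sweepStart = 6e6, sweepEnd = 6.6e6,
    sweepShrink = 0.1, nPCs = 3, mafMin = 0.05, macMin = 16,
    piWindowBp = 1e5, piStepBp = 1e4, sweepQuantile = 0.95
  )
}

#' Run the full discovery pipeline
#'
#' Executes simulate (F2 cross + panel) -> bulked-segregant mapping ->
#' mixed-model association scan -> pi-ratio sweep scan, writing every
#' stage output under `config$outDir` and a JSON manifest listing files,
#' parameters, seed and headline results. Re-running with the same
#' configuration reproduces byte-identical simulated inputs and
#' deterministic stage outputs.
#'
#' @param config list as produced by [demoConfig()] (any entry may be
#'   overridden).
#' @return The manifest, invisibly (also written to
#'   `<outDir>/manifest.json`).
#' @export
runPipeline <- function(config = demoConfig(tempfile("tipmap_run_"))) {
  cfg <- config
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  seedF2 <- deriveSeed(cfg$seed, 1)
  seedBulk <- deriveSeed(cfg$seed, 2)
  seedReads <- deriveSeed(cfg$seed, 3)
  seedBands <- deriveSeed(cfg$seed, 4)
  seedPanel <- deriveSeed(cfg$seed, 5)
  files <- character()
  addFile <- function(p) files <<- c(files, p)

  stage <- "simulate-f2"
  res <- tryCatch({
    genome <- GenomeSpec(cfg$chromLengths, recombRate = cfg$recombRate,
                         snpSpacing = cfg$snpSpacing)
    design <- CrossDesign(nF2 = cfg$nF2, causalChrom = cfg$causalChrom,
                          causalPos = cfg$causalPos,
                          bulkSize = cfg$bulkSize, depth = cfg$depth,
                          seqError = cfg$seqError)
    f2 <- simulateF2(genome, design, seed = seedF2)
    ph <- assignTipPhenotype(f2, cfg$causalChrom, cfg$causalPos)
    bulks <- formBulks(ph, cfg$bulkSize, seed = seedBulk)
    counts <- poolReadSample(f2, bulks, depth = cfg$depth,
                             seqError = cfg$seqError, seed = seedReads)
    addFile(writeBulkCounts(counts, file.path(cfg$outDir,
                                              "bulk_counts.tsv")))

    stage <- "bsa"
    idxP <- snpIndex(counts, "pointed", minDepth = cfg$minDepth)
    idxN <- snpIndex(counts, "non_pointed", minDepth = cfg$minDepth)
    delta <- deltaSnpIndex(idxP, idxN)
    dTab <- asTable(delta)
    write.table(dTab, f <- file.path(cfg$outDir, "delta_snp_index.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
    win <- windowAverage(delta, cfg$windowBp, cfg$stepBp, cfg$minSnps,
                         lengths = cfg$chromLengths)
    depthClasses <- unique(round(quantile(delta@depth,
                                          probs = seq(0.1, 0.9, 0.2),
                                          na.rm = TRUE)))
    mClasses <- unique(pmax(1L, round(quantile(
      windowNSnps(win)[!windowMasked(win)],
      probs = c(0.1, 0.5, 0.9)))))
    bands <- nullDeltaBands(cfg$bulkSize, depthClasses, mClasses,
                            nRep = cfg$nRep, seed = seedBands)
    wTab <- asTable(win)
    bl <- .bandLookup(bands, win@meanDepth, windowNSnps(win))
    wTab <- cbind(wTab, bl[, c("lower99", "lower95", "upper95", "upper99")])
    write.table(wTab, f <- file.path(cfg$outDir, "delta_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
    regions <- callQtlRegions(win, bands, level = 99)
    addFile(writeBed(regions, file.path(cfg$outDir, "qtl_regions_99.bed"),
                     extraCols = if (length(regions))
                       data.frame(peak = mcols(regions)$peakValue)
                     else NULL))

    stage <- "simulate-panel"
    spec <- PanelSpec(nSnps = cfg$panelSnps,
                      chromLengths = cfg$chromLengths,
                      causalChrom = cfg$causalChrom,
                      causalPos = cfg$causalPos,
                      sweepChrom = cfg$causalChrom,
                      sweepStart = cfg$sweepStart,
                      sweepEnd = cfg$sweepEnd,
                      sweepShrink = cfg$sweepShrink)
    panel <- simulatePanel(spec, seed = seedPanel)
    addFile(writeGenotypeVcf(panel, file.path(cfg$outDir, "panel.vcf")))
    meta <- data.frame(accession = colData(panel)$accession,
                       group = colData(panel)$group,
                       theta = NA_real_,
                       tip_code = colData(panel)$phenotype)
    addFile(writeAccessionMeta(meta, file.path(cfg$outDir,
                                               "panel_meta.tsv")))

    stage <- "gwas"
    filtered <- mafFilter(panel, cfg$mafMin, cfg$macMin)
    scan <- lmmScan(filtered, nPCs = cfg$nPCs)
    write.table(asTable(scan), f <- file.path(cfg$outDir, "gwas_scan.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
    sm <- scanSummary(scan)
    jsonlite::write_json(sm, f <- file.path(cfg$outDir,
                                            "gwas_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    addFile(f)

    stage <- "scan"
    groups <- colData(panel)$group
    piWild <- piWindow(panel, samples = which(groups == "wild"),
                       windowBp = cfg$piWindowBp, stepBp = cfg$piStepBp,
                       lengths = cfg$chromLengths)
    piCer <- piWindow(panel, samples = which(groups == "CER"),
                      windowBp = cfg$piWindowBp, stepBp = cfg$piStepBp,
                      lengths = cfg$chromLengths)
    sweep <- piRatioScan(piWild, piCer, q = cfg$sweepQuantile)
    rTab <- asTable(sweep$track)
    rTab$threshold <- sweep$threshold
    write.table(rTab, f <- file.path(cfg$outDir, "pi_ratio.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    addFile(f)
    addFile(writeBed(sweep$regions, file.path(cfg$outDir,
                                              "sweep_regions.bed")))

    list(scan = sm, regions = regions, sweep = sweep)
  }, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })

  manifest <- list(
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("outDir", "seed"))],
    files = basename(files),
    results = list(
      gwasLeadSnp = res$scan$leadSnp,
      gwasLeadP = res$scan$leadP,
      gwasLambda = res$scan$lambda,
      qtlRegions99 = if (length(res$regions))
        sprintf("%s:%d-%d", as.character(seqnames(res$regions)),
                start(res$regions), end(res$regions))
      else character(),
      sweepThreshold = res$sweep$threshold,
      sweepRegions = if (length(res$sweep$regions))
        sprintf("%s:%d-%d", as.character(seqnames(res$sweep$regions)),
                start(res$sweep$regions), end(res$sweep$regions))
      else character()
    )
  )
  jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  manifest$files <- c(manifest$files, "manifest.json")
  invisible(manifest)
}
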