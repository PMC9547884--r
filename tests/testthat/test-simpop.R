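test_that("F2 genotypes follow the Mendelian 1:2:1 ratio and balanced allele frequency", {
  genome <- tinyGenome(nSnps = 5)
  design <- CrossDesign(nF2 = 10000, causalChrom = "ch05", causalPos = 1e5,
                        bulkSize = 100)
  f2 <- simulateF2(genome, design, seed = 101)
  d <- dosage(f2)
  ## marginal genotype classes at a single SNP are 1/4 : 1/2 : 1/4
  counts <- tabulate(d[1, ] + 1L, nbins = 3)
  expect_gt(chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value, 0.01)
  ## pooled alternate-allele frequency is 1/2 at every SNP (symmetric cross)
  freq <- rowMeans(d) / 2
  expect_true(all(abs(freq - 0.5) < 3 * sqrt(0.125 / ncol(d))))
  ## identical seeds give bit-identical populations
  f2b <- simulateF2(genome, design, seed = 101)
  expect_identical(dosage(f2b), d)
})

test_that("zero recombination makes linked SNPs perfectly correlated", {
  genome <- tinyGenome(nSnps = 3, recombRate = 0)
  design <- CrossDesign(nF2 = 300, causalChrom = "ch05", causalPos = 1e5,
                        bulkSize = 10)
  d <- dosage(simulateF2(genome, design, seed = 7))
  expect_identical(d[1, ], d[2, ])
  expect_identical(d[1, ], d[3, ])
})

test_that("a causal locus off the SNP grid is rejected", {
  genome <- tinyGenome(nSnps = 5)
  design <- CrossDesign(nF2 = 100, causalChrom = "ch05", causalPos = 12345,
                        bulkSize = 10)
  expect_error(simulateF2(genome, design, seed = 1),
               "not among the genome's SNP positions")
})

test_that("recessive phenotype coding follows homozygosity for the pointed allele", {
  d <- matrix(c(2L, 1L, 0L, NA), nrow = 1)
  gt <- gtFrom(d, pos = 500)
  expect_message(
    ph <- assignTipPhenotype(gt, "ch05", 500),
    "excluded")
  expect_identical(unname(ph), c(1L, 0L, 0L, NA_integer_))
  ## dominant model scores carriers
  phD <- suppressMessages(
    assignTipPhenotype(gt, "ch05", 500, model = "dominant"))
  expect_identical(unname(phD)[1:3], c(1L, 1L, 0L))
  ## a large F2 segregates ~1/4 pointed under the recessive model
  genome <- tinyGenome(nSnps = 4)
  design <- CrossDesign(nF2 = 10000, causalChrom = "ch05", causalPos = 4e5,
                        bulkSize = 100)
  f2 <- simulateF2(genome, design, seed = 11)
  frac <- mean(assignTipPhenotype(f2, "ch05", 4e5))
  counts <- c(sum(frac * 10000), 10000 - frac * 10000)
  expect_gt(chisq.test(counts, p = c(0.25, 0.75))$p.value, 0.01)
})

test_that("bulk formation draws disjoint within-class subsets deterministically", {
  ph <- rep(c(1L, 0L), c(500, 700))
  b <- formBulks(ph, 73, seed = 5)
  expect_length(b$pointed, 73)
  expect_length(b$nonPointed, 73)
  expect_true(all(ph[b$pointed] == 1L))
  expect_true(all(ph[b$nonPointed] == 0L))
  expect_length(intersect(b$pointed, b$nonPointed), 0)
  expect_identical(formBulks(ph, 73, seed = 5), b)
  ## empty bulks are allowed, shortage is a named error
  b0 <- formBulks(ph, 0, seed = 1)
  expect_length(b0$pointed, 0)
  expect_error(formBulks(rep(0L, 10), 5, seed = 1), "pointed")
  expect_error(formBulks(c(rep(1L, 9), rep(0L, 2)), 5, seed = 1),
               "non-pointed")
})

test_that("pooled read sampling conserves depth and tracks the bulk allele frequency", {
  m <- 400
  gt0 <- gtFrom(matrix(0L, nrow = m, ncol = 10))
  bulks <- list(pointed = 1:5, nonPointed = 6:10)
  ## p = 0 with no sequencing error gives zero alt reads everywhere
  bc0 <- poolReadSample(gt0, bulks, depth = 70, seqError = 0, seed = 3)
  expect_true(all(assay(bc0, "altReads") == 0))
  ## fixed-depth model: ref + alt = depth at every SNP in both bulks
  bcF <- poolReadSample(gt0, bulks, depth = 70, seed = 4,
                        depthModel = "fixed")
  tot <- assay(bcF, "refReads") + assay(bcF, "altReads")
  expect_true(all(tot == 70L))
  ## Poisson model: both bulks share the per-SNP drawn depth
  bcP <- poolReadSample(gt0, bulks, depth = 70, seed = 5)
  totP <- assay(bcP, "refReads") + assay(bcP, "altReads")
  expect_identical(totP[, "pointed"], totP[, "non_pointed"])
  expect_true(all(totP >= 1))
  ## p = 1/2 gives mean alt fraction ~ 1/2
  gtH <- gtFrom(matrix(1L, nrow = m, ncol = 10))
  bcH <- poolReadSample(gtH, bulks, depth = 70, seqError = 0, seed = 6,
                        depthModel = "fixed")
  frac <- assay(bcH, "altReads")[, "pointed"] / 70
  expect_lt(abs(mean(frac) - 0.5), 3 * sqrt(0.25 / (70 * m)))
  ## determinism
  expect_identical(assay(poolReadSample(gt0, bulks, depth = 70, seed = 5),
                         "altReads"),
                   assay(bcP, "altReads"))
})

test_that("the simulated panel has the configured composition and sweep", {
  spec <- PanelSpec(nSnps = 3000,
                    causalFreq = c(wild = 0, CER = 0.086, BIG = 0.245))
  panel <- simulatePanel(spec, seed = 31)
  cd <- colData(panel)
  expect_identical(ncol(panel), 311L)
  expect_identical(as.vector(table(cd$group)[c("wild", "CER", "BIG")]),
                   c(55L, 105L, 151L))
  ## causal frequency 0 in a group means no pointed accessions there
  expect_identical(sum(cd$phenotype[cd$group == "wild"]), 0L)
  ## phenotype is homozygous-carrier status at the causal SNP
  causal <- metadata(panel)$causalSnp
  expect_identical(unname(cd$phenotype),
                   unname(as.integer(dosage(panel)[causal, ] == 2L)))
  ## sweep region: derived-group diversity reduced relative to outside
  big <- which(cd$group == "BIG")
  pw <- piWindow(panel, samples = big, windowBp = 2e5, stepBp = 2e5)
  tab <- asTable(pw)
  sw <- metadata(panel)$sweep
  inSweep <- tab$chrom == "ch05" &
    tab$start >= GenomicRanges::start(sw) & tab$end <= GenomicRanges::end(sw)
  ok <- !tab$masked
  expect_lt(mean(tab$value[inSweep & ok]),
            0.5 * mean(tab$value[!inSweep & ok]))
})
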