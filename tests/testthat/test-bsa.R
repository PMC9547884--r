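test_that("SNP-index is alt/(ref+alt) with depth masking", {
  bc <- countsFrom(refP = c(35L, 70L, 3L), altP = c(35L, 0L, 2L),
                   refN = c(10L, 10L, 10L), altN = c(10L, 10L, 10L))
  expect_message(idx <- snpIndex(bc, "pointed", minDepth = 10), "1 SNP")
  expect_equal(unname(trackValues(idx)), c(0.5, 0, NA))
  expect_error(snpIndex(bc, "mystery"), "unknown bulk")
})

test_that("delta is non-pointed minus pointed, with the exact -2/3 recessive value", {
  ## identical tracks give delta 0 everywhere
  bc <- countsFrom(refP = c(30L, 40L), altP = c(40L, 30L),
                   refN = c(30L, 40L), altN = c(40L, 30L))
  d0 <- deltaSnpIndex(snpIndex(bc, "pointed"), snpIndex(bc, "non_pointed"))
  expect_equal(unname(trackValues(d0)), c(0, 0))
  ## enumeration oracle at a recessive causal SNP with unbounded depth:
  ## pointed bulk is fixed (index 1); non-pointed genotypes are 0:1 dosage
  ## in ratio 1:2, so its allele frequency is (1*0 + 2*1)/(3*2) = 1/3
  pool <- c(0L, 1L, 1L)
  expect_equal(sum(pool) / (2 * length(pool)), 1 / 3)
  bcC <- countsFrom(refP = 0L, altP = 300L, refN = 200L, altN = 100L)
  dC <- deltaSnpIndex(snpIndex(bcC, "pointed"), snpIndex(bcC, "non_pointed"))
  expect_equal(unname(trackValues(dC)), -2 / 3)
  ## masked inputs stay masked; mismatched SNP sets are an error
  bcM <- countsFrom(refP = c(2L, 30L), altP = c(1L, 40L),
                    refN = c(30L, 40L), altN = c(40L, 30L))
  dM <- deltaSnpIndex(suppressMessages(snpIndex(bcM, "pointed")),
                      snpIndex(bcM, "non_pointed"))
  expect_true(is.na(trackValues(dM)[1]))
  bcX <- countsFrom(refP = c(30L, 40L), altP = c(40L, 30L),
                    refN = c(30L, 40L), altN = c(40L, 30L),
                    pos = c(1e5, 3e5))
  expect_error(
    deltaSnpIndex(snpIndex(bc, "pointed"), snpIndex(bcX, "non_pointed")),
    "ch05:2")
})

test_that("window means equal a brute-force recomputation on random tracks", {
  set.seed(77)
  for (rep in 1:5) {
    m <- 60
    pos <- sort(sample.int(9e5, m))
    val <- runif(m, -1, 1)
    val[sample(m, 10)] <- NA
    tr <- deltaTrackForTest <- new("IndexTrack",
      ranges = GRanges("ch05", IRanges(pos, width = 1)),
      value = val, depth = rep(70, m), stat = "delta")
    w <- windowAverage(tr, windowBp = 2e5, stepBp = 1e5, minSnps = 1,
                       lengths = c(ch05 = 9e5))
    tab <- asTable(w)
    for (i in seq_len(nrow(tab))) {
      expect_equal(tab$value[i],
                   bruteWindowMean(pos, val, tab$start[i], tab$end[i]))
    }
    ## window geometry: 1-step spacing between consecutive starts
    expect_true(all(diff(tab$start) == 1e5))
  }
  ## a window with fewer unmasked SNPs than minSnps is masked
  tr1 <- new("IndexTrack", ranges = GRanges("ch05", IRanges(5e4, width = 1)),
             value = 0.4, depth = 70, stat = "delta")
  w1 <- windowAverage(tr1, windowBp = 1e5, stepBp = 1e5, minSnps = 1,
                      lengths = c(ch05 = 2e5))
  expect_equal(asTable(w1)$value, c(0.4, NA))
  expect_identical(windowMasked(w1), c(FALSE, TRUE))
  w2 <- windowAverage(tr1, windowBp = 1e5, stepBp = 1e5, minSnps = 2,
                      lengths = c(ch05 = 2e5))
  expect_true(all(windowMasked(w2)))
})

test_that("null bands are symmetric, nested, and shrink with depth and bulk size", {
  b <- nullDeltaBands(73, 70, 1, nRep = 10000, seed = 404)
  tb <- bandTable(b)
  ## two-sided symmetry about zero within Monte-Carlo error
  expect_lt(abs(tb$upper95 + tb$lower95), 0.02)
  expect_lt(abs(tb$upper99 + tb$lower99), 0.02)
  ## 95% band nested inside the 99% band (validity also enforces this)
  expect_true(tb$lower95 >= tb$lower99 && tb$upper95 <= tb$upper99)
  ## independent run with another seed agrees closely (MC stability)
  tb2 <- bandTable(nullDeltaBands(73, 70, 1, nRep = 10000, seed = 405))
  expect_lt(abs(tb$upper95 - tb2$upper95), 0.02)
  ## width is non-increasing in depth and in bulk size over a grid
  width95 <- function(bulk, depth)
    with(bandTable(nullDeltaBands(bulk, depth, 1, nRep = 5000, seed = 9)),
         upper95 - lower95)
  expect_gt(width95(73, 20), width95(73, 80))
  expect_gt(width95(20, 70), width95(80, 70))
  ## more SNPs per window narrows the band
  tbM <- bandTable(nullDeltaBands(73, 70, c(1, 25), nRep = 5000, seed = 10))
  expect_gt(tbM$upper95[tbM$m == 1], tbM$upper95[tbM$m == 25])
  ## determinism and replicate floor
  expect_identical(bandTable(nullDeltaBands(73, 70, 1, nRep = 1000, seed = 2)),
                   bandTable(nullDeltaBands(73, 70, 1, nRep = 1000, seed = 2)))
  expect_error(nullDeltaBands(73, 70, 1, nRep = 500, seed = 2), "1000")
})

test_that("region calling flags windows outside the band and merges them", {
  win <- new("WindowTrack",
             ranges = GRanges("ch05", IRanges(c(1, 2e5, 4e5, 6e5),
                                              width = 3e5)),
             value = c(0.01, -0.5, -0.45, 0.0),
             nSnps = rep(20L, 4), meanDepth = rep(70, 4),
             masked = rep(FALSE, 4), stat = "delta")
  bands <- nullDeltaBands(73, 70, 20, nRep = 2000, seed = 11)
  reg <- callQtlRegions(win, bands, level = 99)
  ## the two overlapping significant windows merge into one region
  expect_length(reg, 1)
  expect_equal(start(reg), 2e5)
  expect_equal(end(reg), 7e5 - 1)
  expect_equal(mcols(reg)$peakValue, -0.5)
  ## nothing outside the band -> empty call set
  winNull <- new("WindowTrack", ranges = win@ranges,
                 value = c(0.01, -0.002, 0.003, 0),
                 nSnps = rep(20L, 4), meanDepth = rep(70, 4),
                 masked = rep(FALSE, 4), stat = "delta")
  expect_length(callQtlRegions(winNull, bands, 99), 0)
})

test_that("a simulated recessive QTL is recovered end to end at small scale", {
  genome <- GenomeSpec(c(ch05 = 5e6), snpSpacing = 2e4, recombRate = 0.25)
  design <- CrossDesign(nF2 = 600, causalChrom = "ch05", causalPos = 3e6,
                        bulkSize = 40, depth = 40)
  f2 <- simulateF2(genome, design, seed = 207)
  ph <- assignTipPhenotype(f2, "ch05", 3e6)
  bulks <- formBulks(ph, 40, seed = 208)
  bc <- poolReadSample(f2, bulks, depth = 40, seed = 209)
  dl <- deltaSnpIndex(snpIndex(bc, "pointed"), snpIndex(bc, "non_pointed"))
  w <- windowAverage(dl, windowBp = 1e6, stepBp = 2e5, minSnps = 5)
  bands <- nullDeltaBands(40, 40, c(25, 50), nRep = 2000, seed = 210)
  reg <- callQtlRegions(w, bands, level = 99)
  hit <- GRanges("ch05", IRanges(3e6, width = 1))
  expect_gt(length(reg), 0)
  expect_true(length(findOverlaps(hit, reg)) > 0)
  ## the causal-region peak is negative under the sign convention
  ov <- subjectHits(findOverlaps(hit, reg))
  expect_lt(mcols(reg)$peakValue[ov], 0)
})
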