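test_that("windowed pi matches the closed form for two differing haplotypes", {
  ## one sample heterozygous, one missing at the site: n = 2 called alleles
  ## differing at 1 site over a 100-bp window -> pi = 1/100
  d <- matrix(c(1L, NA), nrow = 1)
  gt <- gtFrom(cbind(d, NA), pos = 50)
  pw <- piWindow(gt, windowBp = 100, stepBp = 100, lengths = c(ch05 = 100))
  expect_equal(asTable(pw)$value, 0.01)
  ## a monomorphic window has pi 0
  gt0 <- gtFrom(matrix(c(2L, 2L, 2L), nrow = 1), pos = 50)
  pw0 <- piWindow(gt0, windowBp = 100, stepBp = 100, lengths = c(ch05 = 100))
  expect_equal(asTable(pw0)$value, 0)
  ## a window without called sites is masked
  pwm <- piWindow(gt0, windowBp = 100, stepBp = 100, lengths = c(ch05 = 300))
  expect_identical(windowMasked(pwm), c(FALSE, TRUE, TRUE))
})

test_that("the site formula equals brute-force pairwise differences (<= 8 alleles)", {
  set.seed(55)
  for (i in 1:200) {
    ns <- sample(2:4, 1)
    dos <- sample(c(0:2, NA), ns, replace = TRUE)
    if (sum(!is.na(dos)) < 1) next
    gt <- gtFrom(matrix(dos, nrow = 1), pos = 50)
    pw <- piWindow(gt, windowBp = 100, stepBp = 100,
                   lengths = c(ch05 = 100))
    got <- asTable(pw)$value * 100
    want <- bruteSitePi(dos)
    if (is.na(want)) expect_true(is.na(got) || windowMasked(pw)[1])
    else expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("pi-ratio flags the genome-wide top quantile and masks zero denominators", {
  mkTrack <- function(v, masked = rep(FALSE, length(v)))
    new("WindowTrack",
        ranges = GRanges("ch05", IRanges(seq(1, by = 100, length.out = length(v)),
                                         width = 100)),
        value = v, nSnps = rep(5L, length(v)),
        meanDepth = rep(NA_real_, length(v)), masked = masked,
        stat = "pi")
  ## identical diversity: exactly ceiling(5%) of windows flagged by the
  ## rank-based quantile rule
  a <- mkTrack(rep(0.01, 40)); b <- mkTrack(rep(0.01, 40))
  sc <- piRatioScan(a, b, q = 0.95)
  expect_identical(sum(sc$flagged), as.integer(ceiling(0.05 * 40)))
  expect_true(all(sc$track@value[!sc$track@masked] == 1))
  ## zero denominator -> masked and excluded from the quantile
  b2 <- mkTrack(c(0, rep(0.01, 39)))
  sc2 <- piRatioScan(a, b2, q = 0.95)
  expect_true(sc2$track@masked[1])
  expect_identical(sum(sc2$flagged), as.integer(ceiling(0.05 * 39)))
  ## flagged windows are the largest ratios, at or above the threshold
  set.seed(8)
  a3 <- mkTrack(runif(100, 0.005, 0.02))
  sc3 <- piRatioScan(a3, b <- mkTrack(rep(0.01, 100)), q = 0.95)
  expect_true(all(sc3$track@value[sc3$flagged] >= sc3$threshold))
  expect_lte(sum(sc3$flagged), ceiling(0.05 * 100))
  ## mismatched windows are an error
  expect_error(piRatioScan(a, mkTrack(rep(0.01, 39))), "identical windows")
})

test_that("per-group carrier frequencies reproduce printed one-decimal values", {
  ## enumeration oracles: unique counts rounding to 1.8% of 55, 8.6% of
  ## 105 and 24.5% of 151
  uniqueCount <- function(n, pct) {
    hits <- which(vapply(0:n, function(k)
      abs(floor(1000 * k / n + 0.5) / 10 - pct) < 1e-9, TRUE)) - 1L
    expect_length(hits, 1)
    hits
  }
  kW <- uniqueCount(55, 1.8); kC <- uniqueCount(105, 8.6)
  kB <- uniqueCount(151, 24.5)
  expect_identical(c(kW, kC, kB), c(1L, 9L, 37L))
  groups <- rep(c("wild", "CER", "BIG"), c(55, 105, 151))
  carrier <- c(rep(2L, kW), rep(0L, 55 - kW),
               rep(2L, kC), rep(0L, 105 - kC),
               rep(2L, kB), rep(0L, 151 - kB))
  gt <- gtFrom(matrix(c(carrier, rep(0L, 311)), nrow = 2, byrow = TRUE))
  f <- alleleFreqByGroup(gt, 1, groups = groups)
  expect_equal(f$freq_pct[match(c("wild", "CER", "BIG"), f$group)],
               c(1.8, 8.6, 24.5))
  ## the complementary (ref) allele in the wild group prints 98.2
  fRef <- alleleFreqByGroup(gt, 1, groups = groups, allele = "ref")
  expect_equal(fRef$freq_pct[fRef$group == "wild"], 98.2)
  ## zero carriers -> 0.0
  f0 <- alleleFreqByGroup(gt, 2, groups = groups)
  expect_true(all(f0$freq_pct == 0))
})

test_that("r2 matches hand-computed correlations and detects duplicates", {
  ## duplicated SNP column -> r2 = 1
  g1 <- c(0L, 0L, 1L, 1L, 2L, 2L)
  g2 <- c(0L, 1L, 1L, 2L, 2L, 2L)
  gt <- gtFrom(rbind(g1, g1, g2))
  r2 <- ldR2(gt, "ch05", 1, 1e6)
  expect_equal(r2[1, 2], 1)
  ## 6-sample worked pair: explicit sum-based Pearson arithmetic
  n <- 6
  sxy <- sum(g1 * g2) - sum(g1) * sum(g2) / n
  sxx <- sum(g1^2) - sum(g1)^2 / n
  syy <- sum(g2^2) - sum(g2)^2 / n
  expect_equal(r2[1, 3], (sxy / sqrt(sxx * syy))^2)
  expect_equal(r2, t(r2))
  expect_true(all(diag(r2) == 1))
  ## independent SNPs at large n: r2 near zero
  set.seed(12)
  big <- gtFrom(matrix(rbinom(2 * 2000, 2, 0.5), nrow = 2))
  r2b <- ldR2(big, "ch05", 1, 1e6)
  expect_lt(r2b[1, 2], 0.01)
  ## monomorphic SNPs are excluded with a message
  gtm <- gtFrom(rbind(g1, rep(1L, 6), g2))
  expect_message(r2m <- ldR2(gtm, "ch05", 1, 1e6), "monomorphic")
  expect_identical(nrow(r2m), 2L)
})

test_that("haploblocks follow the greedy mean-r2 rule", {
  pos <- c(100, 200, 300, 400)
  ## all pairs perfectly correlated -> a single block spanning all SNPs
  r2 <- matrix(1, 4, 4)
  hb <- haploblocks(r2, pos, r2Min = 0.7)
  expect_identical(nrow(hb$blocks), 1L)
  expect_equal(hb$blocks$nSnps, 4L)
  ## two uncorrelated halves -> two blocks
  r2c <- diag(4)
  r2c[1, 2] <- r2c[2, 1] <- 0.9
  r2c[3, 4] <- r2c[4, 3] <- 0.9
  hb2 <- haploblocks(r2c, pos, r2Min = 0.7)
  expect_identical(nrow(hb2$blocks), 2L)
  expect_equal(hb2$blocks$startPos, c(100, 300))
  ## no pair above the threshold -> no blocks (single SNPs are not blocks)
  hb3 <- haploblocks(diag(4), pos, r2Min = 0.7)
  expect_identical(nrow(hb3$blocks), 0L)
  ## the lead SNP's block is returned; a lead outside the region errors
  hbL <- haploblocks(r2c, pos, r2Min = 0.7, lead = 350)
  expect_equal(hbL$leadBlock$startPos, 300)
  expect_error(haploblocks(r2c, pos, r2Min = 0.7, lead = 9999),
               "outside the region")
})
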