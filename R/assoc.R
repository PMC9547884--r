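## Mixed-model association scan: MAF/MAC filtering, PCs, kinship, a
## single-variance-component LMM with per-SNP variance-ratio optimization,
## Bonferroni thresholds and the genomic inflation factor.

#' Filter SNPs on minor-allele frequency and carrier count
#'
#' Keeps SNPs with minor-allele frequency strictly greater than `mafMin`
#' AND at least `macMin` samples carrying the minor allele, both computed
#' over non-missing calls (the panel filter: MAF > 0.05, carriers >= 16).
#' The filter is idempotent.
#'
#' @param gt a [GenotypeData].
#' @param mafMin minor-allele frequency lower bound (strict).
#' @param macMin minimum number of samples carrying the minor allele.
#' @return The filtered [GenotypeData]; the number of removed SNPs is
#'   reported with a message.
#' @export
mafFilter <- function(gt, mafMin = 0.05, macMin = 16) {
  d <- dosage(gt)
  called <- rowSums(!is.na(d))
  altFreq <- rowSums(d, na.rm = TRUE) / pmax(2 * called, 1)
  maf <- pmin(altFreq, 1 - altFreq)
  minorIsAlt <- altFreq <= 0.5
  carriers <- ifelse(minorIsAlt,
                     rowSums(d >= 1L, na.rm = TRUE),
                     rowSums(d <= 1L, na.rm = TRUE))
  keep <- called > 0 & maf > mafMin & carriers >= macMin
  message(sum(!keep), " SNP(s) removed by the MAF/MAC filter, ",
          sum(keep), " kept")
  gt[keep, ]
}

## mean-imputed, optionally standardized sample-by-SNP matrix
.imputedMatrix <- function(gt, standardize = FALSE) {
  X <- t(dosage(gt))          # samples x SNPs
  p <- colMeans(X, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  Z <- sweep(X, 2, 2 * p)
  Z[is.na(Z)] <- 0
  if (standardize)
    Z <- sweep(Z, 2, sqrt(2 * p * (1 - p)), "/")
  Z
}

#' Principal components of the genotype matrix
#'
#' SNP dosages are centred by twice the allele frequency and scaled by
#' `sqrt(2p(1-p))`; missing dosages are mean-imputed and all-missing or
#' monomorphic SNPs excluded. PCs are eigenvectors of the sample covariance
#' scaled by the square root of their eigenvalues.
#'
#' @param gt a [GenotypeData].
#' @param nComponents number of components (default 3, the covariate set
#'   used for the panel scan).
#' @return Numeric matrix (samples x `nComponents`) of PC coordinates.
#' @export
computePCs <- function(gt, nComponents = 3) {
  Z <- .imputedMatrix(gt, standardize = TRUE)
  stopIfNot(nrow(Z) >= nComponents + 1, "too few samples for ", nComponents,
            " components")
  stopIfNot(ncol(Z) >= 1, "no polymorphic SNPs")
  K <- tcrossprod(Z) / ncol(Z)
  e <- eigen(K, symmetric = TRUE)
  k <- seq_len(nComponents)
  scores <- e$vectors[, k, drop = FALSE] %*%
    diag(sqrt(pmax(e$values[k], 0)), nComponents)
  dimnames(scores) <- list(colnames(gt), paste0("PC", k))
  scores
}

#' Centred kinship (relatedness) matrix
#'
#' K = Z Z' / m with Z the column-centred dosage matrix over m SNPs and
#' missing dosages mean-imputed; symmetric with non-negative diagonal.
#'
#' @param gt a [GenotypeData] (normally after [mafFilter()]).
#' @return A square symmetric matrix over samples.
#' @export
kinshipMatrix <- function(gt) {
  Z <- .imputedMatrix(gt, standardize = FALSE)
  stopIfNot(ncol(Z) >= 1, "no usable SNPs for kinship")
  K <- tcrossprod(Z) / ncol(Z)
  dimnames(K) <- list(colnames(gt), colnames(gt))
  K
}

#' Bonferroni-style genome-wide thresholds
#'
#' Suggestive threshold 1/n and significance threshold 0.05/n for n tested
#' SNPs (for the panel's 4,155,820 SNPs: about 2.41e-7 and 1.20e-8).
#'
#' @param nSnps number of SNPs tested (>= 1).
#' @return Named numeric vector `c(suggestive =, significant =)`.
#' @examples
#' bonferroniThresholds(4155820)
#' @export
bonferroniThresholds <- function(nSnps) {
  stopIfNot(nSnps >= 1, "nSnps must be at least 1")
  c(suggestive = 1 / nSnps, significant = 0.05 / nSnps)
}

#' Genomic inflation factor lambda
#'
#' Median of the chi-square(1 df) quantile-transformed p-values divided by
#' the null median 0.4549; approximately 1 for a well-calibrated scan.
#'
#' @param p p-values in (0, 1].
#' @return lambda (scalar).
#' @export
lambdaGC <- function(p) {
  p <- p[!is.na(p)]
  stopIfNot(length(p) > 0, "no p-values")
  if (any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  median(qchisq(p, df = 1, lower.tail = FALSE)) /
    qchisq(0.5, df = 1, lower.tail = FALSE)
}

## profile ML log-likelihood pieces for one variance ratio delta, vectorized
## over SNPs: returns the weighted regression summaries of y and every g on
## the fixed covariates under weights 1/(eigenvalue + delta)
.profileGrid <- function(delta, d, yt, X0t, Gt, Gt2 = Gt^2) {
  w <- 1 / (d + delta)
  X0w <- X0t * w
  A <- crossprod(X0w, X0t)
  Ai <- solve(A)
  b0y <- crossprod(X0w, yt)              # c x 1
  Syy <- sum(w * yt^2) - drop(crossprod(b0y, Ai %*% b0y))
  B <- crossprod(X0w, Gt)                # c x m
  AiB <- Ai %*% B
  Sgg <- drop(crossprod(Gt2, w)) - colSums(B * AiB)
  Sgy <- drop(crossprod(Gt, w * yt)) -
    drop(crossprod(B, Ai %*% b0y))
  rss <- Syy - ifelse(Sgg > 1e-12, Sgy^2 / Sgg, 0)
  n <- length(yt)
  ll <- -0.5 * (n * log(2 * pi * pmax(rss, 1e-300) / n) + n +
                  sum(log(d + delta)))
  list(ll = ll, rss = rss, Sgg = Sgg, Sgy = Sgy)
}

## scalar version for one SNP (used in the golden-section refinement)
.profileOne <- function(delta, d, yt, X0t, g) {
  r <- .profileGrid(delta, d, yt, X0t, matrix(g, ncol = 1))
  r$ll[1]
}

#' Linear mixed-model association scan
#'
#' Per-SNP single-variance-component LMM: y = Xb + g beta + u + e with
#' u ~ N(0, sg^2 K), e ~ N(0, se^2 I). K is eigendecomposed once; for each
#' SNP the likelihood (ML) is maximized over the variance ratio
#' delta = se^2/sg^2 on a 100-point log-spaced grid over \[1e-5, 1e5\] with
#' golden-section refinement inside the winning bracket. The binary
#' phenotype is fitted as quantitative (0/1 coding), matching how such scans
#' are run with Gaussian mixed-model software. Wald tests use
#' sigma^2 = RSS/(n - p) and a t reference with n - p df, so with
#' K = identity the scan reduces exactly to OLS.
#'
#' @param gt a filtered [GenotypeData].
#' @param phenotype numeric vector over samples (0/1 for the tip trait);
#'   defaults to `colData(gt)$phenotype`.
#' @param nPCs number of PC covariates (computed from `gt`); ignored when
#'   `covariates` is given.
#' @param covariates optional samples-x-q covariate matrix (no intercept
#'   column; one is added).
#' @param K kinship matrix; defaults to [kinshipMatrix()] of `gt`.
#' @param refine logical; run the golden-section refinement (default TRUE).
#' @return An [AssocScan]; SNPs with a degenerate (near-constant) rotated
#'   genotype are skipped with a message and get `NA` results. Scan-level
#'   thresholds come from [bonferroniThresholds()] and lambda from
#'   [lambdaGC()].
#' @export
lmmScan <- function(gt, phenotype = NULL, nPCs = 3, covariates = NULL,
                    K = NULL, refine = TRUE) {
  if (is.null(phenotype)) phenotype <- colData(gt)$phenotype
  stopIfNot(!is.null(phenotype) && length(phenotype) == ncol(gt),
            "phenotype must match the samples")
  y <- as.numeric(phenotype)
  if (is.null(covariates) && nPCs > 0) covariates <- computePCs(gt, nPCs)
  if (is.null(K)) K <- kinshipMatrix(gt)
  stopIfNot(nrow(K) == ncol(gt) && ncol(K) == ncol(gt),
            "K must be square over the samples")

  n <- ncol(gt)
  G <- t(dosage(gt))                      # samples x SNPs
  G <- sweep(G, 2, colMeans(G, na.rm = TRUE))  # centre by observed mean
  G[is.na(G)] <- 0                        # = impute missing to the SNP mean
  X0 <- cbind(Intercept = rep(1, n), covariates)
  pX <- ncol(X0) + 1L

  e <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(e$values, 1e-8)
  U <- e$vectors
  yt <- drop(crossprod(U, y))
  X0t <- crossprod(U, X0)
  Gt <- crossprod(U, G)

  deltas <- 10^seq(-5, 5, length.out = 100)
  m <- ncol(Gt)
  Gt2 <- Gt^2
  bestLL <- rep(-Inf, m)
  bestIdx <- rep(1L, m)
  for (i in seq_along(deltas)) {
    ll <- .profileGrid(deltas[i], d, yt, X0t, Gt, Gt2)$ll
    better <- ll > bestLL
    bestLL[better] <- ll[better]
    bestIdx[better] <- i
  }

  bestDelta <- deltas[bestIdx]
  if (refine) {
    gr <- (sqrt(5) - 1) / 2
    logd <- log10(deltas)
    for (j in seq_len(m)) {
      lo <- logd[max(bestIdx[j] - 1L, 1L)]
      hi <- logd[min(bestIdx[j] + 1L, length(deltas))]
      if (hi - lo < 1e-8) next
      a <- lo; b <- hi
      x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
      f1 <- .profileOne(10^x1, d, yt, X0t, Gt[, j])
      f2 <- .profileOne(10^x2, d, yt, X0t, Gt[, j])
      for (it in 1:20) {
        if (f1 < f2) {
          a <- x1; x1 <- x2; f1 <- f2
          x2 <- a + gr * (b - a)
          f2 <- .profileOne(10^x2, d, yt, X0t, Gt[, j])
        } else {
          b <- x2; x2 <- x1; f2 <- f1
          x1 <- b - gr * (b - a)
          f1 <- .profileOne(10^x1, d, yt, X0t, Gt[, j])
        }
        if (b - a < 1e-4) break
      }
      bestDelta[j] <- 10^((a + b) / 2)
    }
  }

  ## final Wald statistics at the per-SNP optimum
  beta <- se <- pval <- rep(NA_real_, m)
  byDelta <- split(seq_len(m), bestDelta)
  for (grp in byDelta) {
    r <- .profileGrid(bestDelta[grp[1]], d, yt, X0t,
                      Gt[, grp, drop = FALSE])
    ok <- r$Sgg > 1e-8
    bet <- ifelse(ok, r$Sgy / r$Sgg, NA_real_)
    sig2 <- pmax(r$rss, 0) / (n - pX)
    s <- ifelse(ok, sqrt(sig2 / r$Sgg), NA_real_)
    beta[grp] <- bet
    se[grp] <- s
    pval[grp] <- ifelse(ok, 2 * pt(abs(bet / s), df = n - pX,
                                   lower.tail = FALSE), NA_real_)
  }
  skipped <- sum(is.na(pval))
  if (skipped)
    message(skipped, " SNP(s) skipped (degenerate genotype after rotation)")
  pval[!is.na(pval)] <- pmax(pval[!is.na(pval)], .Machine$double.xmin)

  thr <- bonferroniThresholds(sum(!is.na(pval)))
  new("AssocScan", ranges = rowRanges(gt), beta = beta, se = se, p = pval,
      delta = bestDelta, suggestive = unname(thr["suggestive"]),
      significant = unname(thr["significant"]),
      lambda = lambdaGC(pval))
}
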