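#' @include AllClasses.R uvmr.R
NULL

## leave-one-out IVW slopes for all SNPs at once, given weights w = 1/sy^2
.looSlopes <- function(bx, by, w) {
  sxy <- sum(w * bx * by)
  sxx <- sum(w * bx^2)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed residual sum of squares from leave-one-out
#' IVW predictions (residuals standardised by the outcome SE) is compared
#' against its null distribution obtained from \code{nSim} parametric
#' simulations under the fitted model (both exposure and outcome betas
#' resampled from their sampling distributions). Per-SNP outlier p-values
#' compare each observed squared residual with its simulated distribution
#' and are Bonferroni-corrected by k; SNPs below \code{alpha} after
#' correction are flagged. The distortion test compares the IVW estimate
#' before and after removing the flagged outliers against the distortion
#' obtained by removing random subsets of the same size.
#'
#' @param set A [HarmonizedSet-class] with at least 4 SNPs.
#' @param nSim Number of simulated datasets (default 5000; at least 1000
#'   recommended).
#' @param seed Mandatory RNG seed; identical seeds give bit-identical
#'   results.
#' @param alpha Level for outlier flagging after correction (default
#'   0.05).
#' @return A [PressoResult-class].
#' @export
mrPresso <- function(set, nSim = 5000, seed, alpha = 0.05) {
  seed <- .checkSeed(seed)
  d <- .setVectors(set, 4L, "MR-PRESSO")
  k <- nrow(d)
  bx <- d$beta_exp; sx <- d$se_exp
  by <- d$beta_out; sy <- d$se_out
  w <- 1 / sy^2

  bLoo <- .looSlopes(bx, by, w)
  rObs <- (by - bLoo * bx) / sy
  rssObs <- sum(rObs^2)

  sims <- .withSeed(seed, {
    BX <- matrix(stats::rnorm(k * nSim, bx, sx), k, nSim)
    BY <- matrix(stats::rnorm(k * nSim, bLoo * bx, sy), k, nSim)
    SXY <- colSums(w * BX * BY)
    SXX <- colSums(w * BX^2)
    BL <- (rep(SXY, each = k) - w * BX * BY) /
          (rep(SXX, each = k) - w * BX^2)
    R2 <- ((BY - BL * BX) / sy)^2
    list(rss = colSums(R2), r2 = R2,
         subsets = if (k >= 2)
           replicate(min(nSim, 1000L), sample.int(k, 1L)) else NULL)
  })

  globalPval <- (1 + sum(sims$rss >= rssObs)) / (nSim + 1)
  perSnpRaw <- (1 + rowSums(sims$r2 >= rObs^2)) / (nSim + 1)
  perSnp <- pmin(1, perSnpRaw * k)
  names(perSnp) <- d$snp
  outliers <- d$snp[perSnp < alpha]

  before <- mrIVW(set)
  after <- NULL
  distortionPval <- NA_real_
  if (length(outliers) && length(outliers) < k - 1) {
    subSet <- set
    keep <- !(d$snp %in% outliers)
    subSet@data <- d[keep, , drop = FALSE]
    subSet@audit <- subSet@audit[subSet@audit$snp %in% d$snp[keep], ,
                                 drop = FALSE]
    after <- mrIVW(subSet)
    dObs <- (after@beta - before@beta) / abs(after@beta)
    nOut <- length(outliers)
    dSim <- .withSeed(seed + 1L, {
      vapply(seq_len(min(nSim, 1000L)), function(i) {
        drop <- sample.int(k, nOut)
        ww <- w[-drop]
        bb <- sum(ww * bx[-drop] * by[-drop]) / sum(ww * bx[-drop]^2)
        (bb - before@beta) / abs(bb)
      }, numeric(1))
    })
    distortionPval <- (1 + sum(abs(dSim) >= abs(dObs))) /
      (length(dSim) + 1)
  }

  methods::new("PressoResult",
    globalRss = rssObs, globalPval = globalPval,
    outlierPvals = perSnp, outlierIds = outliers,
    distortionPval = distortionPval, estimateBefore = before,
    estimateAfter = after, nSim = as.integer(nSim), seed = seed)
}
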