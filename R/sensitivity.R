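#' @include AllClasses.R uvmr.R
NULL

#' Cochran's Q heterogeneity test
#'
#' \eqn{Q = \sum_j w_j (\hat\beta_j - fit_j)^2} over the per-SNP Wald
#' ratios with first-order weights \eqn{w_j = \beta_{exp,j}^2/se_{out,j}^2}
#' and fitted values from the chosen reference model (IVW: a common slope,
#' df = k-1; Egger: slope plus intercept, df = k-2). Excess Q indicates
#' heterogeneity among instruments, a symptom of invalid instruments.
#'
#' @param set A [HarmonizedSet-class].
#' @param reference "ivw" (default) or "egger".
#' @return A [QResult-class] with the per-SNP contributions.
#' @export
cochranQ <- function(set, reference = c("ivw", "egger")) {
  reference <- match.arg(reference)
  d <- .setVectors(set, if (reference == "ivw") 2L else 3L, "Cochran's Q")
  k <- nrow(d)
  w <- 1 / d$se_out^2
  if (reference == "ivw") {
    beta <- mrIVW(set, effects = "fixed")@beta
    fitted <- beta * d$beta_exp
    df <- k - 1
  } else {
    e <- mrEgger(set)
    flip <- sign(d$beta_exp)
    flip[flip == 0] <- 1
    fitted <- flip * (e$intercept@estimate +
                        e$estimate@beta * abs(d$beta_exp))
    df <- k - 2
  }
  contrib <- w * (d$beta_out - fitted)^2
  names(contrib) <- d$snp
  Q <- sum(contrib)
  methods::new("QResult", qStat = Q, df = as.numeric(df),
               pval = stats::pchisq(Q, df, lower.tail = FALSE),
               contributions = contrib, reference = reference)
}

#' Leave-one-out influence analysis
#'
#' Refits IVW k times, omitting each SNP in turn. A left-out run is
#' flagged when the full-set estimate is significant (its 95 percent CI
#' excludes 0) but the left-out CI no longer supports an effect of the
#' same sign (it includes 0 or lies on the opposite side) -- i.e. the
#' conclusion hinges on that single SNP.
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param effects IVW variant passed to [mrIVW()].
#' @return A [LooTable-class].
#' @export
leaveOneOut <- function(set, effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  d <- .setVectors(set, 3L, "leave-one-out")
  full <- mrIVW(set, effects = effects)
  fullSig <- full@ciLow > 0 || full@ciHigh < 0
  sgn <- sign(full@beta)
  rows <- lapply(seq_len(nrow(d)), function(j) {
    sub <- set
    sub@data <- d[-j, , drop = FALSE]
    sub@audit <- sub@audit[sub@audit$snp %in% sub@data$snp, , drop = FALSE]
    est <- mrIVW(sub, effects = effects)
    supportsSign <- if (sgn > 0) est@ciLow > 0 else est@ciHigh < 0
    data.frame(snp = d$snp[j], beta = est@beta, se = est@se,
               ciLow = est@ciLow, ciHigh = est@ciHigh, pval = est@pval,
               flag = fullSig && !supportsSign, stringsAsFactors = FALSE)
  })
  methods::new("LooTable", estimates = do.call(rbind, rows),
               fullEstimate = full)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure against
#' the variance they explain in the outcome, both via the binary-trait
#' approximation \eqn{\sum_j 2 p_j (1-p_j) \beta_j^2} (see [perSnpR2()]).
#' The implied correlations from the two independent samples are Fisher
#' z-transformed and compared with
#' \eqn{z = (z_{exp} - z_{out}) / \sqrt{1/(n_{exp}-3) + 1/(n_{out}-3)}}.
#' The exposure-to-outcome orientation is supported when the exposure side
#' explains significantly more variance.
#'
#' @param set A [HarmonizedSet-class] whose \code{eaf_exp} is complete.
#' @param nExp,nOut Sample sizes of the exposure and outcome GWAS.
#' @param alpha Significance level for the verdict (default 0.05).
#' @return A [SteigerResult-class].
#' @export
steigerTest <- function(set, nExp, nOut, alpha = 0.05) {
  d <- .setVectors(set, 1L, "Steiger test")
  if (anyNA(d$eaf_exp))
    .stopf("missing eaf: Steiger r2 undefined")
  r2e <- sum(perSnpR2(d$eaf_exp, d$beta_exp))
  r2o <- sum(perSnpR2(d$eaf_exp, d$beta_out))
  re <- sqrt(min(r2e, 1 - 1e-12))
  ro <- sqrt(min(r2o, 1 - 1e-12))
  z <- (atanh(re) - atanh(ro)) / sqrt(1 / (nExp - 3) + 1 / (nOut - 3))
  p <- 2 * stats::pnorm(-abs(z))
  methods::new("SteigerResult", r2Exposure = r2e, r2Outcome = r2o,
               zStat = z, pval = p,
               directionOk = (r2e > r2o) && (p < alpha), alpha = alpha)
}

#' Power for a binary-outcome MR analysis
#'
#' Closed-form non-centrality approximation in the style of the standard
#' online calculator for case-control outcomes:
#' \deqn{NCP = n\, r^2\, K (1-K)\, \beta^2}
#' with n the outcome sample size, \eqn{r^2} the variance the instruments
#' explain in the exposure, K the outcome case fraction and \eqn{\beta}
#' the causal log-odds ratio per unit exposure; two-sided power at level
#' \eqn{\alpha} is
#' \eqn{\Phi(\sqrt{NCP} - z_{1-\alpha/2}) + \Phi(-\sqrt{NCP} - z_{1-\alpha/2})},
#' which reduces to \eqn{\alpha} exactly at \eqn{\beta = 0}.
#'
#' @param nTotal Outcome GWAS sample size.
#' @param caseFraction Outcome case fraction in (0, 1).
#' @param r2Instrument Instrument variance explained in the exposure.
#' @param betaCausal Causal effect (log-OR per unit exposure log-odds).
#' @param alpha Two-sided significance level (default 0.05).
#' @return Power in \[0, 1\], with the formula recorded in attribute
#'   \code{"method"}.
#' @export
powerBinary <- function(nTotal, caseFraction, r2Instrument, betaCausal,
                        alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) .stopf("alpha must lie in (0, 1)")
  if (caseFraction <= 0 || caseFraction >= 1)
    .stopf("caseFraction must lie in (0, 1)")
  if (r2Instrument < 0 || r2Instrument > 1)
    .stopf("r2Instrument must lie in [0, 1]")
  ncp <- nTotal * r2Instrument * caseFraction * (1 - caseFraction) *
    betaCausal^2
  z <- stats::qnorm(1 - alpha / 2)
  pow <- stats::pnorm(sqrt(ncp) - z) + stats::pnorm(-sqrt(ncp) - z)
  attr(pow, "method") <- "NCP = n * r2 * K(1-K) * beta^2, two-sided normal"
  pow
}

#' Consolidated sensitivity report for one exposure-outcome pair
#'
#' Runs the full diagnostic battery and returns the pieces in one list:
#' Cochran's Q under both references, the Egger intercept test, MR-PRESSO,
#' radial MR, leave-one-out, and (when frequencies and sample sizes are
#' available) the Steiger verdict and power.
#'
#' @param set A [HarmonizedSet-class].
#' @param nSim MR-PRESSO simulated datasets (default 5000).
#' @param seed RNG seed for MR-PRESSO.
#' @param alpha Outlier/test level (default 0.05).
#' @param nExp,nOut Sample sizes for the Steiger test (optional).
#' @param betaCausal Causal estimate used for the power calculation
#'   (defaults to the IVW estimate).
#' @param caseFractionOut Outcome case fraction for power (optional).
#' @return Named list of diagnostic results.
#' @export
sensitivityBattery <- function(set, nSim = 5000, seed, alpha = 0.05,
                               nExp = NULL, nOut = NULL,
                               betaCausal = NULL, caseFractionOut = NULL) {
  out <- list(
    q_ivw = cochranQ(set, "ivw"),
    q_egger = if (nSnps(set) >= 3) cochranQ(set, "egger") else NULL,
    egger_intercept = if (nSnps(set) >= 3) mrEgger(set)$intercept else NULL,
    presso = if (nSnps(set) >= 4)
      mrPresso(set, nSim = nSim, seed = seed, alpha = alpha) else NULL,
    radial = radialMR(set, alpha = alpha),
    loo = if (nSnps(set) >= 3) leaveOneOut(set) else NULL)
  if (!is.null(nExp) && !is.null(nOut) && !anyNA(set@data$eaf_exp)) {
    out$steiger <- steigerTest(set, nExp = nExp, nOut = nOut, alpha = alpha)
    if (!is.null(caseFractionOut)) {
      b <- if (is.null(betaCausal)) mrIVW(set)@beta else betaCausal
      out$power <- powerBinary(nOut, caseFractionOut,
                               out$steiger@r2Exposure, b, alpha = alpha)
    }
  }
  out
}
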