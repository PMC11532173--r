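#' @include AllClasses.R harmonize.R
NULL

.setVectors <- function(set, min_k, caller) {
  d <- set@data
  if (nrow(d) < min_k)
    .stopf("%s requires at least %d instruments (have %d)",
           caller, min_k, nrow(d))
  d
}

#' Single-SNP Wald ratio
#'
#' Per-variant causal estimate: the SNP-outcome effect divided by the
#' SNP-exposure effect, with first-order delta-method standard error
#' \eqn{se_{out}/|\beta_{exp}|}.
#'
#' @param beta_exp,se_exp SNP-exposure effect and SE.
#' @param beta_out,se_out SNP-outcome effect and SE.
#' @return An [MREstimate-class] with method "WaldRatio".
#' @examples
#' waldRatio(0.1, 0.01, 0.02, 0.005)   # beta 0.2, se 0.05
#' @export
waldRatio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (any(beta_exp == 0)) .stopf("undefined ratio: beta_exp = 0")
  .newEstimate("WaldRatio", beta_out / beta_exp, se_out / abs(beta_exp),
               nsnp = 1L)
}

## first-order ratio weights used by IVW/median/Q: 1/se(ratio)^2
.ratioWeights <- function(d) d$beta_exp^2 / d$se_out^2

#' Inverse-variance weighted estimator
#'
#' Weighted regression of outcome effects on exposure effects through the
#' origin with weights \eqn{1/se_{out}^2}; algebraically the
#' inverse-variance weighted mean of the per-SNP Wald ratios. The default
#' multiplicative random-effects model inflates the fixed-effect SE by
#' \eqn{\sqrt{\max(1, Q/(k-1))}} so that excess heterogeneity widens the
#' interval but the SE is never deflated below the fixed-effect value.
#'
#' @param set A [HarmonizedSet-class] with at least 2 SNPs.
#' @param effects "multiplicative_random" (default) or "fixed".
#' @return An [MREstimate-class]; \code{extras} carries Q, its df and the
#'   SE inflation factor applied.
#' @export
mrIVW <- function(set, effects = c("multiplicative_random", "fixed")) {
  effects <- match.arg(effects)
  d <- .setVectors(set, 2L, "IVW")
  w <- 1 / d$se_out^2
  sxx <- sum(w * d$beta_exp^2)
  beta <- sum(w * d$beta_exp * d$beta_out) / sxx
  seFixed <- sqrt(1 / sxx)
  k <- nrow(d)
  Q <- sum(w * (d$beta_out - beta * d$beta_exp)^2)
  infl <- if (effects == "multiplicative_random")
    sqrt(max(1, Q / (k - 1))) else 1
  .newEstimate("IVW", beta, seFixed * infl, k,
               extras = list(effects = effects, Q = Q, Q_df = k - 1,
                             inflation = infl))
}

#' MR-Egger regression
#'
#' Weighted regression of outcome on exposure effects with a free
#' intercept (weights \eqn{1/se_{out}^2}). The slope is the causal
#' estimate; the intercept estimates the average directional pleiotropic
#' effect and its test (p > 0.05 read as no evidence of directional
#' pleiotropy) is returned alongside. Rows are first oriented so that all
#' exposure effects are non-negative, the convention under which the
#' intercept is identified.
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param reference "normal" (default) or "t" (k-2 df) reference for CIs
#'   and p-values.
#' @param dispersion "floor": SEs scaled by
#'   \eqn{\max(1, \hat\sigma)} where \eqn{\hat\sigma^2} is the weighted
#'   residual mean square (default, never deflates); "plain": scaled by
#'   \eqn{\hat\sigma} as in ordinary weighted least squares.
#' @return List with elements \code{estimate} ([MREstimate-class], method
#'   "MR-Egger") and \code{intercept} ([EggerInterceptTest-class]).
#' @export
mrEgger <- function(set, reference = c("normal", "t"),
                    dispersion = c("floor", "plain")) {
  reference <- match.arg(reference)
  dispersion <- match.arg(dispersion)
  d <- .setVectors(set, 3L, "MR-Egger")
  flip <- sign(d$beta_exp)
  flip[flip == 0] <- 1
  bx <- d$beta_exp * flip
  by <- d$beta_out * flip
  w <- 1 / d$se_out^2
  fit <- .wlsFit(cbind(intercept = 1, slope = bx), by, w)
  k <- nrow(d)
  sigma2 <- fit$rss / (k - 2)
  fac <- switch(dispersion, floor = max(1, sqrt(sigma2)),
                plain = sqrt(sigma2))
  se <- fit$seUnit * fac
  est <- .newEstimate("MR-Egger", fit$coef[["slope"]], se[["slope"]], k,
                      extras = list(dispersion = dispersion,
                                    Q = fit$rss, Q_df = k - 2),
                      reference = reference, df = k - 2)
  pInt <- if (reference == "t")
    2 * stats::pt(-abs(fit$coef[["intercept"]] / se[["intercept"]]), k - 2)
  else
    2 * stats::pnorm(-abs(fit$coef[["intercept"]] / se[["intercept"]]))
  list(estimate = est,
       intercept = methods::new("EggerInterceptTest",
                                estimate = fit$coef[["intercept"]],
                                se = se[["intercept"]], pval = pInt))
}

## weighted least squares by normal equations; seUnit assumes unit
## residual variance (known-variance weights)
.wlsFit <- function(X, y, w) {
  XtW <- t(X * w)
  XtWX <- XtW %*% X
  qrx <- qr(XtWX)
  if (qrx$rank < ncol(X)) {
    cn <- colnames(X)
    .stopf("rank-deficient design: collinear columns among %s",
           paste(cn, collapse = ", "))
  }
  covUnit <- solve(XtWX)
  coef <- drop(covUnit %*% (XtW %*% y))
  names(coef) <- colnames(X)
  res <- y - drop(X %*% coef)
  seUnit <- sqrt(diag(covUnit))
  names(seUnit) <- colnames(X)
  list(coef = coef, covUnit = covUnit, seUnit = seUnit,
       rss = sum(w * res^2), residuals = res)
}

## weighted median of x at cumulative weight 0.5 (linear interpolation)
.weightedMedian <- function(x, w) {
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  if (cw[1] >= 0.5) return(x[1])
  if (cw[length(cw)] <= 0.5) return(x[length(x)])
  stats::approx(cw, x, xout = 0.5, ties = "ordered")$y
}

## parametric bootstrap SE for ratio-based estimators
.bootSE <- function(d, statistic, nBoot, seed) {
  k <- nrow(d)
  .withSeed(seed, {
    reps <- vapply(seq_len(nBoot), function(i) {
      bx <- stats::rnorm(k, d$beta_exp, d$se_exp)
      by <- stats::rnorm(k, d$beta_out, d$se_out)
      statistic(bx, by)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted median estimator
#'
#' Weighted median of the per-SNP Wald ratios with inverse-variance
#' weights \eqn{\beta_{exp}^2/se_{out}^2}, interpolated at cumulative
#' weight 0.5. Consistent when at least half of the total instrument
#' weight comes from valid instruments. The SE is a parametric bootstrap:
#' per-SNP betas are resampled from their sampling distributions and the
#' weighted median recomputed.
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param nBoot Bootstrap replicates (default 1000; a warning is issued
#'   below 100).
#' @param seed Mandatory RNG seed for the bootstrap.
#' @return An [MREstimate-class] with method "WeightedMedian".
#' @export
mrWeightedMedian <- function(set, nBoot = 1000, seed) {
  seed <- .checkSeed(seed)
  if (nBoot < 100) .warnf("nBoot < 100: bootstrap SE will be unstable")
  d <- .setVectors(set, 3L, "weighted median")
  w <- .ratioWeights(d)
  beta <- .weightedMedian(d$beta_out / d$beta_exp, w)
  se <- .bootSE(d, function(bx, by) .weightedMedian(by / bx, bx^2 / d$se_out^2),
                nBoot, seed)
  .newEstimate("WeightedMedian", beta, se, nrow(d),
               extras = list(n_boot = nBoot, seed = seed))
}

## kernel-density argmax of ratios with weights
.modeArgmax <- function(r, w, phi) {
  if (length(unique(r)) == 1L) return(r[1])
  s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  if (s <= 0) s <- 0.9 * stats::sd(r) * length(r)^(-1 / 5)
  h <- phi * s
  dens <- stats::density(r, weights = w / sum(w), bw = h, n = 1024)
  dens$x[which.max(dens$y)]
}

#' Mode-based estimators (simple and weighted mode)
#'
#' The causal estimate is the argmax of a normal-kernel density of the
#' per-SNP Wald ratios: unweighted for the simple mode, inverse-variance
#' weighted for the weighted mode. The bandwidth is \code{phi} times the
#' modified Silverman rule \eqn{0.9\,\min(sd, mad)\,k^{-1/5}} of the
#' ratios. SE by parametric bootstrap as in [mrWeightedMedian()].
#'
#' @param set A [HarmonizedSet-class] with at least 3 SNPs.
#' @param weighted Use inverse-variance weights (weighted mode) or not
#'   (simple mode).
#' @param phi Bandwidth multiplier (> 0, default 1).
#' @param nBoot,seed Bootstrap settings as in [mrWeightedMedian()].
#' @return An [MREstimate-class], method "SimpleMode" or "WeightedMode".
#' @export
mrMode <- function(set, weighted = FALSE, phi = 1, nBoot = 1000, seed) {
  if (!is.numeric(phi) || phi <= 0) .stopf("phi must be > 0")
  seed <- .checkSeed(seed)
  d <- .setVectors(set, 3L, "mode estimator")
  r <- d$beta_out / d$beta_exp
  w <- if (weighted) .ratioWeights(d) else rep(1, nrow(d))
  beta <- .modeArgmax(r, w, phi)
  se <- .bootSE(d, function(bx, by) {
    wb <- if (weighted) bx^2 / d$se_out^2 else w
    .modeArgmax(by / bx, wb, phi)
  }, nBoot, seed)
  .newEstimate(if (weighted) "WeightedMode" else "SimpleMode",
               beta, se, nrow(d),
               extras = list(phi = phi, n_boot = nBoot, seed = seed))
}

#' Tidy table of UVMR estimates for one exposure-outcome pair
#'
#' Runs the requested estimators and stacks their one-row summaries into
#' the standard reporting layout (exposure, outcome, method, nsnp, OR,
#' 95 percent CI, p-value).
#'
#' @param set A [HarmonizedSet-class].
#' @param estimators Subset of c("IVW", "MR-Egger", "WeightedMedian",
#'   "SimpleMode", "WeightedMode").
#' @param nBoot,seed Bootstrap settings for median/mode estimators.
#' @return data.frame, one row per estimator.
#' @export
mrEstimateTable <- function(set,
                            estimators = c("IVW", "MR-Egger",
                                           "WeightedMedian"),
                            nBoot = 1000, seed = 1L) {
  rows <- lapply(estimators, function(m) {
    est <- switch(m,
      "IVW" = mrIVW(set),
      "MR-Egger" = mrEgger(set)$estimate,
      "WeightedMedian" = mrWeightedMedian(set, nBoot = nBoot, seed = seed),
      "SimpleMode" = mrMode(set, weighted = FALSE, nBoot = nBoot,
                            seed = seed),
      "WeightedMode" = mrMode(set, weighted = TRUE, nBoot = nBoot,
                              seed = seed),
      .stopf("unknown estimator '%s'", m))
    as.data.frame(est)
  })
  cbind(exposure = set@exposureLabel, outcome = set@outcomeLabel,
        do.call(rbind, rows), stringsAsFactors = FALSE)
}
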