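#' @include AllClasses.R uvmr.R
NULL

#' Radial (Galbraith) MR with modified second-order weights
#'
#' Reformulates IVW in radial coordinates: the per-SNP Wald ratios
#' \eqn{\hat\beta_j} are regressed through the origin on
#' \eqn{\sqrt{w_j}} after scaling by \eqn{\sqrt{w_j}}, giving slope
#' \eqn{\sum w_j \hat\beta_j / \sum w_j}. Weights are the modified
#' second-order form
#' \eqn{w_j = (se_{out,j}^2/\beta_{exp,j}^2 +
#'   \hat\beta^2 se_{exp,j}^2/\beta_{exp,j}^2)^{-1}},
#' updated from the current slope and iterated to convergence. Each SNP's
#' heterogeneity contribution \eqn{Q_j = w_j(\hat\beta_j - \hat\beta)^2}
#' is chi-square(1) under homogeneity; SNPs with upper-tail p below
#' \code{alpha/k} (Bonferroni over the k instruments) are flagged as
#' outliers.
#'
#' @param set A [HarmonizedSet-class] with at least 2 SNPs.
#' @param alpha Nominal outlier level before the Bonferroni adjustment
#'   (default 0.05).
#' @param maxIter,tol Weight-iteration controls (defaults 100 and 1e-8 on
#'   the slope); non-convergence is an error reporting the last iterate.
#' @return A [RadialResult-class].
#' @export
radialMR <- function(set, alpha = 0.05, maxIter = 100, tol = 1e-8) {
  d <- .setVectors(set, 2L, "radial MR")
  k <- nrow(d)
  ratio <- d$beta_out / d$beta_exp
  ## start from first-order weights
  w <- d$beta_exp^2 / d$se_out^2
  slope <- sum(w * ratio) / sum(w)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- 1 / (d$se_out^2 / d$beta_exp^2 +
                slope^2 * d$se_exp^2 / d$beta_exp^2)
    slopeNew <- sum(w * ratio) / sum(w)
    if (abs(slopeNew - slope) < tol) {
      slope <- slopeNew
      break
    }
    slope <- slopeNew
    if (iter >= maxIter)
      .stopf("radial weight iteration did not converge in %d passes (last slope %.6g)",
             maxIter, slope)
  }
  contrib <- w * (ratio - slope)^2
  names(contrib) <- d$snp
  totalQ <- sum(contrib)
  pPer <- stats::pchisq(contrib, 1, lower.tail = FALSE)
  outliers <- d$snp[pPer < alpha / k]
  methods::new("RadialResult",
    slope = slope, slopeSE = sqrt(1 / sum(w)),
    contributions = contrib, totalQ = totalQ,
    qPval = stats::pchisq(totalQ, k - 1, lower.tail = FALSE),
    outlierIds = outliers, alpha = alpha, iterations = iter)
}
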