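#' @include AllClasses.R uvmr.R instruments.R
NULL

## orientation of a record's alleles (ea2/oa2) relative to reference
## (ea1/oa1): +1 aligned, -1 flipped, NA incompatible
.alleleSign <- function(ea1, oa1, ea2, oa2) {
  out <- rep(NA_real_, length(ea1))
  same <- (ea2 == ea1 & oa2 == oa1) |
          (.revComp(ea2) == ea1 & .revComp(oa2) == oa1)
  swap <- !same & ((ea2 == oa1 & oa2 == ea1) |
                   (.revComp(ea2) == oa1 & .revComp(oa2) == ea1))
  out[same] <- 1
  out[swap] <- -1
  out
}

#' Build a multi-exposure harmonized set for MVMR
#'
#' Takes the union of each exposure's genome-wide-significant SNPs, clumps
#' the union jointly (greedy pass ranked by the best p-value across
#' exposures), aligns every exposure and the outcome to a common effect
#' allele per SNP, drops palindromic variants, and drops SNPs missing from
#' any input table.
#'
#' @param exposures Named list of two or more [GwasTable-class] objects.
#' @param outcome A [GwasTable-class].
#' @param ld LD r-squared matrix covering the candidate union.
#' @param pExposure Significance threshold for instrument candidacy
#'   (default 5e-8).
#' @param r2Max,windowKb Clumping parameters as in [clumpSnps()].
#' @return A [MultiHarmonizedSet-class].
#' @export
buildMvmrSet <- function(exposures, outcome, ld, pExposure = 5e-8,
                         r2Max = 0.01, windowKb = 5000) {
  if (length(exposures) < 2L)
    .stopf("MVMR needs at least 2 exposures")
  stopifnot(all(vapply(exposures, methods::is, TRUE, "GwasTable")),
            methods::is(outcome, "GwasTable"))
  labels <- vapply(exposures, traitLabel, character(1))
  if (is.null(names(exposures))) names(exposures) <- labels

  ## union of significant SNPs, ranked by best cross-exposure p
  cand <- list()
  for (ex in exposures) {
    r <- ex@records
    r <- r[r$pval < pExposure, , drop = FALSE]
    cand[[length(cand) + 1L]] <- r
  }
  cand <- do.call(rbind, cand)
  if (!nrow(cand)) .stopf("no genome-wide-significant SNPs in any exposure")
  cand <- cand[order(cand$pval, cand$snp), , drop = FALSE]
  cand <- cand[!duplicated(cand$snp), , drop = FALSE]  # keep best p per SNP
  rownames(cand) <- NULL
  unionTable <- methods::new("GwasTable", traitLabel = "mvmr-union",
                             records = cand)
  clumped <- clumpSnps(unionTable, ld, r2Max = r2Max, windowKb = windowKb)
  ref <- clumped@records

  action <- rep("kept", nrow(ref))
  pal <- isPalindromic(ref$effect_allele, ref$other_allele)
  action[pal] <- "dropped-palindromic"

  m <- length(exposures)
  k0 <- nrow(ref)
  betaExp <- matrix(NA_real_, k0, m, dimnames = list(ref$snp, labels))
  seExp <- matrix(NA_real_, k0, m, dimnames = list(ref$snp, labels))
  for (j in seq_len(m)) {
    r <- exposures[[j]]@records
    idx <- match(ref$snp, r$snp)
    hit <- !is.na(idx)
    sgn <- rep(NA_real_, k0)
    sgn[hit] <- .alleleSign(ref$effect_allele[hit], ref$other_allele[hit],
                            r$effect_allele[idx[hit]],
                            r$other_allele[idx[hit]])
    betaExp[hit, j] <- r$beta[idx[hit]] * sgn[hit]
    seExp[hit, j] <- r$se[idx[hit]]
  }
  o <- outcome@records
  idx <- match(ref$snp, o$snp)
  hit <- !is.na(idx)
  sgnO <- rep(NA_real_, k0)
  sgnO[hit] <- .alleleSign(ref$effect_allele[hit], ref$other_allele[hit],
                           o$effect_allele[idx[hit]],
                           o$other_allele[idx[hit]])
  betaOut <- rep(NA_real_, k0)
  seOut <- rep(NA_real_, k0)
  betaOut[hit] <- o$beta[idx[hit]] * sgnO[hit]
  seOut[hit] <- o$se[idx[hit]]

  incomplete <- action == "kept" &
    (apply(is.na(betaExp), 1, any) | is.na(betaOut))
  action[incomplete] <- "dropped-missing"

  keep <- action == "kept"
  if (sum(keep) <= m)
    .stopf("underdetermined MVMR: %d SNPs for %d exposures",
           sum(keep), m)
  audit <- data.frame(snp = ref$snp, action = action,
                      stringsAsFactors = FALSE)
  notSig <- setdiff(cand$snp, ref$snp)
  if (length(notSig))
    audit <- rbind(audit,
                   data.frame(snp = notSig, action = "dropped-clumped",
                              stringsAsFactors = FALSE))
  methods::new("MultiHarmonizedSet",
    exposureLabels = labels, outcomeLabel = outcome@traitLabel,
    snps = ref$snp[keep],
    betaExp = betaExp[keep, , drop = FALSE],
    seExp = seExp[keep, , drop = FALSE],
    betaOut = betaOut[keep], seOut = seOut[keep], audit = audit)
}

#' Assemble a MultiHarmonizedSet from aligned matrices
#'
#' Convenience constructor for effects already expressed on a common
#' effect allele per SNP (e.g. simulator output).
#'
#' @param snps SNP ids.
#' @param betaExp,seExp k x m matrices (columns named by exposure).
#' @param betaOut,seOut Outcome effect and SE vectors.
#' @param outcomeLabel Outcome name.
#' @return A [MultiHarmonizedSet-class].
#' @export
multiHarmonizedSet <- function(snps, betaExp, seExp, betaOut, seOut,
                               outcomeLabel = "outcome") {
  labels <- colnames(betaExp)
  if (is.null(labels)) labels <- paste0("exposure", seq_len(ncol(betaExp)))
  methods::new("MultiHarmonizedSet",
    exposureLabels = labels, outcomeLabel = outcomeLabel,
    snps = as.character(snps), betaExp = unname(betaExp) + 0,
    seExp = unname(seExp) + 0, betaOut = betaOut, seOut = seOut,
    audit = data.frame(snp = as.character(snps), action = "kept",
                       stringsAsFactors = FALSE))
}

.mvmrFit <- function(set, intercept, modelLabel, method) {
  k <- length(set@snps)
  m <- length(set@exposureLabels)
  minK <- m + 1L + as.integer(intercept)
  if (k <= minK - 1L)
    .stopf("%s requires more than %d SNPs for %d exposures (have %d)",
           method, minK - 1L, m, k)
  X <- set@betaExp
  colnames(X) <- set@exposureLabels
  y <- set@betaOut
  if (intercept) {
    ## orient rows so the first exposure's effects are non-negative
    flip <- sign(X[, 1])
    flip[flip == 0] <- 1
    X <- X * flip
    y <- y * flip
    X <- cbind(`(intercept)` = 1, X)
  }
  w <- 1 / set@seOut^2
  fit <- .wlsFit(X, y, w)
  df <- k - ncol(X)
  Q <- fit$rss
  infl <- sqrt(max(1, Q / df))          # multiplicative random effects
  se <- fit$seUnit * infl
  z <- qnorm(0.975)
  sel <- set@exposureLabels
  est <- data.frame(exposure = sel, beta = fit$coef[sel], se = se[sel],
                    ciLow = fit$coef[sel] - z * se[sel],
                    ciHigh = fit$coef[sel] + z * se[sel],
                    pval = 2 * stats::pnorm(-abs(fit$coef[sel] / se[sel])),
                    row.names = NULL, stringsAsFactors = FALSE)
  interceptTest <- NULL
  if (intercept) {
    b0 <- fit$coef[["(intercept)"]]
    s0 <- se[["(intercept)"]]
    interceptTest <- methods::new("EggerInterceptTest", estimate = b0,
                                  se = s0,
                                  pval = 2 * stats::pnorm(-abs(b0 / s0)))
  }
  methods::new("MvmrResult",
    modelLabel = modelLabel, method = method, estimates = est,
    intercept = interceptTest, qStat = Q, qDf = as.numeric(df),
    qPval = stats::pchisq(Q, df, lower.tail = FALSE),
    condF = .conditionalF(set), nsnp = as.integer(k))
}

## two-sample conditional instrument-strength F: for each exposure,
## regress its effects on the other exposures' (weights 1/se_i^2) and
## scale the residual heterogeneity by the residual df
.conditionalF <- function(set) {
  m <- length(set@exposureLabels)
  k <- length(set@snps)
  out <- numeric(m)
  names(out) <- set@exposureLabels
  for (i in seq_len(m)) {
    others <- set@betaExp[, -i, drop = FALSE]
    wi <- 1 / set@seExp[, i]^2
    if (ncol(others)) {
      fit <- .wlsFit(cbind(others), set@betaExp[, i], wi)
      qx <- fit$rss
    } else {
      qx <- sum(wi * set@betaExp[, i]^2)
    }
    out[i] <- qx / (k - m + 1)
  }
  out
}

#' Multivariable IVW
#'
#' Weighted least squares of the outcome effects on the m exposure-effect
#' columns with no intercept and weights \eqn{1/se_{out}^2}; each
#' coefficient is that exposure's direct effect conditional on the others.
#' SEs use the weighted LS covariance with multiplicative random-effects
#' inflation \eqn{\sqrt{\max(1, Q/(k-m))}}; residual Cochran's Q is
#' reported, along with conditional instrument-strength F statistics
#' (reported, not gated on).
#'
#' @param set A [MultiHarmonizedSet-class] with k > m + 1 SNPs.
#' @param modelLabel Free-text label stored on the result.
#' @return An [MvmrResult-class].
#' @export
mvmrIVW <- function(set, modelLabel = NULL) {
  if (is.null(modelLabel))
    modelLabel <- paste(set@exposureLabels, collapse = " + ")
  .mvmrFit(set, intercept = FALSE, modelLabel = modelLabel,
           method = "MVMR-IVW")
}

#' Multivariable MR-Egger
#'
#' As [mvmrIVW()] plus an intercept column; rows are oriented so the
#' first exposure's effects are non-negative. The intercept test doubles
#' as the MVMR directional-pleiotropy check.
#'
#' @param set A [MultiHarmonizedSet-class] with k > m + 2 SNPs.
#' @param modelLabel Free-text label stored on the result.
#' @return An [MvmrResult-class] with a non-NULL \code{intercept}.
#' @export
mvmrEgger <- function(set, modelLabel = NULL) {
  if (is.null(modelLabel))
    modelLabel <- paste(set@exposureLabels, collapse = " + ")
  .mvmrFit(set, intercept = TRUE, modelLabel = modelLabel,
           method = "MVMR-Egger")
}
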