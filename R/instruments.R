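#' @include AllClasses.R harmonize.R
NULL

#' Multi-instrument F statistic
#'
#' Instrument-strength F for a set of k variants jointly explaining a
#' fraction r2 of exposure variance in a sample of size n:
#' \deqn{F = (R^2/k) / ((1-R^2)/(n-k-1)).}
#' F > 10 is the conventional weak-instrument cutoff.
#'
#' @param r2 Variance explained, in \[0, 1).
#' @param k Number of instruments (positive integer).
#' @param n Sample size; must satisfy n > k + 1.
#' @return The F value.
#' @examples
#' fStatistic(0.5, 1, 3)           # 1
#' fStatistic(0.02, 40, 40000)     # about 20.4
#' @export
fStatistic <- function(r2, k, n) {
  if (any(r2 < 0 | r2 >= 1)) .stopf("r2 must lie in [0, 1)")
  if (any(k < 1)) .stopf("k must be a positive integer")
  if (any(n - k - 1 < 1)) .stopf("degrees of freedom: need n > k + 1")
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Per-SNP variance explained for a binary trait
#'
#' Default approximation on the log-odds scale:
#' \eqn{r^2 = 2 p (1-p) \beta^2} with p the effect-allele frequency.
#'
#' @param eaf Effect-allele frequency (strictly inside (0,1)).
#' @param beta Per-allele effect on the log-odds scale.
#' @return Vector of per-SNP variance explained.
#' @examples
#' perSnpR2(0.3, 0.2)  # 2*0.3*0.7*0.04 = 0.0168
#' @export
perSnpR2 <- function(eaf, beta) {
  if (anyNA(eaf)) .stopf("missing eaf: cannot compute variance explained")
  if (any(eaf <= 0 | eaf >= 1)) .stopf("eaf must lie strictly in (0, 1)")
  2 * eaf * (1 - eaf) * beta^2
}

#' Greedy LD clumping of summary statistics
#'
#' Standard p-value-ranked greedy pruning: SNPs are visited in ascending
#' p-value order (ties broken by lexicographic snp id, so the result is
#' independent of input row order) and accepted iff their r-squared with
#' every already-accepted SNP within \code{windowKb} is below \code{r2Max}.
#' When positions are absent the window is ignored and every pair is
#' compared.
#'
#' @param table A [GwasTable-class].
#' @param ld LD r-squared matrix covering all SNPs of \code{table}
#'   (see [ldMatrix()]).
#' @param r2Max Pruning threshold (default 0.01).
#' @param windowKb Window in kilobases (default 5000).
#' @return A [GwasTable-class] of retained SNPs.
#' @export
clumpSnps <- function(table, ld, r2Max = 0.01, windowKb = 5000) {
  stopifnot(methods::is(table, "GwasTable"))
  r <- table@records
  if (!nrow(r)) return(table)
  missing <- setdiff(r$snp, colnames(ld))
  if (length(missing))
    .stopf("SNP(s) absent from LD matrix: %s",
           paste(missing, collapse = ", "))
  ord <- order(r$pval, r$snp)
  accepted <- integer(0)
  havePos <- !anyNA(r$chrom) && !anyNA(r$pos)
  for (i in ord) {
    conflict <- FALSE
    for (j in accepted) {
      inWindow <- TRUE
      if (havePos)
        inWindow <- r$chrom[i] == r$chrom[j] &&
          abs(r$pos[i] - r$pos[j]) <= windowKb * 1000
      if (inWindow && ld[r$snp[i], r$snp[j]] >= r2Max) {
        conflict <- TRUE
        break
      }
    }
    if (!conflict) accepted <- c(accepted, i)
  }
  keep <- sort(accepted)
  methods::new("GwasTable", traitLabel = table@traitLabel,
               records = {
                 x <- r[keep, , drop = FALSE]; rownames(x) <- NULL; x
               })
}

#' Select instruments for one exposure
#'
#' Applies, in order: (1) exposure genome-wide significance
#' (p < \code{pExposure}); (2) greedy LD clumping at
#' (\code{r2Max}, \code{windowKb}); (3) exclusion of SNPs significantly
#' associated with the outcome (p < \code{pOutcome}), which likely act on
#' the outcome directly. The retained set's variance explained is the sum
#' of per-SNP \eqn{2p(1-p)\beta^2} contributions, and the overall F uses
#' [fStatistic()] with n = the exposure's \code{n_total}; the set is
#' declared valid iff F > \code{fMin}. Per-SNP F values (k = 1) are also
#' reported.
#'
#' @param exposure,outcome [GwasTable-class] objects.
#' @param ld LD r-squared matrix covering the significance-filtered SNPs.
#' @param pExposure,pOutcome,r2Max,windowKb,fMin Thresholds; defaults are
#'   genome-wide significance 5e-8 on both sides, clumping at r2 0.01
#'   within 5000 kb, and minimum F of 10.
#' @return An [InstrumentSet-class].
#' @export
selectInstruments <- function(exposure, outcome, ld,
                              pExposure = 5e-8, pOutcome = 5e-8,
                              r2Max = 0.01, windowKb = 5000, fMin = 10) {
  stopifnot(methods::is(exposure, "GwasTable"),
            methods::is(outcome, "GwasTable"))
  if (!nSnps(exposure) || !nSnps(outcome))
    .stopf("both tables must be non-empty")
  e <- exposure@records
  audit <- data.frame(snp = e$snp, action = "kept",
                      stringsAsFactors = FALSE)

  sig <- e$pval < pExposure
  audit$action[!sig] <- "dropped-not-significant"
  stage1 <- methods::new("GwasTable", traitLabel = exposure@traitLabel,
                         records = {
                           x <- e[sig, , drop = FALSE]
                           rownames(x) <- NULL; x
                         })
  if (!nSnps(stage1))
    .stopf("no SNPs survive the exposure-significance filter (p < %g)",
           pExposure)

  stage2 <- clumpSnps(stage1, ld, r2Max = r2Max, windowKb = windowKb)
  clumped <- setdiff(stage1@records$snp, stage2@records$snp)
  audit$action[audit$snp %in% clumped] <- "dropped-clumped"
  if (!nSnps(stage2))
    .stopf("no SNPs survive LD clumping")

  o <- outcome@records
  oP <- o$pval[match(stage2@records$snp, o$snp)]
  outSig <- !is.na(oP) & oP < pOutcome
  audit$action[audit$snp %in% stage2@records$snp[outSig]] <-
    "dropped-outcome-significant"
  kept <- stage2@records[!outSig, , drop = FALSE]
  rownames(kept) <- NULL
  if (!nrow(kept))
    .stopf("no SNPs survive the outcome-significance exclusion (p < %g)",
           pOutcome)

  if (anyNA(kept$eaf))
    .stopf("missing eaf for retained SNP(s): variance explained undefined")
  r2 <- perSnpR2(kept$eaf, kept$beta)
  names(r2) <- kept$snp
  r2Total <- sum(r2)
  n <- kept$n_total
  n <- if (all(is.na(n))) NA_real_ else max(n, na.rm = TRUE)
  k <- nrow(kept)
  fAll <- if (is.na(n)) NA_real_ else fStatistic(min(r2Total, 1 - 1e-12), k, n)
  fPer <- if (is.na(n)) rep(NA_real_, k)
          else fStatistic(pmin(r2, 1 - 1e-12), 1, n)
  names(fPer) <- kept$snp

  methods::new("InstrumentSet",
    exposureLabel = exposure@traitLabel,
    table = methods::new("GwasTable", traitLabel = exposure@traitLabel,
                         records = kept),
    r2PerSnp = r2, r2Total = r2Total, fStat = fAll, fPerSnp = fPer,
    thresholds = list(p_exposure = pExposure, p_outcome = pOutcome,
                      r2_clump = r2Max, kb_clump = windowKb, f_min = fMin,
                      r2_method = "2p(1-p)beta^2 (log-odds scale)"),
    valid = isTRUE(fAll > fMin), audit = audit)
}
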