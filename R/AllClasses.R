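## S4 containers for the MR pipeline. Validity methods enforce the data
## contracts; constructors below do coercion and friendlier error messages.

.VALID_ALLELES <- c("A", "C", "G", "T")

.GWAS_COLUMNS <- c("snp", "effect_allele", "other_allele", "eaf",
                   "beta", "se", "pval", "n_cases", "n_total",
                   "chrom", "pos")

#' GwasTable: one trait's GWAS summary statistics
#'
#' Per-SNP association summary statistics for a single (case-control) trait
#' on the log-odds scale. The \code{records} data.frame always carries the
#' canonical columns \code{snp}, \code{effect_allele}, \code{other_allele},
#' \code{eaf}, \code{beta}, \code{se}, \code{pval}, \code{n_cases},
#' \code{n_total}, \code{chrom}, \code{pos}; \code{eaf}, \code{n_cases},
#' \code{chrom} and \code{pos} may be \code{NA}. Coordinates are 1-based and
#' are carried but never used for record matching (\code{snp} is the key).
#'
#' @slot traitLabel Trait name, e.g. an endpoint identifier.
#' @slot records data.frame of per-SNP records, one row per SNP.
#' @seealso [gwasTable()], [readGwas()], [harmonize()]
#' @export
setClass("GwasTable",
  representation(traitLabel = "character", records = "data.frame"))

setValidity("GwasTable", function(object) {
  r <- object@records
  msg <- character()
  if (length(object@traitLabel) != 1L || is.na(object@traitLabel))
    msg <- c(msg, "traitLabel must be a single non-NA string")
  if (!all(.GWAS_COLUMNS %in% names(r)))
    msg <- c(msg, paste("records lacks columns:",
                        paste(setdiff(.GWAS_COLUMNS, names(r)), collapse = ", ")))
  if (length(msg)) return(msg)
  if (anyDuplicated(r$snp))
    msg <- c(msg, "snp ids must be unique within a table")
  if (nrow(r)) {
    if (!all(r$effect_allele %in% .VALID_ALLELES) ||
        !all(r$other_allele %in% .VALID_ALLELES))
      msg <- c(msg, "alleles must be one of A, C, G, T")
    if (any(r$effect_allele == r$other_allele))
      msg <- c(msg, "effect_allele must differ from other_allele")
    if (any(!is.finite(r$se) | r$se <= 0))
      msg <- c(msg, "se must be finite and > 0")
    if (any(!is.finite(r$pval) | r$pval <= 0 | r$pval > 1))
      msg <- c(msg, "pval must lie in (0, 1]")
    eaf <- r$eaf[!is.na(r$eaf)]
    if (any(eaf <= 0 | eaf >= 1))
      msg <- c(msg, "eaf, when present, must lie strictly in (0, 1)")
    nt <- r$n_total[!is.na(r$n_total)]
    if (any(nt <= 0)) msg <- c(msg, "n_total must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' HarmonizedSet: exposure-outcome aligned effect estimates
#'
#' Output of [harmonize()]: per-SNP exposure and outcome effects expressed
#' relative to the exposure's effect allele, plus a per-SNP audit of the
#' action taken on every SNP in the id intersection.
#'
#' @slot exposureLabel,outcomeLabel Trait names.
#' @slot data data.frame with columns \code{snp}, \code{beta_exp},
#'   \code{se_exp}, \code{beta_out}, \code{se_out}, \code{eaf_exp}.
#' @slot audit data.frame with columns \code{snp}, \code{action}.
#' @slot palindromePolicy Policy used ("drop_all" or "infer_by_eaf").
#' @export
setClass("HarmonizedSet",
  representation(exposureLabel = "character", outcomeLabel = "character",
                 data = "data.frame", audit = "data.frame",
                 palindromePolicy = "character"))

.HARMONIZE_ACTIONS <- c("kept", "allele-flipped", "dropped-palindromic",
                        "dropped-missing", "dropped-incompatible",
                        "dropped-outcome-significant")

setValidity("HarmonizedSet", function(object) {
  d <- object@data
  msg <- character()
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out", "eaf_exp")
  if (!all(need %in% names(d)))
    msg <- c(msg, "data lacks required columns")
  if (!all(c("snp", "action") %in% names(object@audit)))
    msg <- c(msg, "audit lacks snp/action columns")
  if (length(msg)) return(msg)
  if (anyDuplicated(d$snp)) msg <- c(msg, "duplicated snp in data")
  if (nrow(d) && any(d$se_exp <= 0 | d$se_out <= 0))
    msg <- c(msg, "standard errors must be > 0")
  if (!all(object@audit$action %in% .HARMONIZE_ACTIONS))
    msg <- c(msg, "unknown audit action")
  retained <- object@audit$snp[object@audit$action %in%
                                 c("kept", "allele-flipped")]
  if (!setequal(retained, d$snp))
    msg <- c(msg, "audit retained set must equal data snp set")
  if (length(msg)) msg else TRUE
})

#' MultiHarmonizedSet: several exposures aligned to one outcome
#'
#' Output of [buildMvmrSet()]: per-SNP effect estimates for m exposures and
#' one outcome, all expressed relative to a common effect allele per SNP.
#'
#' @slot exposureLabels Ordered exposure names (columns of the matrices).
#' @slot outcomeLabel Outcome name.
#' @slot snps SNP ids (rows).
#' @slot betaExp,seExp k x m matrices of exposure effects / SEs.
#' @slot betaOut,seOut Outcome effect / SE vectors (length k).
#' @slot audit Per-SNP action data.frame as in [HarmonizedSet-class].
#' @export
setClass("MultiHarmonizedSet",
  representation(exposureLabels = "character", outcomeLabel = "character",
                 snps = "character", betaExp = "matrix", seExp = "matrix",
                 betaOut = "numeric", seOut = "numeric", audit = "data.frame"))

setValidity("MultiHarmonizedSet", function(object) {
  k <- length(object@snps); m <- length(object@exposureLabels)
  msg <- character()
  if (!all(dim(object@betaExp) == c(k, m)) ||
      !all(dim(object@seExp) == c(k, m)))
    msg <- c(msg, "betaExp/seExp must be k x m")
  if (length(object@betaOut) != k || length(object@seOut) != k)
    msg <- c(msg, "betaOut/seOut must have length k")
  if (k && m && k <= m)
    msg <- c(msg, "need more SNPs than exposures")
  if (k && anyNA(object@betaExp))
    msg <- c(msg, "retained rows must have no missing exposure betas")
  if (length(msg)) msg else TRUE
})

#' InstrumentSet: selected instruments for one exposure
#'
#' Output of [selectInstruments()]. Carries the retained records, per-SNP
#' and total variance explained (2p(1-p)beta^2 approximation on the log-odds
#' scale), per-SNP and overall F statistics, the thresholds used, and a
#' stage-by-stage audit of how the candidate set was filtered.
#'
#' @slot exposureLabel Exposure name.
#' @slot table [GwasTable-class] of retained SNPs.
#' @slot r2PerSnp Named per-SNP variance explained.
#' @slot r2Total Sum of \code{r2PerSnp}.
#' @slot fStat Overall F for the retained set.
#' @slot fPerSnp Named per-SNP F (k = 1 in the formula).
#' @slot thresholds List of the thresholds applied.
#' @slot valid TRUE iff \code{fStat} exceeds the configured minimum.
#' @slot audit data.frame with columns \code{snp}, \code{action}.
#' @export
setClass("InstrumentSet",
  representation(exposureLabel = "character", table = "GwasTable",
                 r2PerSnp = "numeric", r2Total = "numeric",
                 fStat = "numeric", fPerSnp = "numeric",
                 thresholds = "list", valid = "logical",
                 audit = "data.frame"))

#' MREstimate: a causal-effect estimate
#'
#' One method's causal estimate on the log-odds-ratio scale, with its
#' normal-approximation 95\% interval and odds-ratio transform.
#'
#' @slot method Method label ("IVW", "MR-Egger", "WeightedMedian",
#'   "SimpleMode", "WeightedMode", "WaldRatio", "MVMR-IVW", "MVMR-Egger").
#' @slot beta,se Causal log-OR and its standard error.
#' @slot ciLow,ciHigh 95\% bounds on the log-OR scale.
#' @slot pval Two-sided p-value.
#' @slot orValue,orCiLow,orCiHigh Exponentiated estimate and bounds.
#' @slot nsnp Number of instruments used.
#' @slot extras Method-specific extras (e.g. Q statistic for IVW).
#' @export
setClass("MREstimate",
  representation(method = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 orValue = "numeric", orCiLow = "numeric",
                 orCiHigh = "numeric", nsnp = "integer", extras = "list"))

setValidity("MREstimate", function(object) {
  msg <- character()
  if (is.finite(object@beta) && is.finite(object@ciLow) &&
      (object@ciLow > object@beta || object@ciHigh < object@beta))
    msg <- c(msg, "CI must bracket the point estimate")
  if (is.finite(object@orValue) && object@orValue <= 0)
    msg <- c(msg, "odds ratio must be positive")
  if (length(msg)) msg else TRUE
})

#' EggerInterceptTest: directional-pleiotropy test
#'
#' The MR-Egger intercept with its SE and two-sided p-value; p > 0.05 is
#' conventionally read as no evidence of directional horizontal pleiotropy.
#'
#' @slot estimate,se,pval Intercept estimate, SE and p-value.
#' @export
setClass("EggerInterceptTest",
  representation(estimate = "numeric", se = "numeric", pval = "numeric"))

#' QResult: Cochran's Q heterogeneity test
#'
#' @slot qStat Q statistic (sum of the per-SNP contributions).
#' @slot df Degrees of freedom: k-1 (IVW reference) or k-2 (Egger).
#' @slot pval Upper-tail chi-square p-value.
#' @slot contributions Named per-SNP contributions.
#' @slot reference Reference fit ("ivw" or "egger").
#' @export
setClass("QResult",
  representation(qStat = "numeric", df = "numeric", pval = "numeric",
                 contributions = "numeric", reference = "character"))

setValidity("QResult", function(object) {
  if (length(object@contributions) &&
      abs(object@qStat - sum(object@contributions)) >
        1e-6 * max(1, object@qStat))
    "qStat must equal the sum of per-SNP contributions" else TRUE
})

#' PressoResult: MR-PRESSO global, outlier and distortion tests
#'
#' @slot globalRss Observed leave-one-out residual sum of squares.
#' @slot globalPval Simulation p-value of the global test.
#' @slot outlierPvals Named per-SNP p-values (Bonferroni-corrected).
#' @slot outlierIds SNPs flagged at the configured alpha.
#' @slot distortionPval Distortion-test p-value (NA when no outliers).
#' @slot estimateBefore,estimateAfter IVW estimates on the full set and on
#'   the complement of the flagged outliers (after is NULL when none).
#' @slot nSim,seed Simulation settings used.
#' @export
setClass("PressoResult",
  representation(globalRss = "numeric", globalPval = "numeric",
                 outlierPvals = "numeric", outlierIds = "character",
                 distortionPval = "numeric", estimateBefore = "MREstimate",
                 estimateAfter = "ANY", nSim = "integer", seed = "integer"))

#' RadialResult: radial (Galbraith) MR with modified second-order weights
#'
#' @slot slope Radial IVW slope (causal estimate).
#' @slot slopeSE Standard error of the slope.
#' @slot contributions Named per-SNP Q contributions.
#' @slot totalQ Sum of contributions.
#' @slot qPval Upper-tail chi-square(k-1) p of totalQ.
#' @slot outlierIds SNPs whose contribution exceeds the Bonferroni-adjusted
#'   chi-square(1) critical value at \code{alpha}.
#' @slot alpha Nominal level before the multiplicity adjustment.
#' @slot iterations Weight-update iterations used.
#' @export
setClass("RadialResult",
  representation(slope = "numeric", slopeSE = "numeric",
                 contributions = "numeric", totalQ = "numeric",
                 qPval = "numeric", outlierIds = "character",
                 alpha = "numeric", iterations = "integer"))

#' SteigerResult: directionality test
#'
#' @slot r2Exposure,r2Outcome Instrument variance explained on each side.
#' @slot zStat Z statistic for the difference of Fisher-transformed
#'   correlations from two independent samples.
#' @slot pval Two-sided normal p-value.
#' @slot directionOk TRUE iff r2Exposure > r2Outcome and pval < alpha.
#' @slot alpha Level used for the verdict.
#' @export
setClass("SteigerResult",
  representation(r2Exposure = "numeric", r2Outcome = "numeric",
                 zStat = "numeric", pval = "numeric",
                 directionOk = "logical", alpha = "numeric"))

#' LooTable: leave-one-out influence analysis
#'
#' @slot estimates data.frame with one row per left-out SNP: \code{snp},
#'   \code{beta}, \code{se}, \code{ciLow}, \code{ciHigh}, \code{pval},
#'   \code{flag}. A row is flagged when the full-set estimate is
#'   significant (its CI excludes 0) but the left-out CI no longer supports
#'   an effect of the same sign.
#' @slot fullEstimate IVW estimate on the complete set.
#' @export
setClass("LooTable",
  representation(estimates = "data.frame", fullEstimate = "MREstimate"))

#' MvmrResult: multivariable MR direct effects
#'
#' @slot modelLabel Free-text model label (e.g. "TOS adjusted for GD").
#' @slot method "MVMR-IVW" or "MVMR-Egger".
#' @slot estimates data.frame, one row per exposure: \code{exposure},
#'   \code{beta}, \code{se}, \code{ciLow}, \code{ciHigh}, \code{pval}.
#' @slot intercept [EggerInterceptTest-class] for MVMR-Egger, else NULL.
#' @slot qStat,qDf,qPval Residual heterogeneity.
#' @slot condF Named conditional instrument-strength F per exposure.
#' @slot nsnp Instruments used.
#' @export
setClass("MvmrResult",
  representation(modelLabel = "character", method = "character",
                 estimates = "data.frame", intercept = "ANY",
                 qStat = "numeric", qDf = "numeric", qPval = "numeric",
                 condF = "numeric", nsnp = "integer"))

#' MetaResult: pooled causal estimate across outcome stages
#'
#' @slot model "fixed", "random_DL" or "random_REML".
#' @slot beta,se Pooled log-OR and SE.
#' @slot ciLow,ciHigh,pval 95\% bounds and two-sided p.
#' @slot qStat,df,qPval Heterogeneity across pooled rows.
#' @slot tau2 Between-study variance (0 for fixed).
#' @slot i2 Higgins I-squared in percent.
#' @slot subgroups Named list of per-subgroup [MetaResult-class] objects
#'   (empty unless produced by [subgroupMeta()]).
#' @export
setClass("MetaResult",
  representation(model = "character", beta = "numeric", se = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", pval = "numeric",
                 qStat = "numeric", df = "numeric", qPval = "numeric",
                 tau2 = "numeric", i2 = "numeric", subgroups = "list"))

setValidity("MetaResult", function(object) {
  msg <- character()
  if (is.finite(object@tau2) && object@tau2 < 0)
    msg <- c(msg, "tau2 must be >= 0")
  if (is.finite(object@i2) && (object@i2 < 0 || object@i2 > 100))
    msg <- c(msg, "i2 must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
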