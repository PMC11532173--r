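#' @include AllClasses.R AllGenerics.R
NULL

## ---- accessors -----------------------------------------------------------

#' @describeIn GwasTable-class trait label
#' @export
setMethod("traitLabel", "GwasTable", function(x) x@traitLabel)

#' @describeIn InstrumentSet-class exposure label
#' @export
setMethod("traitLabel", "InstrumentSet", function(x) x@exposureLabel)

#' @describeIn GwasTable-class SNP ids
#' @export
setMethod("snpIds", "GwasTable", function(x) x@records$snp)

#' @describeIn HarmonizedSet-class retained SNP ids
#' @export
setMethod("snpIds", "HarmonizedSet", function(x) x@data$snp)

#' @describeIn MultiHarmonizedSet-class retained SNP ids
#' @export
setMethod("snpIds", "MultiHarmonizedSet", function(x) x@snps)

#' @describeIn InstrumentSet-class retained SNP ids
#' @export
setMethod("snpIds", "InstrumentSet", function(x) x@table@records$snp)

#' @describeIn GwasTable-class number of records
#' @export
setMethod("nSnps", "GwasTable", function(x) nrow(x@records))

#' @describeIn HarmonizedSet-class number of retained SNPs
#' @export
setMethod("nSnps", "HarmonizedSet", function(x) nrow(x@data))

#' @describeIn MultiHarmonizedSet-class number of retained SNPs
#' @export
setMethod("nSnps", "MultiHarmonizedSet", function(x) length(x@snps))

#' @describeIn InstrumentSet-class number of retained SNPs
#' @export
setMethod("nSnps", "InstrumentSet", function(x) nrow(x@table@records))

#' @describeIn HarmonizedSet-class per-SNP harmonization audit
#' @export
setMethod("auditTrail", "HarmonizedSet", function(x) x@audit)

#' @describeIn MultiHarmonizedSet-class per-SNP harmonization audit
#' @export
setMethod("auditTrail", "MultiHarmonizedSet", function(x) x@audit)

#' @describeIn InstrumentSet-class per-SNP selection audit
#' @export
setMethod("auditTrail", "InstrumentSet", function(x) x@audit)

#' @describeIn PressoResult-class flagged outlier SNPs
#' @export
setMethod("outlierIds", "PressoResult", function(x) x@outlierIds)

#' @describeIn RadialResult-class flagged outlier SNPs
#' @export
setMethod("outlierIds", "RadialResult", function(x) x@outlierIds)

## ---- coercion ------------------------------------------------------------

#' @export
#' @method as.data.frame GwasTable
as.data.frame.GwasTable <- function(x, ...) x@records

#' @export
#' @method as.data.frame HarmonizedSet
as.data.frame.HarmonizedSet <- function(x, ...) x@data

#' Tidy one-row summary of an estimate
#'
#' @param x An [MREstimate-class].
#' @param ... Unused.
#' @return A one-row data.frame with method, nsnp, beta, se, or, CI, p.
#' @export
#' @method as.data.frame MREstimate
as.data.frame.MREstimate <- function(x, ...) {
  data.frame(method = x@method, nsnp = x@nsnp, beta = x@beta, se = x@se,
             or = x@orValue, or_ci_low = x@orCiLow, or_ci_high = x@orCiHigh,
             pval = x@pval, stringsAsFactors = FALSE)
}

#' @export
#' @method as.data.frame MvmrResult
as.data.frame.MvmrResult <- function(x, ...) {
  cbind(model = x@modelLabel, method = x@method, x@estimates,
        stringsAsFactors = FALSE)
}

#' @export
#' @method as.data.frame MetaResult
as.data.frame.MetaResult <- function(x, ...) {
  data.frame(model = x@model, beta = x@beta, se = x@se,
             or = exp(x@beta), or_ci_low = exp(x@ciLow),
             or_ci_high = exp(x@ciHigh), pval = x@pval,
             q = x@qStat, q_df = x@df, q_pval = x@qPval,
             tau2 = x@tau2, i2 = x@i2, stringsAsFactors = FALSE)
}

## ---- show ----------------------------------------------------------------

setMethod("show", "GwasTable", function(object) {
  cat("GwasTable '", object@traitLabel, "': ", nrow(object@records),
      " SNPs\n", sep = "")
  if (nrow(object@records))
    print(utils::head(object@records, 5L), row.names = FALSE)
  if (nrow(object@records) > 5L) cat("...\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  acts <- table(object@audit$action)
  cat("HarmonizedSet ", object@exposureLabel, " -> ", object@outcomeLabel,
      ": ", nrow(object@data), " SNPs retained (policy ",
      object@palindromePolicy, ")\n", sep = "")
  cat("  audit:", paste(names(acts), acts, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MultiHarmonizedSet", function(object) {
  cat("MultiHarmonizedSet [", paste(object@exposureLabels, collapse = ", "),
      "] -> ", object@outcomeLabel, ": ", length(object@snps),
      " SNPs\n", sep = "")
})

setMethod("show", "InstrumentSet", function(object) {
  cat("InstrumentSet '", object@exposureLabel, "': ",
      nrow(object@table@records), " SNPs, sum r2 = ",
      signif(object@r2Total, 4), ", F = ", signif(object@fStat, 5),
      if (object@valid) " (valid)" else " (weak)", "\n", sep = "")
})

setMethod("show", "MREstimate", function(object) {
  cat(sprintf("%s (k=%d): beta %.4f (se %.4f), OR %.3f [%.3f, %.3f], p %.3g\n",
              object@method, object@nsnp, object@beta, object@se,
              object@orValue, object@orCiLow, object@orCiHigh, object@pval))
})

setMethod("show", "EggerInterceptTest", function(object) {
  cat(sprintf("Egger intercept: %.4f (se %.4f), p %.3g\n",
              object@estimate, object@se, object@pval))
})

setMethod("show", "QResult", function(object) {
  cat(sprintf("Cochran's Q (%s): Q %.3f on %d df, p %.3g\n",
              object@reference, object@qStat, as.integer(object@df),
              object@pval))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("MR-PRESSO: global RSS %.3f, p %.3g; %d outlier(s)%s\n",
              object@globalRss, object@globalPval, length(object@outlierIds),
              if (length(object@outlierIds))
                paste0(" [", paste(object@outlierIds, collapse = ", "), "]")
              else ""))
})

setMethod("show", "RadialResult", function(object) {
  cat(sprintf("Radial MR: slope %.4f (se %.4f), Q %.3f, p %.3g; %d outlier(s)\n",
              object@slope, object@slopeSE, object@totalQ, object@qPval,
              length(object@outlierIds)))
})

setMethod("show", "SteigerResult", function(object) {
  cat(sprintf("Steiger: r2(exposure) %.4g vs r2(outcome) %.4g, z %.2f, p %.3g -> %s\n",
              object@r2Exposure, object@r2Outcome, object@zStat, object@pval,
              if (object@directionOk) "orientation supported"
              else "orientation NOT supported"))
})

setMethod("show", "LooTable", function(object) {
  cat("Leave-one-out over", nrow(object@estimates), "SNPs;",
      sum(object@estimates$flag), "flagged\n")
})

setMethod("show", "MvmrResult", function(object) {
  cat(object@method, "-", object@modelLabel, "(k =", object@nsnp, ")\n")
  print(object@estimates, row.names = FALSE)
  cat(sprintf("  residual Q %.3f on %d df, p %.3g\n",
              object@qStat, as.integer(object@qDf), object@qPval))
})

setMethod("show", "MetaResult", function(object) {
  cat(sprintf("Meta (%s): OR %.3f [%.3f, %.3f], p %.3g; tau2 %.4g, I2 %.1f%%\n",
              object@model, exp(object@beta), exp(object@ciLow),
              exp(object@ciHigh), object@pval, object@tau2, object@i2))
  for (nm in names(object@subgroups)) {
    s <- object@subgroups[[nm]]
    cat(sprintf("  %s: OR %.3f [%.3f, %.3f], p %.3g\n", nm,
                exp(s@beta), exp(s@ciLow), exp(s@ciHigh), s@pval))
  }
})
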