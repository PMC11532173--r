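#' @include AllClasses.R
NULL

#' Trait label of a summary-statistics container
#'
#' @param x A [GwasTable-class] or [InstrumentSet-class].
#' @return A length-one character vector.
#' @export
setGeneric("traitLabel", function(x) standardGeneric("traitLabel"))

#' SNP identifiers carried by an object
#'
#' @param x A container holding per-SNP rows.
#' @return Character vector of SNP ids, in storage order.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Number of SNPs in an object
#'
#' @param x A container holding per-SNP rows.
#' @return Integer count.
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))

#' Per-SNP audit trail of a harmonization or selection step
#'
#' Every SNP that entered the step appears exactly once, with the action
#' taken (\code{kept}, \code{allele-flipped}, \code{dropped-palindromic},
#' \code{dropped-missing}, \code{dropped-incompatible},
#' \code{dropped-outcome-significant}, or a selection-stage label).
#'
#' @param x A [HarmonizedSet-class], [MultiHarmonizedSet-class] or
#'   [InstrumentSet-class].
#' @return A data.frame with columns \code{snp} and \code{action}.
#' @export
setGeneric("auditTrail", function(x) standardGeneric("auditTrail"))

#' Outlier SNP ids flagged by a diagnostic
#'
#' @param x A [PressoResult-class] or [RadialResult-class].
#' @return Character vector of flagged SNP ids (possibly empty).
#' @export
setGeneric("outlierIds", function(x) standardGeneric("outlierIds"))
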