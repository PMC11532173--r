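#' @include AllClasses.R gwas-io.R
NULL

#' Is an allele pair palindromic?
#'
#' A variant is palindromic (strand-ambiguous) when its two alleles are
#' complementary: A/T or C/G. Such variants cannot be oriented across
#' datasets from allele codes alone.
#'
#' @param a1,a2 Allele codes (A/C/G/T), vectorised.
#' @return Logical vector.
#' @examples
#' isPalindromic("A", "T")  # TRUE
#' isPalindromic("A", "G")  # FALSE
#' @export
isPalindromic <- function(a1, a2) {
  a1 <- toupper(a1); a2 <- toupper(a2)
  if (any(!a1 %in% .VALID_ALLELES) || any(!a2 %in% .VALID_ALLELES))
    .stopf("alleles must be one of A, C, G, T")
  if (any(a1 == a2))
    .stopf("invalid variant: identical alleles")
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on snp id and expresses every outcome effect
#' relative to the exposure's effect allele. Outcome records whose alleles
#' are swapped relative to the exposure have their beta negated (and eaf
#' complemented); allele codes are also compared after reverse
#' complementation, so a strand flip alone does not drop a variant.
#' Palindromic variants are handled per \code{palindromePolicy}:
#' \describe{
#'   \item{drop_all}{(default) every palindromic SNP is removed, since its
#'     orientation is ambiguous across strand conventions.}
#'   \item{infer_by_eaf}{a palindromic SNP is kept when both allele
#'     frequencies fall outside \code{eafWindow} on the same side (kept
#'     as-is) or opposite sides (flipped); otherwise it is dropped.}
#' }
#' Every SNP of the intersection receives exactly one audit action.
#'
#' @param exposure,outcome [GwasTable-class] objects.
#' @param palindromePolicy "drop_all" or "infer_by_eaf".
#' @param eafWindow Ambiguity window for \code{infer_by_eaf}; frequencies
#'   inside \code{[eafWindow[1], eafWindow[2]]} are considered
#'   uninformative.
#' @param pOutcome Optional threshold: SNPs with outcome p-value below it
#'   are dropped (action \code{dropped-outcome-significant}) as likely
#'   direct outcome loci. \code{NULL} (default) disables the filter.
#' @return A [HarmonizedSet-class].
#' @examples
#' exp <- gwasTable(data.frame(snp = c("rs1", "rs2"),
#'   effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'   beta = c(0.1, 0.2), se = c(0.01, 0.02), pval = c(1e-10, 1e-12),
#'   eaf = c(0.3, 0.4)), "exposure")
#' out <- gwasTable(data.frame(snp = c("rs1", "rs2"),
#'   effect_allele = c("G", "C"), other_allele = c("A", "T"),
#'   beta = c(-0.05, 0.02), se = c(0.02, 0.02), pval = c(0.01, 0.3),
#'   eaf = c(0.7, 0.4)), "outcome")
#' h <- harmonize(exp, out)   # rs1 is allele-flipped: beta_out = +0.05
#' as.data.frame(h)
#' @export
harmonize <- function(exposure, outcome,
                      palindromePolicy = c("drop_all", "infer_by_eaf"),
                      eafWindow = c(0.42, 0.58), pOutcome = NULL) {
  stopifnot(methods::is(exposure, "GwasTable"),
            methods::is(outcome, "GwasTable"))
  palindromePolicy <- match.arg(palindromePolicy)
  if (!nSnps(exposure) || !nSnps(outcome))
    .stopf("both tables must be non-empty")
  e <- exposure@records
  o <- outcome@records
  common <- intersect(e$snp, o$snp)
  if (!length(common))
    .stopf("no overlapping SNPs between '%s' and '%s'",
           exposure@traitLabel, outcome@traitLabel)
  e <- e[match(common, e$snp), ]
  o <- o[match(common, o$snp), ]

  action <- character(length(common))
  betaOut <- o$beta
  eafOut <- o$eaf

  sameFwd <- o$effect_allele == e$effect_allele &
             o$other_allele == e$other_allele
  swapFwd <- o$effect_allele == e$other_allele &
             o$other_allele == e$effect_allele
  sameRev <- .revComp(o$effect_allele) == e$effect_allele &
             .revComp(o$other_allele) == e$other_allele
  swapRev <- .revComp(o$effect_allele) == e$other_allele &
             .revComp(o$other_allele) == e$effect_allele

  pal <- isPalindromic(e$effect_allele, e$other_allele)
  keepSame <- !pal & (sameFwd | sameRev)
  keepSwap <- !pal & !keepSame & (swapFwd | swapRev)
  action[keepSame] <- "kept"
  action[keepSwap] <- "allele-flipped"
  betaOut[keepSwap] <- -betaOut[keepSwap]
  eafOut[keepSwap] <- 1 - eafOut[keepSwap]
  action[!pal & !keepSame & !keepSwap] <- "dropped-incompatible"

  if (any(pal)) {
    if (palindromePolicy == "drop_all") {
      action[pal] <- "dropped-palindromic"
    } else {
      ## for palindromes allele codes are uninformative (A/T matches its own
      ## reverse complement); orient by allele frequency when unambiguous
      infoE <- !is.na(e$eaf) & (e$eaf < eafWindow[1] | e$eaf > eafWindow[2])
      infoO <- !is.na(o$eaf) & (o$eaf < eafWindow[1] | o$eaf > eafWindow[2])
      sameSide <- (e$eaf < 0.5) == (o$eaf < 0.5)
      keepP <- pal & infoE & infoO & sameSide
      flipP <- pal & infoE & infoO & !sameSide
      action[keepP] <- "kept"
      action[flipP] <- "allele-flipped"
      betaOut[flipP] <- -betaOut[flipP]
      eafOut[flipP] <- 1 - eafOut[flipP]
      action[pal & !(keepP | flipP)] <- "dropped-palindromic"
    }
  }

  retained <- action %in% c("kept", "allele-flipped")
  if (!is.null(pOutcome)) {
    sig <- retained & o$pval < pOutcome
    action[sig] <- "dropped-outcome-significant"
    retained <- retained & !sig
  }

  data <- data.frame(snp = common[retained],
                     beta_exp = e$beta[retained],
                     se_exp = e$se[retained],
                     beta_out = betaOut[retained],
                     se_out = o$se[retained],
                     eaf_exp = e$eaf[retained],
                     stringsAsFactors = FALSE)
  audit <- data.frame(snp = common, action = action,
                      stringsAsFactors = FALSE)
  methods::new("HarmonizedSet",
               exposureLabel = exposure@traitLabel,
               outcomeLabel = outcome@traitLabel,
               data = data, audit = audit,
               palindromePolicy = palindromePolicy)
}

## internal: build a HarmonizedSet directly from aligned vectors (used by
## the simulator helpers and tests)
.harmonizedSet <- function(snp, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = rep(NA_real_, length(snp)),
                           exposureLabel = "exposure",
                           outcomeLabel = "outcome") {
  methods::new("HarmonizedSet",
    exposureLabel = exposureLabel, outcomeLabel = outcomeLabel,
    data = data.frame(snp = as.character(snp), beta_exp = beta_exp,
                      se_exp = se_exp, beta_out = beta_out, se_out = se_out,
                      eaf_exp = eaf_exp, stringsAsFactors = FALSE),
    audit = data.frame(snp = as.character(snp), action = "kept",
                       stringsAsFactors = FALSE),
    palindromePolicy = "drop_all")
}

#' Assemble a HarmonizedSet from aligned effect vectors
#'
#' Convenience constructor for effects that are already expressed on a
#' common effect allele (e.g. simulator output or published tables).
#'
#' @param snp SNP ids.
#' @param beta_exp,se_exp,beta_out,se_out Aligned effects and SEs.
#' @param eaf_exp Effect-allele frequencies (optional, NA allowed).
#' @param exposureLabel,outcomeLabel Trait names.
#' @return A [HarmonizedSet-class] with every SNP audited as "kept".
#' @export
harmonizedSet <- function(snp, beta_exp, se_exp, beta_out, se_out,
                          eaf_exp = rep(NA_real_, length(snp)),
                          exposureLabel = "exposure",
                          outcomeLabel = "outcome") {
  .harmonizedSet(snp, beta_exp, se_exp, beta_out, se_out, eaf_exp,
                 exposureLabel, outcomeLabel)
}
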