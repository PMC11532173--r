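Package: mrkit
Title: Two-Sample Univariable and Multivariable Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization with GWAS summary
    statistics on binary traits: instrument selection (genome-wide
    significance, F statistics, LD clumping, outcome-association exclusion),
    allele harmonization with palindromic-variant handling, five univariable
    estimators (inverse-variance weighted, MR-Egger, weighted median, simple
    and weighted mode), multivariable MR for direct effects under named
    adjustment models, a sensitivity battery (Cochran's Q, Egger intercept,
    MR-PRESSO, radial MR, leave-one-out, Steiger directionality, power), and
    random-effects meta-analysis of causal estimates across outcome stages.
    Includes a summary-level simulator of correlated binary-trait GWAS with
    known causal structure for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, yaml, jsonlite
Suggests: testthat (>= 3.0.0), metafor, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'gwas-io.R'
    'harmonize.R'
    'instruments.R'
    'meta.R'
    'methods.R'
    'mrkit-package.R'
    'uvmr.R'
    'mvmr.R'
    'sensitivity.R'
    'pipeline.R'
    'presso.R'
    'radial.R'
    'simulate.R'
    'utils.R'
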