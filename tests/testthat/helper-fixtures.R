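# Small deterministic fixtures built in code.

# a GwasTable from minimal vectors, filling the rest with valid defaults
makeTable <- function(snp, beta, se, pval = NULL, ea = NULL, oa = NULL,
                      eaf = NULL, n_total = 10000, n_cases = 1000,
                      chrom = NA, pos = NA, label = "trait") {
  k <- length(snp)
  if (is.null(pval)) pval <- pmax(2 * pnorm(-abs(beta / se)), 1e-300)
  if (is.null(ea)) ea <- rep("A", k)
  if (is.null(oa)) oa <- rep("G", k)
  if (is.null(eaf)) eaf <- rep(0.3, k)
  gwasTable(data.frame(snp = snp, effect_allele = ea, other_allele = oa,
                       eaf = eaf, beta = beta, se = se, pval = pval,
                       n_cases = n_cases, n_total = n_total,
                       chrom = chrom, pos = pos,
                       stringsAsFactors = FALSE), traitLabel = label)
}

# a random harmonized set with known generating slope
randomSet <- function(k, beta = 0.2, seed = 1, se_out = 0.05,
                      se_exp = 0.01, intercept = 0) {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); expr
  }
  withr_seed({
    bx <- runif(k, 0.05, 0.3)
    sy <- rep_len(se_out, k) * runif(k, 0.5, 1.5)
    by <- intercept + beta * bx + rnorm(k, 0, sy)
    harmonizedSet(sprintf("rs%03d", seq_len(k)), bx,
                  rep_len(se_exp, k), by, sy,
                  eaf_exp = runif(k, 0.1, 0.9))
  })
}
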