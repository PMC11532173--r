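## Internal helpers shared across modules.

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## normal-approximation estimate container
.newEstimate <- function(method, beta, se, nsnp, extras = list(),
                         reference = c("normal", "t"), df = NA_real_) {
  reference <- match.arg(reference)
  crit <- if (reference == "t") stats::qt(0.975, df) else stats::qnorm(0.975)
  pval <- if (reference == "t") 2 * stats::pt(-abs(beta / se), df)
          else 2 * stats::pnorm(-abs(beta / se))
  lo <- beta - crit * se
  hi <- beta + crit * se
  methods::new("MREstimate", method = method, beta = beta, se = se,
               ciLow = lo, ciHigh = hi, pval = pval,
               orValue = exp(beta), orCiLow = exp(lo), orCiHigh = exp(hi),
               nsnp = as.integer(nsnp),
               extras = c(extras, list(reference = reference)))
}

## reverse complement of allele codes
.revComp <- function(a) {
  map <- c(A = "T", C = "G", G = "C", T = "A")
  unname(map[a])
}

.checkSeed <- function(seed) {
  if (is.null(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    .stopf("a single integer 'seed' is required for reproducibility")
  as.integer(seed)
}

## run expr with a private RNG stream, restoring the caller's state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
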