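#' @include AllClasses.R gwas-io.R harmonize.R mvmr.R
NULL

#' Scenario presets for the summary-statistics simulator
#'
#' Returns a fully specified simulation configuration emulating the
#' structure of large biobank case-control GWAS of correlated autoimmune
#' binary traits: per-exposure instrument blocks with effects on the
#' log-odds scale, acyclic structural edges between traits, configurable
#' horizontal pleiotropy, and block-diagonal LD.
#'
#' Scenarios:
#' \describe{
#'   \item{clean}{One exposure (30 instruments, biobank-scale
#'     case-control counts), one outcome, no pleiotropy, no palindromes.
#'     \code{beta} sets the causal effect (default 0: the null).}
#'   \item{balanced_pleiotropy}{As clean, plus mean-zero normal direct
#'     outcome effects on every instrument (InSIDE holds).}
#'   \item{directional_pleiotropy}{50 instruments in a large balanced
#'     case-control design; 48 percent of instruments receive a constant
#'     positive direct outcome effect. The regime where the weighted
#'     median's 50-percent breakdown property is visible.}
#'   \item{outlier_spike}{As clean with \code{beta = 0.2}; 2 of 30
#'     instruments receive direct outcome effects of 10 outcome-SE.}
#'   \item{mediation_gd_tos}{Two exposures: an upstream autoimmune cause
#'     (15 instruments) with a structural edge (0.5) onto a downstream
#'     exposure (15 own instruments, so 30 total) and a direct outcome
#'     effect (0.3); the downstream exposure has no direct outcome
#'     effect. UVMR shows a total effect for both; MVMR attributes the
#'     effect to the upstream cause.}
#'   \item{confounding_ra}{A confounder trait (40 instruments) with
#'     edges onto both the exposure (0.3) and the outcome (0.3); the
#'     exposure itself has no direct effect.}
#'   \item{study}{Three correlated exposures (30/160/15 instruments, one
#'     downstream of another), a shared confounder (40), and four outcome
#'     stages -- the full grid layout for pipeline runs.}
#' }
#'
#' @param name Scenario name (see above).
#' @param beta Causal exposure-outcome effect for scenarios that expose
#'   it (clean, balanced_pleiotropy, outlier_spike; default depends on
#'   the scenario).
#' @param seed Seed stored in the config (default 1).
#' @return A simulation config (list) for [simulateTwoSample()], with
#'   every parameter documented in place.
#' @export
simScenario <- function(name = c("clean", "balanced_pleiotropy",
                                 "directional_pleiotropy", "outlier_spike",
                                 "mediation_gd_tos", "confounding_ra",
                                 "study"),
                        beta = NULL, seed = 1L) {
  name <- match.arg(name)
  ## biobank-scale trait designs: case counts mirror large registry
  ## endpoints for thyrotoxicosis / hypothyroidism / Graves disease /
  ## rheumatoid arthritis exposures and retinopathy-stage outcomes
  TOS <- list(label = "TOS_like", n_cases = 8173, n_total = 270000,
              n_snps = 30, target_r2 = 0.4)
  HPT <- list(label = "HPT_like", n_cases = 40926, n_total = 270000,
              n_snps = 160, target_r2 = 0.8)
  GD <- list(label = "GD_like", n_cases = 2836, n_total = 270000,
             n_snps = 15, target_r2 = 0.5)
  RA <- list(label = "RA_like", n_cases = 12555, n_total = 270000,
             n_snps = 40, target_r2 = 0.6)
  DR <- list(label = "DR_like", n_cases = 10413, n_total = 210000)
  DBR <- list(label = "DBR_like", n_cases = 3098, n_total = 190000)
  NPDR <- list(label = "NPDR_like", n_cases = 672, n_total = 190000)
  PDR <- list(label = "PDR_like", n_cases = 9511, n_total = 210000)

  base <- list(name = name, seed = as.integer(seed),
               af = c(0.05, 0.95), effect_cv = 0.25,
               palindrome_rate = 0,
               ld = list(block_size = 1L, r2_within = 0),
               pleiotropy = list(type = "none"))
  cfg <- switch(name,
    clean = {
      b <- if (is.null(beta)) 0 else beta
      c(base, list(exposures = list(TOS), outcomes = list(DR),
                   edges = list(list(from = "TOS_like", to = "DR_like",
                                     beta = b))))
    },
    balanced_pleiotropy = {
      b <- if (is.null(beta)) 0 else beta
      out <- c(base, list(exposures = list(TOS), outcomes = list(DR),
                          edges = list(list(from = "TOS_like",
                                            to = "DR_like", beta = b))))
      out$pleiotropy <- list(type = "balanced", sd = 0.02,
                             exposure = "TOS_like")
      out
    },
    directional_pleiotropy = {
      b <- if (is.null(beta)) 0.2 else beta
      bigX <- list(label = "EXP_big", n_cases = 250000, n_total = 500000,
                   n_snps = 50, target_r2 = 1.2)
      bigY <- list(label = "OUT_big", n_cases = 250000, n_total = 500000)
      out <- c(base, list(exposures = list(bigX), outcomes = list(bigY),
                          edges = list(list(from = "EXP_big",
                                            to = "OUT_big", beta = b))))
      ## near-equal frequencies and effect sizes keep instrument weights
      ## homogeneous, so the invalid half never outweighs the valid half
      ## and the median's 50-percent breakdown bound is visible
      out$af <- c(0.45, 0.55)
      out$effect_cv <- 0.05
      out$pleiotropy <- list(type = "directional", fraction = 0.48,
                             size = 0.125, exposure = "EXP_big")
      out
    },
    outlier_spike = {
      b <- if (is.null(beta)) 0.2 else beta
      out <- c(base, list(exposures = list(TOS), outcomes = list(DR),
                          edges = list(list(from = "TOS_like",
                                            to = "DR_like", beta = b))))
      out$pleiotropy <- list(type = "spike_in", k = 2L, size = 10,
                             exposure = "TOS_like")
      out
    },
    mediation_gd_tos = {
      ## strong upstream instruments keep the exposure columns well
      ## measured, so the downstream direct effect is cleanly identified
      GDm <- GD; GDm$target_r2 <- 1.0
      c(base, list(
        exposures = list(GDm, c(TOS["label"], TOS["n_cases"],
                                TOS["n_total"],
                                list(n_snps = 15, target_r2 = 0.3))),
        outcomes = list(DR),
        edges = list(
          list(from = "GD_like", to = "TOS_like", beta = 0.4),
          list(from = "GD_like", to = "DR_like", beta = 0.25),
          list(from = "TOS_like", to = "DR_like", beta = 0))))
    },
    confounding_ra = {
      c(base, list(
        exposures = list(RA, c(HPT["label"], HPT["n_cases"],
                               HPT["n_total"],
                               list(n_snps = 30, target_r2 = 0.2))),
        outcomes = list(DR),
        edges = list(
          list(from = "RA_like", to = "HPT_like", beta = 0.3),
          list(from = "RA_like", to = "DR_like", beta = 0.3),
          list(from = "HPT_like", to = "DR_like", beta = 0))))
    },
    study = {
      out <- c(base, list(
        exposures = list(GD,
                         c(TOS["label"], TOS["n_cases"], TOS["n_total"],
                           list(n_snps = 15, target_r2 = 0.3)),
                         HPT, RA),
        outcomes = list(DR, DBR, NPDR, PDR),
        edges = list(list(from = "GD_like", to = "TOS_like", beta = 0.5))))
      for (y in c("DR_like", "DBR_like", "NPDR_like", "PDR_like")) {
        out$edges <- c(out$edges, list(
          list(from = "GD_like", to = y, beta = 0.2),
          list(from = "HPT_like", to = y, beta = 0.15),
          list(from = "RA_like", to = y, beta = 0.1),
          list(from = "TOS_like", to = y, beta = 0)))
      }
      out$palindrome_rate <- 0.05
      out
    })
  cfg
}

.edgeMatrix <- function(cfg) {
  labs <- c(vapply(cfg$exposures, `[[`, character(1), "label"),
            vapply(cfg$outcomes, `[[`, character(1), "label"))
  E <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
  for (e in cfg$edges) {
    if (!e$from %in% labs || !e$to %in% labs)
      .stopf("edge references unknown trait '%s' or '%s'", e$from, e$to)
    E[e$from, e$to] <- e$beta
  }
  ## acyclicity: traits are processed in declaration order, so every edge
  ## must point forward
  idx <- stats::setNames(seq_along(labs), labs)
  for (e in cfg$edges)
    if (idx[e$from] >= idx[e$to])
      .stopf("edges must be acyclic and forward in trait order (%s -> %s)",
             e$from, e$to)
  E
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates summary statistics directly at the summary level: each
#' exposure's instrument block receives true per-allele effects on the
#' log-odds scale (random sign; magnitudes normal around a mean chosen so
#' the block's expected \eqn{\sum 2p(1-p)\beta^2} hits the configured
#' target), trait effects propagate along the declared acyclic structural
#' edges, outcome effects are formed as causal effect times true exposure
#' effect plus structural-path and pleiotropic contributions, and observed
#' betas add independent sampling noise with the case-control
#' approximation \eqn{se = 1/\sqrt{2p(1-p)\,n\,K(1-K)}} (K the trait's
#' case fraction). Exposure and outcome samples are independent (strict
#' two-sample design). The emitted LD matrix equals the configured block
#' structure exactly.
#'
#' @param cfg Config from [simScenario()] (fields may be edited before
#'   the call).
#' @param seed Overrides \code{cfg$seed} when given. Mandatory one way or
#'   the other; the same seed gives bit-identical output.
#' @return List with elements \code{tables} (named list of
#'   [GwasTable-class], one per trait), \code{ld} (r-squared matrix over
#'   the whole SNP panel), and \code{truth} (list: per-trait true effect
#'   vectors, instrument ids per trait, pleiotropic SNPs and their direct
#'   effects, the edge matrix, per-SNP variance explained, per-trait SEs
#'   and case fractions).
#' @export
simulateTwoSample <- function(cfg, seed = NULL) {
  seed <- .checkSeed(if (is.null(seed)) cfg$seed else seed)
  E <- .edgeMatrix(cfg)
  exposures <- cfg$exposures
  outcomes <- cfg$outcomes
  nSnpsPer <- vapply(exposures, `[[`, numeric(1), "n_snps")
  M <- sum(nSnpsPer)
  blockOf <- rep(seq_along(exposures), nSnpsPer)

  .withSeed(seed, {
    snp <- sprintf("rs%05d", seq_len(M))
    eaf <- stats::runif(M, cfg$af[1], cfg$af[2])

    ## positions: LD blocks are adjacent; independent blocks far apart
    ldBlockSize <- max(1L, as.integer(cfg$ld$block_size))
    ldBlock <- ceiling(seq_len(M) / ldBlockSize)
    chrom <- ((ldBlock - 1L) %% 22L) + 1L
    pos <- 1e6 + ((ldBlock - 1L) %/% 22L) * 2e7 +
      (seq_len(M) - (ldBlock - 1L) * ldBlockSize - 1L) * 1000
    ld <- diag(1, M)
    dimnames(ld) <- list(snp, snp)
    if (cfg$ld$r2_within > 0 && ldBlockSize > 1L)
      for (b in unique(ldBlock)) {
        i <- which(ldBlock == b)
        ld[i, i] <- cfg$ld$r2_within
        ld[cbind(i, i)] <- 1
      }

    ## alleles; a configurable fraction palindromic
    nonPal <- list(c("A", "C"), c("A", "G"), c("T", "C"), c("T", "G"))
    pal <- list(c("A", "T"), c("C", "G"))
    isPal <- stats::runif(M) < cfg$palindrome_rate
    pair <- lapply(seq_len(M), function(i)
      if (isPal[i]) pal[[sample.int(2, 1)]]
      else nonPal[[sample.int(4, 1)]])
    ea <- vapply(pair, `[`, character(1), 1)
    oa <- vapply(pair, `[`, character(1), 2)

    ## own (direct) instrument effects per exposure block
    own <- matrix(0, M, length(exposures))
    cv <- cfg$effect_cv
    for (j in seq_along(exposures)) {
      i <- which(blockOf == j)
      tpq <- 2 * eaf[i] * (1 - eaf[i])
      mu <- sqrt(exposures[[j]]$target_r2 / ((1 + cv^2) * sum(tpq)))
      mag <- abs(stats::rnorm(length(i), mu, cv * mu))
      own[i, j] <- sample(c(-1, 1), length(i), replace = TRUE) * mag
    }

    ## propagate along structural edges in declaration order
    labs <- colnames(E)
    nX <- length(exposures)
    eff <- matrix(0, M, length(labs), dimnames = list(snp, labs))
    for (j in seq_len(nX)) {
      eff[, j] <- own[, j]
      up <- which(E[, j] != 0)
      for (u in up) eff[, j] <- eff[, j] + E[u, j] * eff[, u]
    }

    ## pleiotropy: direct outcome effects for instruments of one exposure
    pl <- cfg$pleiotropy
    pleio <- numeric(M)
    pleioIds <- character(0)
    plBlock <- if (!is.null(pl$exposure))
      which(vapply(exposures, `[[`, character(1), "label") == pl$exposure)
    else 1L
    target <- which(blockOf == plBlock)
    if (pl$type == "balanced") {
      pleio[target] <- stats::rnorm(length(target), 0, pl$sd)
      pleioIds <- snp[target]
    } else if (pl$type == "directional") {
      ## positive direct effects in the exposure-increasing orientation,
      ## the frame in which unbalanced pleiotropy shifts ratio estimates
      kPl <- round(pl$fraction * length(target))
      pick <- sample(target, kPl)
      pleio[pick] <- pl$size * sign(own[pick, plBlock])
      pleioIds <- snp[sort(pick)]
    } else if (pl$type == "spike_in") {
      pick <- sample(target, pl$k)
      pleioIds <- snp[sort(pick)]
    }

    ## per-trait sampling SEs and observed tables
    tables <- list()
    seMat <- matrix(NA_real_, M, length(labs), dimnames = list(snp, labs))
    caseFrac <- numeric(length(labs))
    names(caseFrac) <- labs
    allTraits <- c(exposures, outcomes)
    for (t in seq_along(labs)) {
      tr <- allTraits[[t]]
      K <- tr$n_cases / tr$n_total
      caseFrac[t] <- K
      seMat[, t] <- 1 / sqrt(2 * eaf * (1 - eaf) * tr$n_total * K * (1 - K))
      if (t > nX) {  # outcome: structural contributions + pleiotropy
        for (u in seq_len(nX))
          if (E[u, t] != 0) eff[, t] <- eff[, t] + E[u, t] * eff[, u]
        eff[, t] <- eff[, t] + pleio
        if (pl$type == "spike_in") {
          pick <- match(pleioIds, snp)
          eff[pick, t] <- eff[pick, t] + pl$size * seMat[pick, t]
        }
      }
      bhat <- eff[, t] + stats::rnorm(M, 0, seMat[, t])
      pv <- pmax(2 * stats::pnorm(-abs(bhat / seMat[, t])),
                 .Machine$double.xmin)
      tables[[labs[t]]] <- gwasTable(data.frame(
        snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
        beta = bhat, se = seMat[, t], pval = pv,
        n_cases = tr$n_cases, n_total = tr$n_total,
        chrom = chrom, pos = pos, stringsAsFactors = FALSE),
        traitLabel = labs[t])
    }

    ## instruments of a trait: every SNP with a nonzero true effect on it
    instruments <- lapply(seq_len(nX), function(j) snp[eff[, j] != 0])
    names(instruments) <- labs[seq_len(nX)]

    truth <- list(edges = E, effects = eff,
                  instruments = instruments,
                  pleiotropic_snps = pleioIds,
                  pleiotropy = pl,
                  se = seMat, case_fraction = caseFrac,
                  r2_per_snp = 2 * eaf * (1 - eaf) * eff^2,
                  eaf = eaf, ld = ld, seed = seed,
                  se_model = "1/sqrt(2p(1-p) n K(1-K)), logistic variance factor")
    list(tables = tables, ld = ld, truth = truth)
  })
}

#' Harmonized set of a simulated pair using the true instrument list
#'
#' Convenience for calibration studies: pairs the simulated exposure and
#' outcome tables restricted to the exposure's true instruments (every
#' SNP with a nonzero true effect on it), bypassing significance
#' selection so the instrument count is exactly as configured.
#'
#' @param sim Output of [simulateTwoSample()].
#' @param exposure,outcome Trait labels.
#' @return A [HarmonizedSet-class].
#' @export
simHarmonized <- function(sim, exposure, outcome) {
  ids <- sim$truth$instruments[[exposure]]
  e <- sim$tables[[exposure]]@records
  o <- sim$tables[[outcome]]@records
  i <- match(ids, e$snp)
  j <- match(ids, o$snp)
  .harmonizedSet(ids, e$beta[i], e$se[i], o$beta[j], o$se[j],
                 eaf_exp = e$eaf[i],
                 exposureLabel = exposure, outcomeLabel = outcome)
}

#' Multi-exposure harmonized set from a simulation's truth
#'
#' Union of the named exposures' true instruments, aligned (the simulator
#' emits everything on a common effect allele already).
#'
#' @param sim Output of [simulateTwoSample()].
#' @param exposures Character vector of exposure labels.
#' @param outcome Outcome label.
#' @return A [MultiHarmonizedSet-class].
#' @export
simMvmrSet <- function(sim, exposures, outcome) {
  ids <- sort(unique(unlist(sim$truth$instruments[exposures])))
  bx <- sapply(exposures, function(e)
    sim$tables[[e]]@records$beta[match(ids, sim$tables[[e]]@records$snp)])
  sx <- sapply(exposures, function(e)
    sim$tables[[e]]@records$se[match(ids, sim$tables[[e]]@records$snp)])
  o <- sim$tables[[outcome]]@records
  j <- match(ids, o$snp)
  multiHarmonizedSet(ids, as.matrix(bx), as.matrix(sx),
                     o$beta[j], o$se[j], outcomeLabel = outcome)
}

#' Materialize scenario fixtures on disk
#'
#' Writes, for each requested scenario, the per-trait summary-statistic
#' TSVs (standard dialect), the LD matrix, and a truth JSON under
#' \code{dir/<scenario>/}.
#'
#' @param dir Output directory (created if needed).
#' @param scenarios Scenario names (default: all).
#' @param seed Simulation seed.
#' @return Invisibly, the paths written.
#' @export
writeScenarioFixtures <- function(dir,
                                  scenarios = c("clean",
                                                "balanced_pleiotropy",
                                                "directional_pleiotropy",
                                                "outlier_spike",
                                                "mediation_gd_tos",
                                                "confounding_ra"),
                                  seed = 1L) {
  paths <- character(0)
  for (sc in scenarios) {
    sim <- simulateTwoSample(simScenario(sc, seed = seed))
    d <- file.path(dir, sc)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    for (lab in names(sim$tables)) {
      p <- file.path(d, paste0(lab, ".tsv"))
      writeGwas(sim$tables[[lab]], p)
      paths <- c(paths, p)
    }
    ldPath <- file.path(d, "ld.tsv")
    utils::write.table(sim$ld, ldPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    truth <- sim$truth
    truth$ld <- NULL
    jsonlite::write_json(truth, file.path(d, "truth.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    paths <- c(paths, ldPath, file.path(d, "truth.json"))
  }
  invisible(paths)
}
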