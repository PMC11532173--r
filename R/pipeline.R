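#' @include AllClasses.R instruments.R uvmr.R mvmr.R sensitivity.R meta.R
NULL

#' Assemble a study configuration
#'
#' Bundles the trait registry, the exposure/outcome grid, the MVMR
#' adjustment models, thresholds and seeds for [runStudy()] and friends.
#'
#' @param traits Named list of [GwasTable-class] objects or file paths
#'   (paths are read with [readGwas()]).
#' @param exposures,outcomes Trait names forming the UVMR grid.
#' @param ld LD r-squared matrix (or a path readable by
#'   [readLDMatrix()]).
#' @param models MVMR model specs: each a list with \code{name},
#'   \code{exposure}, \code{adjust_for} (character vector) and optional
#'   \code{outcomes} (default: all configured outcomes).
#' @param thresholds Instrument-selection thresholds; defaults
#'   p_exposure = p_outcome = 5e-8, r2_clump = 0.01, kb_clump = 5000,
#'   f_min = 10.
#' @param nTests Number of MR tests for the Bonferroni-adjusted
#'   significance threshold 0.05/nTests (default 2, i.e. 0.025).
#' @param seed Base RNG seed; per-pair seeds are derived from it.
#' @param pressoNSim MR-PRESSO simulated datasets (default 5000).
#' @param removeOutliers Remove the union of MR-PRESSO and radial-MR
#'   outliers before final estimation (default TRUE).
#' @param estimators Methods reported in the UVMR grid.
#' @param outDir Optional output directory for TSV/JSON fragments.
#' @return A validated config list of class \code{mrStudyConfig}.
#' @export
studyConfig <- function(traits, exposures, outcomes, ld, models = list(),
                        thresholds = list(), nTests = 2, seed = 1L,
                        pressoNSim = 5000, removeOutliers = TRUE,
                        estimators = c("IVW", "MR-Egger",
                                       "WeightedMedian"),
                        outDir = NULL) {
  if (nTests < 1) .stopf("nTests must be >= 1")
  traits <- lapply(traits, function(x)
    if (methods::is(x, "GwasTable")) x else readGwas(x))
  if (is.null(names(traits)) || any(!nzchar(names(traits))))
    names(traits) <- vapply(traits, traitLabel, character(1))
  for (nm in c(exposures, outcomes))
    if (!nm %in% names(traits))
      .stopf("trait '%s' not in the registry", nm)
  for (m in models) {
    for (nm in c(m$exposure, m$adjust_for, m$outcomes))
      if (!nm %in% names(traits) && !nm %in% outcomes)
        .stopf("model '%s' references unregistered trait '%s'",
               m$name, nm)
  }
  th <- utils::modifyList(list(p_exposure = 5e-8, p_outcome = 5e-8,
                               r2_clump = 0.01, kb_clump = 5000,
                               f_min = 10), thresholds)
  if (is.character(ld)) ld <- readLDMatrix(ld)
  structure(list(traits = traits, exposures = exposures,
                 outcomes = outcomes, ld = ldMatrix(ld), models = models,
                 thresholds = th, nTests = nTests,
                 alpha = 0.05 / nTests, seed = .checkSeed(seed),
                 pressoNSim = pressoNSim,
                 removeOutliers = isTRUE(removeOutliers),
                 estimators = estimators, outDir = outDir),
            class = "mrStudyConfig")
}

#' Read a study configuration from YAML
#'
#' Expects top-level keys \code{traits} (label -> path), \code{exposures},
#' \code{outcomes}, \code{ld} (path), and optionally \code{models},
#' \code{thresholds}, \code{n_tests}, \code{seed}, \code{out_dir}.
#' Relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return An \code{mrStudyConfig} (see [studyConfig()]).
#' @export
readStudyConfig <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  traits <- lapply(y$traits, resolve)
  studyConfig(traits = traits,
              exposures = unlist(y$exposures),
              outcomes = unlist(y$outcomes),
              ld = resolve(y$ld),
              models = if (is.null(y$models)) list() else y$models,
              thresholds = if (is.null(y$thresholds)) list()
                           else y$thresholds,
              nTests = if (is.null(y$n_tests)) 2 else y$n_tests,
              seed = if (is.null(y$seed)) 1L else y$seed,
              outDir = y$out_dir)
}

.pairSeed <- function(cfg, i) (cfg$seed + 1000L * i) %% .Machine$integer.max

#' Run the univariable MR grid
#'
#' For every exposure-outcome pair: instrument selection, harmonization,
#' the sensitivity battery, optional removal of MR-PRESSO/radial-MR
#' outliers, the configured estimators, and a significance verdict at the
#' Bonferroni-adjusted threshold 0.05/nTests. A failing pair is recorded
#' and the grid continues.
#'
#' @param cfg An \code{mrStudyConfig}.
#' @return List with \code{estimates} (tidy grid data.frame including a
#'   \code{significant} column), \code{sensitivity} (per-pair diagnostic
#'   lists), \code{log} (per-pair stage counts and removed outliers) and
#'   \code{errors} (named condition messages).
#' @export
runUvmrGrid <- function(cfg) {
  stopifnot(inherits(cfg, "mrStudyConfig"))
  th <- cfg$thresholds
  rows <- list()
  sens <- list()
  logs <- list()
  errors <- list()
  i <- 0L
  for (e in cfg$exposures) for (y in cfg$outcomes) {
    i <- i + 1L
    key <- paste(e, y, sep = " -> ")
    res <- tryCatch({
      inst <- selectInstruments(cfg$traits[[e]], cfg$traits[[y]], cfg$ld,
                                pExposure = th$p_exposure,
                                pOutcome = th$p_outcome,
                                r2Max = th$r2_clump,
                                windowKb = th$kb_clump, fMin = th$f_min)
      h <- harmonize(inst@table, cfg$traits[[y]])
      pairSeed <- .pairSeed(cfg, i)
      nExp <- max(cfg$traits[[e]]@records$n_total, na.rm = TRUE)
      nOut <- max(cfg$traits[[y]]@records$n_total, na.rm = TRUE)
      kOut <- suppressWarnings(
        max(cfg$traits[[y]]@records$n_cases, na.rm = TRUE))
      battery <- sensitivityBattery(h, nSim = cfg$pressoNSim,
                                    seed = pairSeed,
                                    nExp = nExp, nOut = nOut,
                                    caseFractionOut =
                                      if (is.finite(kOut)) kOut / nOut
                                      else NULL)
      removed <- character(0)
      if (cfg$removeOutliers) {
        removed <- union(
          if (!is.null(battery$presso)) outlierIds(battery$presso)
          else character(0),
          outlierIds(battery$radial))
        if (length(removed) && length(removed) < nSnps(h) - 2) {
          keep <- !(h@data$snp %in% removed)
          h@data <- h@data[keep, , drop = FALSE]
          h@audit <- h@audit[h@audit$snp %in% h@data$snp, , drop = FALSE]
        }
      }
      tab <- mrEstimateTable(h, estimators = cfg$estimators,
                             seed = pairSeed)
      tab$significant <- tab$pval < cfg$alpha
      list(tab = tab, battery = battery,
           log = list(instrument_audit = table(inst@audit$action),
                      f_stat = inst@fStat, r2 = inst@r2Total,
                      harmonize_audit = table(auditTrail(h)$action),
                      outliers_removed = removed,
                      n_final = nSnps(h), seed = pairSeed))
    }, error = function(cond) cond)
    if (inherits(res, "condition")) {
      errors[[key]] <- conditionMessage(res)
    } else {
      rows[[key]] <- res$tab
      sens[[key]] <- res$battery
      logs[[key]] <- res$log
    }
  }
  list(estimates = if (length(rows)) do.call(rbind, c(rows,
         list(make.row.names = FALSE))) else NULL,
       sensitivity = sens, log = logs, errors = errors)
}

#' Run the configured MVMR adjustment models
#'
#' Per model and outcome: instrument union + joint clumping via
#' [buildMvmrSet()], then [mvmrIVW()] and [mvmrEgger()], with direct
#' effects judged at the Bonferroni-adjusted threshold.
#'
#' @param cfg An \code{mrStudyConfig} with non-empty \code{models}.
#' @return List with \code{estimates} (tidy data.frame: model, outcome,
#'   method, per-exposure rows) and \code{errors}.
#' @export
runMvmrModels <- function(cfg) {
  stopifnot(inherits(cfg, "mrStudyConfig"))
  th <- cfg$thresholds
  rows <- list()
  errors <- list()
  for (m in cfg$models) {
    outs <- if (is.null(m$outcomes)) cfg$outcomes else m$outcomes
    exps <- c(m$exposure, m$adjust_for)
    for (y in outs) {
      key <- paste(m$name, y, sep = " / ")
      res <- tryCatch({
        set <- buildMvmrSet(cfg$traits[exps], cfg$traits[[y]], cfg$ld,
                            pExposure = th$p_exposure,
                            r2Max = th$r2_clump,
                            windowKb = th$kb_clump)
        lab <- paste0(m$exposure, " adjusted for ",
                      paste(m$adjust_for, collapse = ", "))
        ivw <- mvmrIVW(set, modelLabel = lab)
        egg <- mvmrEgger(set, modelLabel = lab)
        rbind(cbind(outcome = y, as.data.frame(ivw)),
              cbind(outcome = y, as.data.frame(egg)))
      }, error = function(cond) cond)
      if (inherits(res, "condition"))
        errors[[key]] <- conditionMessage(res)
      else {
        res$significant <- res$pval < cfg$alpha
        rows[[key]] <- res
      }
    }
  }
  list(estimates = if (length(rows)) do.call(rbind, c(rows,
         list(make.row.names = FALSE))) else NULL,
       errors = errors)
}

#' Pool the UVMR grid by exposure subgroup
#'
#' Takes the IVW rows of a [runUvmrGrid()] fragment and pools the log-ORs
#' across outcome stages with a random-effects model, per exposure
#' subgroup and overall, emitting forest-plot data alongside.
#'
#' @param cfg An \code{mrStudyConfig}.
#' @param uvmr Fragment returned by [runUvmrGrid()].
#' @param model Pooling model (default random-effects REML).
#' @return List with \code{pooled} ([MetaResult-class] with subgroups)
#'   and \code{forest} (data.frame).
#' @export
runMeta <- function(cfg, uvmr,
                    model = c("random_REML", "random_DL", "fixed")) {
  model <- match.arg(model)
  est <- uvmr$estimates
  ivw <- est[est$method == "IVW", , drop = FALSE]
  missing <- setdiff(as.vector(outer(cfg$exposures, cfg$outcomes,
                                     paste, sep = " -> ")),
                     paste(ivw$exposure, ivw$outcome, sep = " -> "))
  if (length(missing))
    .stopf("no IVW rows for: %s", paste(missing, collapse = "; "))
  rows <- metaInput(paste(ivw$exposure, ivw$outcome, sep = "-"),
                    logOr = ivw$beta, se = ivw$se,
                    subgroup = ivw$exposure)
  pooled <- subgroupMeta(rows, model = model)
  list(pooled = pooled, forest = forestData(rows, model = model))
}

#' Run the complete study workflow
#'
#' UVMR grid, MVMR models, meta-analysis, and a run manifest; optionally
#' writes the fragments (TSV/JSON) under \code{cfg$outDir}.
#'
#' @param cfg An \code{mrStudyConfig}.
#' @return List of class \code{mrStudyReport}: \code{uvmr}, \code{mvmr},
#'   \code{meta}, \code{manifest}, \code{status} (0 clean, 2 when any
#'   pair failed).
#' @export
runStudy <- function(cfg) {
  stopifnot(inherits(cfg, "mrStudyConfig"))
  uvmr <- runUvmrGrid(cfg)
  mvmr <- if (length(cfg$models)) runMvmrModels(cfg)
          else list(estimates = NULL, errors = list())
  meta <- if (!is.null(uvmr$estimates) &&
              length(uvmr$errors) == 0) runMeta(cfg, uvmr) else NULL
  manifest <- list(seed = cfg$seed, thresholds = cfg$thresholds,
                   n_tests = cfg$nTests, alpha = cfg$alpha,
                   presso_n_sim = cfg$pressoNSim,
                   remove_outliers = cfg$removeOutliers,
                   estimators = cfg$estimators,
                   package_version =
                     as.character(utils::packageVersion("mrkit")))
  status <- if (length(uvmr$errors) || length(mvmr$errors)) 2L else 0L
  report <- structure(list(uvmr = uvmr, mvmr = mvmr, meta = meta,
                           manifest = manifest, status = status),
                      class = "mrStudyReport")
  if (!is.null(cfg$outDir)) writeStudyReport(report, cfg$outDir)
  report
}

#' Write a study report's fragments to disk
#'
#' @param report An \code{mrStudyReport} from [runStudy()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  wtsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(report$uvmr$estimates))
    wtsv(report$uvmr$estimates, "uvmr.tsv")
  if (!is.null(report$mvmr$estimates))
    wtsv(report$mvmr$estimates, "mvmr.tsv")
  if (!is.null(report$meta)) {
    wtsv(report$meta$forest, "forest.tsv")
    p <- file.path(dir, "meta.json")
    pooled <- report$meta$pooled
    jsonlite::write_json(list(
      overall = as.data.frame(pooled),
      subgroups = lapply(pooled@subgroups, as.data.frame)),
      p, auto_unbox = TRUE, digits = NA, dataframe = "rows")
    paths <- c(paths, p)
  }
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(c(report$manifest,
                         list(errors = c(names(report$uvmr$errors),
                                         names(report$mvmr$errors)),
                              status = report$status)),
                       p, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, p))
}
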