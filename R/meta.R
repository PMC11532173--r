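#' @include AllClasses.R
NULL

#' Standard error of a log odds ratio from its 95 percent CI
#'
#' Assumes the interval is a symmetric normal 95 percent CI on the log
#' scale, as printed in standard MR result tables:
#' \eqn{se = (\ln CI_{high} - \ln CI_{low}) / (2 \times 1.959964)}.
#'
#' @param orValue Odds ratio.
#' @param ciLow,ciHigh 95 percent bounds, with
#'   \code{0 < ciLow <= orValue <= ciHigh}.
#' @return Standard error of the log odds ratio.
#' @examples
#' seFromCI(1.10, 1.05, 1.15)   # about 0.0232
#' @export
seFromCI <- function(orValue, ciLow, ciHigh) {
  if (any(ciLow <= 0 | ciLow > orValue | ciHigh < orValue))
    .stopf("need 0 < ciLow <= orValue <= ciHigh")
  if (any(ciLow == ciHigh))
    .stopf("degenerate interval: ciLow equals ciHigh")
  (log(ciHigh) - log(ciLow)) / (2 * stats::qnorm(0.975))
}

#' Assemble meta-analysis input rows
#'
#' Accepts either log-OR + SE directly, or OR with its 95 percent CI
#' (converted via [seFromCI()]).
#'
#' @param label Row labels.
#' @param logOr,se Log odds ratios and SEs (either both given, or derived
#'   from \code{or}/\code{ciLow}/\code{ciHigh}).
#' @param or,ciLow,ciHigh Odds ratio and CI, used when \code{logOr} is
#'   missing.
#' @param subgroup Optional subgroup labels.
#' @return data.frame with columns label, log_or, se, subgroup.
#' @export
metaInput <- function(label, logOr = NULL, se = NULL, or = NULL,
                      ciLow = NULL, ciHigh = NULL, subgroup = NA) {
  if (is.null(logOr)) {
    if (is.null(or) || is.null(ciLow) || is.null(ciHigh))
      .stopf("supply either logOr+se or or+ciLow+ciHigh")
    logOr <- log(or)
    se <- seFromCI(or, ciLow, ciHigh)
  }
  if (any(!is.finite(se) | se <= 0)) .stopf("se must be finite and > 0")
  data.frame(label = as.character(label), log_or = logOr, se = se,
             subgroup = as.character(subgroup), stringsAsFactors = FALSE)
}

.poolCore <- function(y, s, model) {
  k <- length(y)
  w <- 1 / s^2
  fixed <- sum(w * y) / sum(w)
  Q <- sum(w * (y - fixed)^2)
  df <- k - 1
  tau2 <- 0
  if (model == "random_DL" && k > 1) {
    C <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (Q - df) / C)
  } else if (model == "random_REML" && k > 1) {
    ## maximize the restricted log-likelihood over tau2 >= 0
    rll <- function(t2) {
      wi <- 1 / (s^2 + t2)
      mu <- sum(wi * y) / sum(wi)
      -0.5 * (sum(log(s^2 + t2)) + log(sum(wi)) + sum(wi * (y - mu)^2))
    }
    upper <- max(stats::var(y) * 10, max(s^2) * 10, 1e-6)
    opt <- stats::optimize(rll, c(0, upper), maximum = TRUE,
                           tol = .Machine$double.eps^0.5)
    tau2 <- if (rll(0) >= opt$objective) 0 else opt$maximum
  }
  wStar <- 1 / (s^2 + tau2)
  beta <- sum(wStar * y) / sum(wStar)
  se <- sqrt(1 / sum(wStar))
  i2 <- if (Q > 0 && df > 0) max(0, (Q - df) / Q) * 100 else 0
  list(beta = beta, se = se, Q = Q, df = df, tau2 = tau2, i2 = i2)
}

#' Pool causal estimates across analyses
#'
#' Fixed-effect pooling uses inverse-variance weights \eqn{1/se^2}.
#' Random-effects pooling adds a between-study variance \eqn{\tau^2} to
#' every weight; \eqn{\tau^2} is estimated by REML (default, matching the
#' standard meta-analysis default for log-OR inputs) or by the
#' DerSimonian-Laird moment estimator
#' \eqn{\hat\tau^2 = \max(0, (Q - df)/C)}, \eqn{C = \sum w - \sum w^2 /
#' \sum w}. Heterogeneity is summarised by Cochran's Q and
#' \eqn{I^2 = \max(0, (Q - df)/Q) \times 100}.
#'
#' @param rows data.frame from [metaInput()] (columns \code{log_or},
#'   \code{se}; \code{label}, \code{subgroup} optional).
#' @param model "random_REML" (default), "random_DL" or "fixed".
#' @return A [MetaResult-class].
#' @examples
#' rows <- metaInput(c("DBR", "DR", "NPDR", "PDR"),
#'   or = c(1.19, 1.10, 1.19, 1.10), ciLow = c(1.09, 1.04, 1.03, 1.05),
#'   ciHigh = c(1.31, 1.16, 1.37, 1.15))
#' metaPool(rows)   # pooled OR about 1.11 [1.08, 1.15]
#' @export
metaPool <- function(rows, model = c("random_REML", "random_DL", "fixed")) {
  model <- match.arg(model)
  if (!nrow(rows)) .stopf("empty meta-analysis input")
  if (any(rows$se <= 0)) .stopf("se must be > 0")
  p <- .poolCore(rows$log_or, rows$se, model)
  z <- stats::qnorm(0.975)
  methods::new("MetaResult", model = model, beta = p$beta, se = p$se,
               ciLow = p$beta - z * p$se, ciHigh = p$beta + z * p$se,
               pval = 2 * stats::pnorm(-abs(p$beta / p$se)),
               qStat = p$Q, df = as.numeric(p$df),
               qPval = if (p$df > 0)
                 stats::pchisq(p$Q, p$df, lower.tail = FALSE) else NA_real_,
               tau2 = p$tau2, i2 = p$i2, subgroups = list())
}

#' Subgroup meta-analysis
#'
#' Pools each subgroup separately and overall, reporting heterogeneity
#' for every pool.
#'
#' @param rows data.frame from [metaInput()] with a non-NA
#'   \code{subgroup} column.
#' @param model Passed to [metaPool()].
#' @return A [MetaResult-class] for the overall pool whose
#'   \code{subgroups} slot holds one [MetaResult-class] per subgroup.
#' @export
subgroupMeta <- function(rows, model = c("random_REML", "random_DL",
                                         "fixed")) {
  model <- match.arg(model)
  if (anyNA(rows$subgroup) || any(rows$subgroup == "NA"))
    .stopf("every row needs a subgroup label")
  overall <- metaPool(rows, model = model)
  groups <- split(rows, rows$subgroup)
  overall@subgroups <- lapply(groups, metaPool, model = model)
  overall
}

#' Forest-plot data export
#'
#' Emits the per-row estimates plus subgroup and overall pooled diamonds
#' as a plain data.frame suitable for plotting or archiving.
#'
#' @param rows data.frame from [metaInput()].
#' @param model Passed to [metaPool()].
#' @return data.frame with columns type ("study", "subgroup", "overall"),
#'   label, or, ci_low, ci_high, weight_pct.
#' @export
forestData <- function(rows, model = c("random_REML", "random_DL",
                                       "fixed")) {
  model <- match.arg(model)
  res <- if (!anyNA(rows$subgroup) && !all(rows$subgroup == "NA"))
    subgroupMeta(rows, model) else metaPool(rows, model)
  w <- 1 / (rows$se^2 + res@tau2)
  z <- stats::qnorm(0.975)
  out <- data.frame(type = "study", label = rows$label,
                    or = exp(rows$log_or),
                    ci_low = exp(rows$log_or - z * rows$se),
                    ci_high = exp(rows$log_or + z * rows$se),
                    weight_pct = 100 * w / sum(w),
                    stringsAsFactors = FALSE)
  for (nm in names(res@subgroups)) {
    s <- res@subgroups[[nm]]
    out <- rbind(out, data.frame(type = "subgroup", label = nm,
                                 or = exp(s@beta), ci_low = exp(s@ciLow),
                                 ci_high = exp(s@ciHigh),
                                 weight_pct = NA_real_))
  }
  rbind(out, data.frame(type = "overall", label = "overall",
                        or = exp(res@beta), ci_low = exp(res@ciLow),
                        ci_high = exp(res@ciHigh), weight_pct = NA_real_))
}
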